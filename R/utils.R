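#' @importFrom stats rbeta rbinom rnbinom rpois runif rlnorm rexp sd cor pt
#'   binom.test setNames
#' @importFrom utils read.table write.table
#' @importFrom data.table data.table
NULL

.datatable.aware <- TRUE

# Stable 31-adic string hash into [0, 2^31-2]; used to derive independent,
# reproducible RNG streams per (seed, label) without a digest dependency.
.hash_string <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (c in utf8ToInt(x)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

.derive_seed <- function(seed, ...) {
  labs <- paste(c(seed, ...), collapse = "/")
  .hash_string(labs)
}

# Run `expr` under a locally seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Composite key identifying a variant call
#'
#' @param x a calls data frame (see [variant_calls()]) or anything with
#'   `chrom`, `pos`, `ref`, `alt` columns.
#' @return character vector `chrom:pos:ref>alt`, one per row.
#' @export
call_key <- function(x) {
  if (length(x$pos) == 0L) return(character(0))
  paste0(x$chrom, ":", x$pos, ":", x$ref, ">", x$alt)
}
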