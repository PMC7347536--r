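#' Panel of normals keyed by variant
#'
#' Stores, for every variant ever detected in a normal sample, the allelic
#' fraction observed in each normal that carries it. Absence of a key
#' means the variant was seen in no normal. Detection implies a positive
#' allelic fraction, so `af` must lie in (0, 1].
#'
#' @param entries data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `normal_id`, `af`.
#' @param n_normals number of normals that contributed to the panel
#'   (defaults to the number of distinct `normal_id`s); kept explicitly
#'   because a normal may contribute zero variants.
#' @return an object of class `panel_of_normals`.
#' @export
panel_of_normals <- function(entries = NULL, n_normals = NULL) {
  if (is.null(entries) || nrow(entries) == 0L) {
    entries <- data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          normal_id = character(), af = double(),
                          stringsAsFactors = FALSE)
  }
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "normal_id", "af")
  miss <- setdiff(need, names(entries))
  if (length(miss))
    .stopf("panel of normals missing column(s): %s", paste(miss, collapse = ", "))
  if (any(entries$af <= 0 | entries$af > 1))
    .stopf("panel-of-normals allelic fractions must lie in (0, 1]")
  if (is.null(n_normals)) n_normals <- length(unique(entries$normal_id))
  entries <- entries[, need]
  entries$pos <- as.integer(entries$pos)
  structure(list(entries = entries, n_normals = as.integer(n_normals)),
            class = "panel_of_normals")
}

#' @export
print.panel_of_normals <- function(x, ...) {
  cat(sprintf("<panel_of_normals> %d normals, %d detections at %d sites\n",
              x$n_normals, nrow(x$entries),
              length(unique(call_key(x$entries)))))
  invisible(x)
}

#' Merge a matched normal's observations into a panel of normals
#'
#' Used by paired-mode filtering: every variant detected in the matched
#' normal (positive alt depth) is added with its normal allelic fraction,
#' so the patient's own germline fails the allelic-fraction ratio filter.
#'
#' @param pon a [panel_of_normals()].
#' @param normal_callset a [sample_callset()] of the matched normal.
#' @return a new `panel_of_normals` with `n_normals + 1`.
#' @export
pon_merge_normal <- function(pon, normal_callset) {
  calls <- normal_callset$calls
  calls <- calls[calls$alt_depth > 0 & calls$total_depth > 0, , drop = FALSE]
  add <- data.frame(chrom = calls$chrom, pos = calls$pos, ref = calls$ref,
                    alt = calls$alt,
                    normal_id = rep(normal_callset$sample_id, nrow(calls)),
                    af = calls$vaf, stringsAsFactors = FALSE)
  panel_of_normals(rbind(pon$entries, add), n_normals = pon$n_normals + 1L)
}

#' Minimum Af_tumor/Af_normal ratio against a panel of normals
#'
#' For each call, returns the smallest ratio of the tumor allelic fraction
#' to the allelic fraction in any normal carrying the variant, or `Inf`
#' when no normal carries it (the ratio condition then holds vacuously).
#'
#' @param calls a [variant_calls()] data frame (tumor calls).
#' @param pon a [panel_of_normals()].
#' @return numeric vector of per-call minimum ratios.
#' @export
pon_min_ratio <- function(calls, pon) {
  n <- nrow(calls)
  if (n == 0L) return(numeric(0))
  if (nrow(pon$entries) == 0L) return(rep(Inf, n))
  tab <- data.table::data.table(k = call_key(pon$entries),
                                af = pon$entries$af)
  max_af <- tab[, list(max_af = max(af)), by = "k"]
  idx <- match(call_key(calls), max_af$k)
  out <- rep(Inf, n)
  hit <- !is.na(idx)
  out[hit] <- calls$vaf[hit] / max_af$max_af[idx[hit]]
  out
}
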