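#' Build a per-base coverage profile over a territory
#'
#' Depth is interval-encoded: each row gives a constant depth over a
#' half-open 0-based interval. On construction the profile is clipped to
#' the territory and any territory base not covered by an input interval
#' is explicitly assigned depth 0 — bases outside the territory remain
#' undefined and cannot be queried.
#'
#' @param chrom,start,end interval bounds (BED conventions: 0-based,
#'   half-open).
#' @param depth non-negative integer depth per interval.
#' @param territory territory `GRanges` the profile is defined over.
#' @param sample_id sample the profile belongs to.
#' @return a `GRanges` with `depth` metadata column covering exactly the
#'   territory, plus `sample_id` in its metadata.
#' @export
coverage_profile <- function(chrom, start, end, depth, territory,
                             sample_id = NA_character_) {
  if (any(depth < 0)) .stopf("coverage depth must be non-negative")
  if (length(chrom)) {
    if (any(start >= end)) .stopf("coverage intervals must satisfy start < end")
    gr <- GenomicRanges::GRanges(chrom,
            IRanges::IRanges(start = start + 1L, end = end))
    gr$depth <- as.numeric(depth)
    # clip to the territory
    hits <- GenomicRanges::findOverlaps(gr, territory)
    clipped <- IRanges::pintersect(gr[S4Vectors::queryHits(hits)],
                                   territory[S4Vectors::subjectHits(hits)])
    clipped$hit <- NULL
  } else {
    clipped <- GenomicRanges::GRanges()
    clipped$depth <- numeric()
  }
  # zero-fill territory bases without an input interval
  gap <- GenomicRanges::setdiff(territory, clipped)
  if (length(gap)) gap$depth <- 0
  prof <- GenomicRanges::sort(c(clipped, gap))
  S4Vectors::metadata(prof)$sample_id <- sample_id
  S4Vectors::metadata(prof)$territory_name <- territory_name(territory)
  prof
}

#' Read an interval coverage TSV
#'
#' Expects four unnamed columns: chrom, start, end, depth (0-based
#' half-open intervals).
#'
#' @inheritParams coverage_profile
#' @param path TSV file.
#' @return a coverage profile `GRanges`.
#' @export
read_coverage <- function(path, territory, sample_id = NA_character_) {
  if (file.size(path) == 0L)
    return(coverage_profile(character(), integer(), integer(), numeric(),
                            territory, sample_id))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) .stopf("coverage TSV %s needs 4 columns", path)
  if (any(df[[4]] < 0)) .stopf("negative depth in coverage TSV %s", path)
  coverage_profile(df[[1]], as.integer(df[[2]]), as.integer(df[[3]]),
                   df[[4]], territory, sample_id)
}

#' @rdname read_coverage
#' @param cov a coverage profile `GRanges`.
#' @export
write_coverage <- function(cov, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(cov)),
                   start = GenomicRanges::start(cov) - 1L,
                   end = GenomicRanges::end(cov),
                   depth = cov$depth)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Query depth at single positions
#'
#' @param cov coverage profile `GRanges`.
#' @param chrom,pos 1-based positions to query.
#' @return numeric depth per position.
#' @export
depth_at <- function(cov, chrom, pos) {
  if (length(chrom) == 0L) return(numeric(0))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(q, cov, select = "first")
  if (anyNA(hits))
    .stopf("%d queried position(s) fall outside the coverage territory",
           sum(is.na(hits)))
  cov$depth[hits]
}

#' Callable territory size in megabases
#'
#' Counts territory bases whose depth strictly exceeds `min_coverage`
#' (at the default of 15, a base needs depth >= 16) and returns the count
#' in megabases. This is the denominator of the TMB calculation.
#'
#' @param cov coverage profile `GRanges`.
#' @param territory territory `GRanges`.
#' @param min_coverage depth that must be strictly exceeded (default 15).
#' @return callable size in MB (0 for an empty territory).
#' @export
callable_megabases <- function(cov, territory, min_coverage = 15L) {
  if (length(territory) == 0L) return(0)
  keep <- GenomicRanges::reduce(cov[cov$depth > min_coverage])
  inter <- GenomicRanges::intersect(keep, territory)
  sum(as.numeric(GenomicRanges::width(inter))) / 1e6
}
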