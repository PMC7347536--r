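#' Build a genomic territory (panel or exome coding space)
#'
#' A territory is the set of intervals over which variants are counted and
#' callable megabases are measured. It is stored as a reduced
#' [GenomicRanges::GRanges] (overlapping and abutting intervals merged).
#' Constructor input uses BED conventions: 0-based, half-open.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end 0-based half-open interval bounds.
#' @param name territory label (panel or exome id).
#' @return a `GRanges` with a `territory_name` metadata entry.
#' @export
territory <- function(chrom = character(), start = integer(),
                      end = integer(), name = "territory") {
  if (any(start >= end))
    .stopf("territory intervals must satisfy start < end")
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start + 1L, end = end))
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  S4Vectors::metadata(gr)$territory_name <- name
  gr
}

#' @rdname territory
#' @param x a territory `GRanges`.
#' @return `coding_mb`: total territory size in megabases.
#' @export
coding_mb <- function(x) {
  sum(as.numeric(GenomicRanges::width(x))) / 1e6
}

#' @rdname territory
#' @export
territory_name <- function(x) {
  nm <- S4Vectors::metadata(x)$territory_name
  if (is.null(nm)) "territory" else nm
}

#' Read a territory from a BED3 file
#'
#' @param path BED file (>= 3 columns, 0-based half-open, no header).
#' @param name territory label; defaults to the file name.
#' @return a territory `GRanges`.
#' @export
read_bed <- function(path, name = sub("\\.bed$", "", basename(path))) {
  if (file.size(path) == 0L) return(territory(name = name))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) .stopf("BED file %s has fewer than 3 columns", path)
  df[[2]] <- as.integer(df[[2]]); df[[3]] <- as.integer(df[[3]])
  bad <- which(df[[2]] >= df[[3]])
  if (length(bad))
    .stopf("invalid BED interval (start >= end) at line %d of %s",
           bad[1], path)
  territory(df[[1]], df[[2]], df[[3]], name = name)
}

#' Write a territory as BED3
#'
#' @param x territory `GRanges`.
#' @param path output file.
#' @export
write_bed <- function(x, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                   start = GenomicRanges::start(x) - 1L,
                   end = GenomicRanges::end(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# GRanges of width-1 loci for a calls data frame.
.call_loci <- function(calls) {
  GenomicRanges::GRanges(calls$chrom,
                         IRanges::IRanges(start = calls$pos, width = 1L))
}

#' Which calls fall inside a territory?
#'
#' @param calls a [variant_calls()] data frame.
#' @param territory a territory `GRanges`.
#' @return logical vector, one per call.
#' @export
in_territory <- function(calls, territory) {
  if (nrow(calls) == 0L) return(logical(0))
  IRanges::overlapsAny(.call_loci(calls), territory)
}
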