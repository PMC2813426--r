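#' Create a genomic interval table
#'
#' Intervals use the package-wide coordinate convention: 0-based starts,
#' exclusive ends (half-open). Conversion to the 1-based conventions of SAM
#' and VCF-like files happens only inside the readers and writers.
#'
#' @param chrom Character vector of sequence names.
#' @param start Integer vector of 0-based inclusive start offsets.
#' @param end Integer vector of exclusive end offsets.
#' @return A `data.frame` with columns `chrom`, `start`, `end`.
#' @export
interval <- function(chrom, start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(chrom)) || any(!nzchar(chrom))) {
    stop("interval: 'chrom' must be non-empty")
  }
  if (any(start < 0L) || any(start >= end)) {
    stop("interval: require 0 <= start < end")
  }
  data.frame(chrom = as.character(chrom), start = start, end = end,
             stringsAsFactors = FALSE)
}

# Overlap width of [s1,e1) with [s2,e2); 0 when disjoint. Vectorised.
overlap_width <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

# Union length of a set of intervals on one sequence (0-based half-open).
union_length <- function(start, end) {
  if (length(start) == 0L) return(0L)
  r <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  sum(IRanges::width(r))
}
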