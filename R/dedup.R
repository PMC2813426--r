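# Duplicate-read removal and aberrant-pair classification: the
# pre-processing contract between alignment and structural-variant calling.

#' Aberrant-pair configuration
#'
#' A mate pair is aberrant when it maps to two chromosomes or when its
#' outer span falls outside `[lower, upper]` — strictly less than `lower`
#' or strictly greater than `upper`, matching the expected-insert window
#' of the library.
#'
#' @param lower,upper Bounds of the expected insert window, in bases.
#' @return A list of class `aberrant_pair_config`.
#' @export
aberrant_pair_config <- function(lower = 1000L, upper = 2000L) {
  stopifnot(lower > 0L, lower < upper)
  structure(list(lower = as.integer(lower), upper = as.integer(upper)),
            class = "aberrant_pair_config")
}

#' Flag duplicate reads
#'
#' Mate pairs with both ends mapped are duplicates of each other when both
#' ends share start positions (order-insensitive). Single-end records —
#' unpaired reads or pairs with an unmapped mate — are duplicates when they
#' share a start position (and, by default, a strand). Within each
#' duplicate group the read with the lexicographically smallest id stays
#' unflagged; every other member is flagged. Cardinality is preserved and
#' the operation is idempotent and independent of input order.
#'
#' @param reads Alignment data.frame.
#' @param single_end_use_strand Require matching strand for single-end
#'   duplicate groups (pair groups never use strand).
#' @return `reads` with the `duplicate` column recomputed.
#' @export
mark_duplicates <- function(reads, single_end_use_strand = TRUE) {
  reads$duplicate <- FALSE
  is_pair <- reads$paired & reads$mapped & reads$mate_mapped
  if (any(is_pair)) {
    a <- paste0(reads$chrom[is_pair], ":", reads$start[is_pair])
    b <- paste0(reads$mate_chrom[is_pair], ":", reads$mate_start[is_pair])
    key <- ifelse(a <= b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
    reads$duplicate[is_pair] <- !keep_min_id(key, reads$read_id[is_pair])
  }
  is_single <- reads$mapped & !is_pair
  if (any(is_single)) {
    key <- paste0(reads$chrom[is_single], ":", reads$start[is_single])
    if (single_end_use_strand) {
      key <- paste0(key, ":", reads$strand[is_single])
    }
    reads$duplicate[is_single] <- !keep_min_id(key, reads$read_id[is_single])
  }
  reads
}

# TRUE for records carrying the smallest read_id of their key group (all
# records of that read_id, so both ends of the kept pair stay unflagged).
keep_min_id <- function(key, id) {
  dt <- data.table::data.table(grp = key, id = id)
  dt[, keep := id == min(id), by = "grp"]
  dt$keep
}

#' Collapse an alignment table into one row per mate pair
#'
#' @param reads Alignment data.frame; only pairs with both ends mapped are
#'   returned.
#' @return Data.frame with one row per pair: coordinates, CIGARs and
#'   end-exclusive stop coordinates of both ends, plus the pair-level
#'   duplicate flag (TRUE if either end is flagged).
#' @export
pair_reads <- function(reads) {
  r <- reads[reads$paired & reads$mapped & reads$mate_mapped, , drop = FALSE]
  r1 <- r[r$first_in_pair, , drop = FALSE]
  r2 <- r[!r$first_in_pair, , drop = FALSE]
  m <- match(r1$read_id, r2$read_id)
  ok <- !is.na(m)
  r1 <- r1[ok, , drop = FALSE]
  r2 <- r2[m[ok], , drop = FALSE]
  data.frame(
    read_id = r1$read_id,
    chrom1 = r1$chrom, start1 = r1$start,
    end1 = r1$start + cigar_ref_len_fast(r1$cigar),
    chrom2 = r2$chrom, start2 = r2$start,
    end2 = r2$start + cigar_ref_len_fast(r2$cigar),
    duplicate = r1$duplicate | r2$duplicate,
    stringsAsFactors = FALSE
  )
}

#' Outer span of mate pairs
#'
#' "Bases apart" is the outer span: the rightmost end-exclusive coordinate
#' minus the leftmost start. Interchromosomal pairs get `Inf`, so any
#' finite window classifies them aberrant.
#'
#' @param pairs Pair data.frame from [pair_reads()].
#' @return Numeric vector of spans (`Inf` for interchromosomal pairs).
#' @export
pair_span <- function(pairs) {
  ifelse(pairs$chrom1 == pairs$chrom2,
         pmax(pairs$end1, pairs$end2) - pmin(pairs$start1, pairs$start2),
         Inf)
}

#' Classify mate pairs as aberrant
#'
#' @param pairs Pair data.frame from [pair_reads()].
#' @param cfg An [aberrant_pair_config()].
#' @return Logical vector: TRUE when interchromosomal or when the outer
#'   span is strictly below `lower` or strictly above `upper`.
#' @export
is_aberrant <- function(pairs, cfg = aberrant_pair_config()) {
  span <- pair_span(pairs)
  span < cfg$lower | span > cfg$upper
}
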