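# Fixture builders used across the suite. Everything is generated in code;
# no data files.

mk_read <- function(id, chrom, start, strand = "+", cigar = "50M",
                    seq = strrep("A", 50L), mate_chrom = NA_character_,
                    mate_start = NA_integer_, mate_strand = "+",
                    first = TRUE, dup = FALSE, mapped = TRUE) {
  paired <- !is.na(mate_chrom)
  data.frame(read_id = id, chrom = chrom, start = as.integer(start),
             strand = strand, cigar = cigar, seq = seq,
             mate_chrom = mate_chrom, mate_start = as.integer(mate_start),
             mate_strand = mate_strand, mapped = mapped,
             mate_mapped = paired, paired = paired, first_in_pair = first,
             duplicate = dup, stringsAsFactors = FALSE)
}

# Two alignment rows forming a mapped mate pair.
mk_pair <- function(id, chrom1, start1, chrom2, start2, cigar1 = "50M",
                    cigar2 = "50M", seq1 = strrep("A", 50L),
                    seq2 = strrep("A", 50L)) {
  rbind(
    mk_read(id, chrom1, start1, "+", cigar1, seq1, chrom2, start2, "-",
            first = TRUE),
    mk_read(id, chrom2, start2, "-", cigar2, seq2, chrom1, start1, "+",
            first = FALSE)
  )
}

mk_reads <- function(..., seq_lengths = NULL) {
  out <- do.call(rbind, list(...))
  rownames(out) <- NULL
  if (!is.null(seq_lengths)) attr(out, "seq_lengths") <- seq_lengths
  out
}

# One-row gene model data.frame with list columns.
toy_gene <- function(name = "g1", chrom = "chr1", strand = "+",
                     tx_start, tx_end, cds_start, cds_end,
                     exon_starts, exon_ends, symbol = toupper(name)) {
  g <- data.frame(name = name, symbol = symbol, chrom = chrom,
                  strand = strand, tx_start = as.integer(tx_start),
                  tx_end = as.integer(tx_end),
                  cds_start = as.integer(cds_start),
                  cds_end = as.integer(cds_end), stringsAsFactors = FALSE)
  g$exon_starts <- list(as.integer(exon_starts))
  g$exon_ends <- list(as.integer(exon_ends))
  g
}

# Independent slow oracle for SNV observation eligibility: re-scans every
# read with explicit loops, no shared code with the implementation.
oracle_snv_counts <- function(reads, chrom, pos, alt, tail_n = 5L) {
  fwd <- 0L; rev <- 0L
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    if (!r$mapped || r$duplicate || r$chrom != chrom) next
    if (grepl("[ID]", r$cigar)) next
    len <- nchar(r$seq)
    if (pos < r$start || pos >= r$start + len) next
    off <- pos - r$start
    seq_off <- if (r$strand == "+") off else len - 1L - off
    if (seq_off >= len - tail_n) next
    if (substr(r$seq, off + 1L, off + 1L) != alt) next
    if (r$strand == "+") fwd <- fwd + 1L else rev <- rev + 1L
  }
  c(fwd = fwd, rev = rev)
}

# Exact binomial upper tail by direct pmf summation (independent oracle).
oracle_binom_upper <- function(k, n, p) {
  sum(vapply(k:n, function(x) choose(n, x) * p^x * (1 - p)^(n - x),
             numeric(1)))
}

# Reconstruct a haplotype sequence from the reference and truth records
# (independent oracle for truth/donor consistency).
oracle_apply_truth <- function(ref_seq, truth) {
  truth <- truth[order(truth$pos), , drop = FALSE]
  out <- character(0)
  cur <- 0L
  for (i in seq_len(nrow(truth))) {
    p <- truth$pos[i]
    if (p > cur) out <- c(out, substr(ref_seq, cur + 1L, p))
    if (truth$vtype[i] == "SNV") {
      out <- c(out, truth$alt[i]); cur <- p + 1L
    } else if (truth$vtype[i] == "DEL") {
      cur <- p + nchar(truth$ref[i])
    } else {
      out <- c(out, truth$alt[i]); cur <- p
    }
  }
  paste0(paste(out, collapse = ""),
         substr(ref_seq, cur + 1L, nchar(ref_seq)))
}
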