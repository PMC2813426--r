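# Read-level observation eligibility, site-level filtering and dbSNP-style
# catalog matching for SNVs and small (<21 bp) indels.

#' Site filter configuration
#'
#' Defaults implement the published operating point: consensus Phred >= 10,
#' total eligible observations >= 4 and < 60, at least one observation on
#' each strand; SNVs counted only in indel-free reads with the last 5
#' sequenced bases ignored; indel-supporting reads must carry exactly one
#' contiguous indel not at either read edge.
#'
#' @param min_phred Minimum consensus Phred score.
#' @param min_obs Minimum total eligible observations (inclusive).
#' @param max_obs Maximum total eligible observations (exclusive).
#' @param min_per_strand Minimum eligible observations per strand.
#' @param snv_tail_exclusion Number of 3'-tail bases ignored for SNV
#'   support (sequencing order, so reverse-strand reads exclude their
#'   leftmost reference-facing bases).
#' @param require_indel_free_reads_for_snv Only indel-free reads may
#'   support an SNV.
#' @param single_contiguous_indel Indel-supporting reads must contain
#'   exactly one contiguous indel run.
#' @return A list of class `site_filter_config`.
#' @export
site_filter_config <- function(min_phred = 10, min_obs = 4L, max_obs = 60L,
                               min_per_strand = 1L, snv_tail_exclusion = 5L,
                               require_indel_free_reads_for_snv = TRUE,
                               single_contiguous_indel = TRUE) {
  stopifnot(min_obs < max_obs)
  structure(list(min_phred = min_phred, min_obs = as.integer(min_obs),
                 max_obs = as.integer(max_obs),
                 min_per_strand = as.integer(min_per_strand),
                 snv_tail_exclusion = as.integer(snv_tail_exclusion),
                 require_indel_free_reads_for_snv =
                   require_indel_free_reads_for_snv,
                 single_contiguous_indel = single_contiguous_indel),
            class = "site_filter_config")
}

#' Count eligible SNV observations at a site
#'
#' A read supports the alternate allele iff it is mapped and not a
#' duplicate, its CIGAR contains no insertion or deletion run, the site's
#' offset in sequencing order lies before the excluded 3' tail, and the
#' read base at the site equals `alt`. Counts are tallied on the read's
#' strand.
#'
#' @param reads Alignment data.frame.
#' @param chrom,pos Site (0-based).
#' @param alt Alternate base.
#' @param cfg A [site_filter_config()].
#' @return Integer vector `c(fwd, rev)`.
#' @export
eligible_snv_observations <- function(reads, chrom, pos, alt,
                                      cfg = site_filter_config()) {
  r <- reads[reads$mapped & !reads$duplicate & reads$chrom == chrom, ,
             drop = FALSE]
  fwd <- 0L; rev <- 0L
  for (i in seq_len(nrow(r))) {
    if (cfg$require_indel_free_reads_for_snv &&
        !cigar_is_simple(r$cigar[i])) next
    len <- nchar(r$seq[i])
    off <- pos - r$start[i]
    if (off < 0L || off >= len) next
    seq_off <- if (r$strand[i] == "+") off else len - 1L - off
    if (seq_off >= len - cfg$snv_tail_exclusion) next
    if (substr(r$seq[i], off + 1L, off + 1L) != alt) next
    if (r$strand[i] == "+") fwd <- fwd + 1L else rev <- rev + 1L
  }
  c(fwd = fwd, rev = rev)
}

#' Count eligible indel observations at a site
#'
#' A read supports the indel iff its CIGAR contains exactly one insertion
#' or deletion run, that run matches the site's position, type and allele
#' length (and, for insertions, the inserted bases), and the run is
#' flanked by at least one aligned base on both sides.
#'
#' @param reads Alignment data.frame.
#' @param chrom,pos Site (0-based; deletions start at `pos`, insertions
#'   sit before the base at `pos`).
#' @param allele Deleted (DEL) or inserted (INS) bases.
#' @param vtype `"DEL"` or `"INS"`.
#' @param cfg A [site_filter_config()].
#' @return Integer vector `c(fwd, rev)`.
#' @export
eligible_indel_observations <- function(reads, chrom, pos, allele, vtype,
                                        cfg = site_filter_config()) {
  r <- reads[reads$mapped & !reads$duplicate & reads$chrom == chrom, ,
             drop = FALSE]
  want_op <- if (vtype == "DEL") "D" else "I"
  alen <- nchar(allele)
  fwd <- 0L; rev <- 0L
  for (i in seq_len(nrow(r))) {
    if (cigar_is_simple(r$cigar[i])) next
    runs <- cigar_runs(r$cigar[i])[[1]]
    ind <- which(runs$op %in% c("I", "D"))
    if (cfg$single_contiguous_indel && length(ind) != 1L) next
    if (length(ind) < 1L) next
    k <- ind[1]
    if (runs$op[k] != want_op || runs$len[k] != alen) next
    if (k == 1L || k == nrow(runs)) next  # indel at a read edge
    ref_off <- sum(runs$len[seq_len(k - 1L)][
      runs$op[seq_len(k - 1L)] %in% c("M", "D")])
    if (r$start[i] + ref_off != pos) next
    if (vtype == "INS" && r$seq[i] != "*") {
      read_off <- sum(runs$len[seq_len(k - 1L)][
        runs$op[seq_len(k - 1L)] %in% c("M", "I")])
      if (substr(r$seq[i], read_off + 1L, read_off + alen) != allele) next
    }
    if (r$strand[i] == "+") fwd <- fwd + 1L else rev <- rev + 1L
  }
  c(fwd = fwd, rev = rev)
}

#' Apply site-level filters to variant calls
#'
#' @param calls Variant-call data.frame with `phred`, `fwd`, `rev`.
#' @param cfg A [site_filter_config()].
#' @return Logical vector: TRUE where `phred >= min_phred`,
#'   `min_obs <= fwd + rev < max_obs`, and both strands reach
#'   `min_per_strand`.
#' @export
apply_site_filters <- function(calls, cfg = site_filter_config()) {
  tot <- calls$fwd + calls$rev
  calls$phred >= cfg$min_phred &
    tot >= cfg$min_obs & tot < cfg$max_obs &
    calls$fwd >= cfg$min_per_strand & calls$rev >= cfg$min_per_strand
}

#' Match variant calls against a dbSNP-style catalog
#'
#' By default a call matches only when chromosome, position, allele and
#' type all agree with a catalog entry; with `require_allele = FALSE` a
#' position/type match suffices (the looser reading under which a novel
#' allele at a known location counts as known).
#'
#' @param calls Variant-call data.frame.
#' @param catalog Catalog data.frame from [read_dbsnp()].
#' @param require_allele Require the allele to match.
#' @param ref Optional reference; when supplied, indel calls and catalog
#'   entries are left-aligned before matching.
#' @return Logical vector of matches.
#' @export
match_dbsnp <- function(calls, catalog, require_allele = TRUE, ref = NULL) {
  if (nrow(calls) == 0L) return(logical(0))
  call_allele <- ifelse(calls$vtype == "DEL", calls$ref, calls$alt)
  call_pos <- calls$pos
  cat_pos <- catalog$pos
  cat_allele <- catalog$allele
  if (!is.null(ref)) {
    for (i in which(calls$vtype != "SNV")) {
      na <- normalize_indel(ref, calls$chrom[i], call_pos[i],
                            call_allele[i], calls$vtype[i])
      call_pos[i] <- na$pos; call_allele[i] <- na$allele
    }
    for (i in which(catalog$vtype != "SNV")) {
      na <- normalize_indel(ref, catalog$chrom[i], cat_pos[i],
                            cat_allele[i], catalog$vtype[i])
      cat_pos[i] <- na$pos; cat_allele[i] <- na$allele
    }
  }
  if (require_allele) {
    key <- paste(calls$chrom, call_pos, call_allele, calls$vtype)
    ckey <- paste(catalog$chrom, cat_pos, cat_allele, catalog$vtype)
  } else {
    key <- paste(calls$chrom, call_pos, calls$vtype)
    ckey <- paste(catalog$chrom, cat_pos, catalog$vtype)
  }
  key %in% ckey
}

#' Left-align an indel within repetitive context
#'
#' Shifts an insertion or deletion to its leftmost equivalent placement
#' (rotating the allele as it moves), the usual normalisation before
#' position-keyed catalog comparison.
#'
#' @param ref Named character vector of reference sequences.
#' @param chrom,pos Indel site (0-based).
#' @param allele Deleted or inserted bases.
#' @param vtype `"DEL"` or `"INS"`.
#' @return List with normalised `pos` and `allele`.
#' @export
normalize_indel <- function(ref, chrom, pos, allele, vtype) {
  s <- ref[[chrom]]
  while (pos > 0L) {
    prev <- substr(s, pos, pos)  # base at 0-based pos-1
    last <- substr(allele, nchar(allele), nchar(allele))
    if (prev != last) break
    allele <- paste0(prev, substr(allele, 1L, nchar(allele) - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, allele = allele)
}

## ----------------------------------------------- naive pileup caller
# End-to-end plumbing only: the consensus/genotyping model that produced
# the calls this pipeline filters is an upstream tool. This caller exists
# so simulated reads can be turned into call tables; it assumes error-free
# reads of uniform length and reports a fixed high consensus Phred.

#' Call small variants from simulated reads (naive pileup)
#'
#' Collects eligible SNV and indel observations (per
#' [eligible_snv_observations()] / [eligible_indel_observations()] rules,
#' applied in aggregate), calls zygosity by alternate-allele fraction
#' (>= `hom_fraction_threshold` is homozygous) and assigns a fixed
#' consensus Phred. Intended for synthetic error-free reads.
#'
#' @param reads Alignment data.frame (deduplicated).
#' @param ref Named character vector of reference sequences.
#' @param cfg A [site_filter_config()].
#' @param hom_fraction_threshold Alt-fraction cut for homozygous calls.
#' @param phred Consensus Phred assigned to every call.
#' @return Variant-call data.frame (unfiltered).
#' @export
call_small_variants <- function(reads, ref, cfg = site_filter_config(),
                                hom_fraction_threshold = 0.75,
                                phred = 99) {
  r <- reads[reads$mapped & !reads$duplicate & reads$seq != "*", ,
             drop = FALSE]
  if (nrow(r) == 0L) return(empty_variant_calls())
  simple <- cigar_is_simple(r$cigar)
  tail_n <- cfg$snv_tail_exclusion
  # ---- SNV observations from indel-free reads
  sn <- r[simple, , drop = FALSE]
  acc <- list()
  for (i in seq_len(nrow(sn))) {
    len <- nchar(sn$seq[i])
    rs <- charToRaw(sn$seq[i])
    rr <- charToRaw(substr(ref[[sn$chrom[i]]], sn$start[i] + 1L,
                           sn$start[i] + len))
    mm <- which(rs != rr)
    if (length(mm) == 0L) next
    keep <- if (sn$strand[i] == "+") mm <= len - tail_n else mm > tail_n
    mm <- mm[keep]
    if (length(mm) == 0L) next
    acc[[length(acc) + 1L]] <- data.frame(
      chrom = sn$chrom[i], pos = sn$start[i] + mm - 1L,
      ref = rawToChar(rr[mm]), alt = strsplit(rawToChar(rs[mm]), "")[[1]],
      vtype = "SNV", strand = sn$strand[i], stringsAsFactors = FALSE)
  }
  # ---- indel observations
  ind <- r[!simple, , drop = FALSE]
  for (i in seq_len(nrow(ind))) {
    runs <- cigar_runs(ind$cigar[i])[[1]]
    kk <- which(runs$op %in% c("I", "D"))
    if (cfg$single_contiguous_indel && length(kk) != 1L) next
    k <- kk[1]
    if (k == 1L || k == nrow(runs)) next
    pre <- runs[seq_len(k - 1L), , drop = FALSE]
    ref_off <- sum(pre$len[pre$op %in% c("M", "D")])
    read_off <- sum(pre$len[pre$op %in% c("M", "I")])
    pos <- ind$start[i] + ref_off
    if (runs$op[k] == "D") {
      allele <- substr(ref[[ind$chrom[i]]], pos + 1L, pos + runs$len[k])
      vt <- "DEL"
    } else {
      allele <- substr(ind$seq[i], read_off + 1L, read_off + runs$len[k])
      vt <- "INS"
    }
    acc[[length(acc) + 1L]] <- data.frame(
      chrom = ind$chrom[i], pos = pos, ref = if (vt == "DEL") allele else "-",
      alt = if (vt == "INS") allele else "-", vtype = vt,
      strand = ind$strand[i], stringsAsFactors = FALSE)
  }
  if (length(acc) == 0L) return(empty_variant_calls())
  obs <- data.table::rbindlist(acc)
  counts <- obs[, .(fwd = sum(strand == "+"), rev = sum(strand == "-")),
                by = .(chrom, pos, ref, alt, vtype)]
  # eligible coverage at each site from indel-free reads (uniform length)
  len <- as.integer(stats::median(nchar(sn$seq)))
  cov <- site_eligible_coverage(sn, counts$chrom, counts$pos, len, tail_n)
  # indel-carrying reads are absent from the indel-free coverage, so they
  # join the denominator explicitly
  denom <- ifelse(counts$vtype == "SNV", cov,
                  cov + counts$fwd + counts$rev)
  alt_frac <- (counts$fwd + counts$rev) / pmax(denom, 1L)
  out <- data.frame(chrom = counts$chrom, pos = counts$pos,
                    ref = counts$ref, alt = counts$alt,
                    vtype = counts$vtype, phred = phred,
                    fwd = as.integer(counts$fwd),
                    rev = as.integer(counts$rev),
                    zygosity = ifelse(alt_frac >= hom_fraction_threshold,
                                      "hom", "het"),
                    in_dbsnp = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Tail-aware eligible coverage by indel-free reads of uniform length.
site_eligible_coverage <- function(sn, chrom, pos, len, tail_n) {
  cov <- integer(length(pos))
  for (cn in unique(chrom)) {
    qi <- which(chrom == cn)
    fw <- sort(sn$start[sn$chrom == cn & sn$strand == "+"])
    rv <- sort(sn$start[sn$chrom == cn & sn$strand == "-"])
    # + reads: start in [pos-len+tail_n+1 .. pos] leaves the site before
    # the excluded tail; - reads mirrored
    cov[qi] <- (findInterval(pos[qi], fw) -
                  findInterval(pos[qi] - len + tail_n, fw)) +
      (findInterval(pos[qi] - tail_n, rv) -
         findInterval(pos[qi] - len, rv))
  }
  cov
}

#' Filter variant calls and flag catalog membership
#'
#' @param calls Variant-call data.frame.
#' @param catalog Optional dbSNP-style catalog.
#' @param cfg A [site_filter_config()].
#' @param ref Optional reference for indel left-alignment in matching.
#' @return The calls passing [apply_site_filters()], with `in_dbsnp` set.
#' @export
filter_variants <- function(calls, catalog = NULL,
                            cfg = site_filter_config(), ref = NULL) {
  keep <- apply_site_filters(calls, cfg)
  out <- calls[keep, , drop = FALSE]
  if (!is.null(catalog)) {
    out$in_dbsnp <- match_dbsnp(out, catalog, ref = ref)
  }
  rownames(out) <- NULL
  out
}
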