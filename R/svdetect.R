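# Mate-pair structural-variant caller: bin the genome in overlapping
# 500-base bins stepped 100 bases apart, pair source bins with the
# destination bin receiving most of their aberrant mates ("binsets"),
# single-link cluster binsets into breakpoint-flanking regions, call
# events, and classify intrachromosomal events as complete/heterozygous
# deletions from interior-versus-flank read depth.

#' Structural-variant caller configuration
#'
#' Defaults are the published operating point of the method: 500-base bins
#' stepped 100 apart; binsets under 4 reads dropped; clusters of 9-29
#' binsets whose source bins span 1-3 kb accepted; intrachromosomal events
#' under 1 Mb assessed for deletion status against 200 kb flanks, with
#' interior/exterior depth ratio below 25% called a complete deletion and
#' 25-75% a heterozygous deletion.
#'
#' @param bin_width,bin_step Bin geometry in bases.
#' @param min_binset_reads Minimum reads per binset.
#' @param cluster_link Single-linkage distance for source and destination
#'   bins, in bases.
#' @param min_binsets,max_binsets Accepted cluster size range (inclusive).
#' @param min_span,max_span Accepted source-bin span range, in bases.
#' @param span_both_sides Also enforce the span window on destination bins.
#' @param max_deletion_size Largest intrachromosomal event assessed for
#'   deletion status.
#' @param flank Exterior depth window on each side, in bases.
#' @param complete_ratio,het_ratio Depth-ratio thresholds for complete and
#'   heterozygous deletions.
#' @param mirror_overlap Minimum shared-read fraction for merging the two
#'   mirror-image clusters of one event.
#' @return A list of class `sv_config`.
#' @export
sv_config <- function(bin_width = 500L, bin_step = 100L,
                      min_binset_reads = 4L, cluster_link = 2000L,
                      min_binsets = 9L, max_binsets = 29L,
                      min_span = 1000L, max_span = 3000L,
                      span_both_sides = FALSE,
                      max_deletion_size = 1000000L, flank = 200000L,
                      complete_ratio = 0.25, het_ratio = 0.75,
                      mirror_overlap = 0.5) {
  stopifnot(bin_width %% bin_step == 0L, min_span <= max_span,
            complete_ratio > 0, complete_ratio < het_ratio, het_ratio < 1)
  structure(list(bin_width = as.integer(bin_width),
                 bin_step = as.integer(bin_step),
                 min_binset_reads = as.integer(min_binset_reads),
                 cluster_link = as.integer(cluster_link),
                 min_binsets = as.integer(min_binsets),
                 max_binsets = as.integer(max_binsets),
                 min_span = as.integer(min_span),
                 max_span = as.integer(max_span),
                 span_both_sides = span_both_sides,
                 max_deletion_size = as.integer(max_deletion_size),
                 flank = as.integer(flank),
                 complete_ratio = complete_ratio, het_ratio = het_ratio,
                 mirror_overlap = mirror_overlap),
            class = "sv_config")
}

#' Bins covering a position
#'
#' A read belongs to a bin through its start position: all bins
#' `[s, s + width)` with `s` a multiple of `step` and `s <= pos < s + width`.
#' Away from the chromosome start there are exactly `width/step` such bins.
#'
#' @param chrom Sequence name (carried through).
#' @param pos 0-based position.
#' @param cfg An [sv_config()].
#' @return Data.frame of bins with columns `chrom`, `start`, `width`.
#' @export
bins_for_position <- function(chrom, pos, cfg = sv_config()) {
  s_max <- (pos %/% cfg$bin_step) * cfg$bin_step
  s_min <- max(0L, s_max - cfg$bin_width + cfg$bin_step)
  starts <- seq.int(s_min, s_max, by = cfg$bin_step)
  data.frame(chrom = chrom, start = starts, width = cfg$bin_width,
             stringsAsFactors = FALSE)
}

# Expand positions into (row index, bin start) pairs, vectorised.
bin_expand <- function(pos, cfg) {
  k <- cfg$bin_width %/% cfg$bin_step
  s_max <- (pos %/% cfg$bin_step) * cfg$bin_step
  idx <- rep(seq_along(pos), each = k)
  starts <- rep(s_max, each = k) - rep((k - 1L):0L, length(pos)) * cfg$bin_step
  keep <- starts >= 0L
  list(idx = idx[keep], start = starts[keep])
}

#' Build binsets from aberrant mate pairs
#'
#' Each pair contributes with either end as the source. A source bin's
#' binset points at the destination bin holding the largest number of its
#' mates' start positions (ties broken toward the lowest chromosome and
#' start); binsets supported by fewer than `min_binset_reads` reads are
#' discarded.
#'
#' @param pairs Aberrant, deduplicated pair data.frame ([pair_reads()]).
#' @param cfg An [sv_config()].
#' @return Data.frame of binsets: `src_chrom`, `src_start`, `dst_chrom`,
#'   `dst_start`, `count`, and a `read_ids` list column.
#' @export
build_binsets <- function(pairs, cfg = sv_config()) {
  if (nrow(pairs) == 0L) return(empty_binsets())
  # directed copies: (end1 -> end2) and (end2 -> end1)
  src_chrom <- c(pairs$chrom1, pairs$chrom2)
  src_pos <- c(pairs$start1, pairs$start2)
  dst_chrom <- c(pairs$chrom2, pairs$chrom1)
  dst_pos <- c(pairs$start2, pairs$start1)
  rid <- c(pairs$read_id, pairs$read_id)
  se <- bin_expand(src_pos, cfg)
  de <- bin_expand(dst_pos, cfg)
  sdt <- data.table::data.table(i = se$idx, sbin = se$start)
  ddt <- data.table::data.table(i = de$idx, dbin = de$start)
  comb <- merge(sdt, ddt, by = "i", allow.cartesian = TRUE)
  comb[, `:=`(schrom = src_chrom[i], dchrom = dst_chrom[i], rid = rid[i])]
  counts <- comb[, .(count = data.table::uniqueN(rid),
                     read_ids = list(unique(rid))),
                 by = .(schrom, sbin, dchrom, dbin)]
  data.table::setorder(counts, schrom, sbin, -count, dchrom, dbin)
  best <- counts[counts[, .I[1L], by = .(schrom, sbin)]$V1]
  best <- best[count >= cfg$min_binset_reads]
  out <- data.frame(src_chrom = best$schrom, src_start = best$sbin,
                    dst_chrom = best$dchrom, dst_start = best$dbin,
                    count = best$count, stringsAsFactors = FALSE)
  out$read_ids <- best$read_ids
  out
}

empty_binsets <- function() {
  out <- data.frame(src_chrom = character(), src_start = integer(),
                    dst_chrom = character(), dst_start = integer(),
                    count = integer(), stringsAsFactors = FALSE)
  out$read_ids <- list()
  out
}

#' Cluster binsets into breakpoint-flanking groups
#'
#' Single-linkage grouping of binsets whose source bins lie within
#' `cluster_link` of each other and whose destination bins do too (same
#' chromosomes on both sides). Identical (source, destination) binsets are
#' first merged with a union of read ids. Clusters survive only with
#' `min_binsets`-`max_binsets` members and a source-bin span (rightmost
#' bin end minus leftmost bin start) within `[min_span, max_span]`.
#'
#' @param binsets Binset data.frame from [build_binsets()].
#' @param cfg An [sv_config()].
#' @param keep_rejected Also return clusters failing the size/span rules
#'   (flagged by the `accepted` column).
#' @return Data.frame of clusters: regions on both sides, member count,
#'   source span, `read_ids` list column, `accepted`.
#' @export
cluster_binsets <- function(binsets, cfg = sv_config(),
                            keep_rejected = FALSE) {
  if (nrow(binsets) == 0L) return(empty_clusters())
  key <- paste(binsets$src_chrom, binsets$src_start,
               binsets$dst_chrom, binsets$dst_start)
  if (anyDuplicated(key)) {
    merged <- lapply(split(seq_along(key), key), function(ii) {
      b <- binsets[ii[1], , drop = FALSE]
      b$read_ids <- list(unique(unlist(binsets$read_ids[ii])))
      b$count <- length(b$read_ids[[1]])
      b
    })
    binsets <- do.call(rbind, merged)
    rownames(binsets) <- NULL
  }
  grp <- paste(binsets$src_chrom, binsets$dst_chrom)
  comp <- integer(nrow(binsets))
  next_id <- 0L
  for (g in unique(grp)) {
    ii <- which(grp == g)
    parent <- seq_along(ii)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (a in seq_along(ii)) {
      for (b in seq_len(a - 1L)) {
        if (abs(binsets$src_start[ii[a]] - binsets$src_start[ii[b]]) <=
              cfg$cluster_link &&
            abs(binsets$dst_start[ii[a]] - binsets$dst_start[ii[b]]) <=
              cfg$cluster_link) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
    roots <- vapply(seq_along(ii), find, integer(1))
    comp[ii] <- next_id + match(roots, unique(roots))
    next_id <- max(comp[ii])
  }
  rows <- lapply(unique(comp), function(cid) {
    m <- binsets[comp == cid, , drop = FALSE]
    w <- cfg$bin_width
    src_span <- max(m$src_start) + w - min(m$src_start)
    dst_span <- max(m$dst_start) + w - min(m$dst_start)
    ok_n <- nrow(m) >= cfg$min_binsets && nrow(m) <= cfg$max_binsets
    ok_span <- src_span >= cfg$min_span && src_span <= cfg$max_span
    if (cfg$span_both_sides) {
      ok_span <- ok_span && dst_span >= cfg$min_span &&
        dst_span <= cfg$max_span
    }
    out <- data.frame(
      src_chrom = m$src_chrom[1], src_start = min(m$src_start),
      src_end = max(m$src_start) + w,
      dst_chrom = m$dst_chrom[1], dst_start = min(m$dst_start),
      dst_end = max(m$dst_start) + w,
      n_binsets = nrow(m), src_span = src_span,
      accepted = ok_n && ok_span, stringsAsFactors = FALSE)
    out$read_ids <- list(unique(unlist(m$read_ids)))
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!keep_rejected) out <- out[out$accepted, , drop = FALSE]
  out
}

empty_clusters <- function() {
  out <- data.frame(src_chrom = character(), src_start = integer(),
                    src_end = integer(), dst_chrom = character(),
                    dst_start = integer(), dst_end = integer(),
                    n_binsets = integer(), src_span = integer(),
                    accepted = logical(), stringsAsFactors = FALSE)
  out$read_ids <- list()
  out
}

#' Call structural variants from accepted binset clusters
#'
#' Each cluster's source/destination bounding regions become the two
#' breakpoint-flanking regions of a call. The symmetric construction
#' produces two mirror-image clusters per event; clusters sharing at least
#' `mirror_overlap` of their supporting reads (relative to the smaller
#' set) are merged into a single call. Interchromosomal calls are classed
#' immediately; intrachromosomal calls are provisionally
#' `intrachromosomal-other` until [classify_deletion()].
#'
#' @param clusters Accepted clusters from [cluster_binsets()].
#' @param cfg An [sv_config()].
#' @return SV call data.frame (`id`, `class`, regions, `support`,
#'   `read_ids` list column), sorted by coordinates.
#' @export
call_structural_variants <- function(clusters, cfg = sv_config()) {
  if (nrow(clusters) == 0L) return(empty_sv_calls_internal())
  n <- nrow(clusters)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (a in seq_len(n)) {
    for (b in seq_len(a - 1L)) {
      ra <- clusters$read_ids[[a]]; rb <- clusters$read_ids[[b]]
      ov <- length(intersect(ra, rb)) / min(length(ra), length(rb))
      if (ov >= cfg$mirror_overlap) {
        fa <- find(a); fb <- find(b)
        if (fa != fb) parent[fa] <- fb
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  rows <- lapply(unique(roots), function(r) {
    m <- clusters[roots == r, , drop = FALSE]
    # canonical orientation from the first cluster, regions ordered by
    # (chrom, start)
    a <- c(m$src_chrom[1], m$src_start[1], m$src_end[1])
    b <- c(m$dst_chrom[1], m$dst_start[1], m$dst_end[1])
    if (b[1] < a[1] || (b[1] == a[1] &&
                        as.integer(b[2]) < as.integer(a[2]))) {
      tmp <- a; a <- b; b <- tmp
    }
    ids <- unique(unlist(m$read_ids))
    out <- data.frame(
      class = if (a[1] != b[1]) "interchromosomal" else
        "intrachromosomal-other",
      chrom_a = a[1], start_a = as.integer(a[2]), end_a = as.integer(a[3]),
      chrom_b = b[1], start_b = as.integer(b[2]), end_b = as.integer(b[3]),
      support = length(ids), stringsAsFactors = FALSE)
    out$read_ids <- list(ids)
    out
  })
  calls <- do.call(rbind, rows)
  calls <- calls[order(calls$chrom_a, calls$start_a, calls$chrom_b,
                       calls$start_b), , drop = FALSE]
  calls <- cbind(id = sprintf("sv%03d", seq_len(nrow(calls))), calls,
                 stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  calls
}

empty_sv_calls_internal <- function() {
  out <- empty_sv_calls()
  out$read_ids <- list()
  out
}

#' Mean per-base read depth over an interval
#'
#' Depth counts each read's reference footprint (M and D CIGAR runs);
#' the mean over `[start, end)` is the summed overlap divided by the
#' interval length.
#'
#' @param reads Alignment data.frame (deduplicated; duplicate-flagged and
#'   unmapped records are ignored).
#' @param chrom,start,end Query interval, 0-based half-open.
#' @return Mean reads per base (numeric scalar).
#' @export
mean_depth <- function(reads, chrom, start, end) {
  if (end <= start) stop("mean_depth: empty interval")
  r <- reads[reads$mapped & !reads$duplicate & reads$chrom == chrom, ,
             drop = FALSE]
  if (nrow(r) == 0L) return(0)
  rs <- r$start
  re <- r$start + cigar_ref_len_fast(r$cigar)
  sum(overlap_width(rs, re, start, end)) / (end - start)
}

# Precompute per-chromosome footprints once; queries then reduce to a
# vectorised clipped-overlap sum.
depth_index <- function(reads) {
  r <- reads[reads$mapped & !reads$duplicate, , drop = FALSE]
  re <- r$start + cigar_ref_len_fast(r$cigar)
  split(data.frame(rs = r$start, re = re), r$chrom)
}

# cigar_ref_len for mostly-simple CIGARs without the per-element parser.
cigar_ref_len_fast <- function(cigar) {
  out <- integer(length(cigar))
  simple <- cigar_is_simple(cigar)
  out[simple] <- as.integer(sub("M$", "", cigar[simple]))
  if (any(!simple)) out[!simple] <- cigar_ref_len(cigar[!simple])
  out
}

indexed_depth <- function(idx, chrom, start, end) {
  d <- idx[[chrom]]
  if (is.null(d) || end <= start) return(0)
  sum(overlap_width(d$rs, d$re, start, end)) / (end - start)
}

#' Classify intrachromosomal calls as deletions by depth ratio
#'
#' For intrachromosomal calls whose interior (the gap between the two
#' breakpoint-flanking regions) is non-empty and shorter than
#' `max_deletion_size`, the interior mean depth is compared with the mean
#' of two `flank`-sized exterior windows (truncated at chromosome ends; if
#' one flank is empty the other is used alone). Ratio below
#' `complete_ratio` gives `deletion-complete`; between `complete_ratio`
#' and `het_ratio` (inclusive) gives `deletion-heterozygous`; otherwise
#' the call stays `intrachromosomal-other`.
#'
#' @param calls SV call data.frame from [call_structural_variants()].
#' @param reads Deduplicated alignment data.frame.
#' @param seq_lengths Named integer vector of chromosome lengths (defaults
#'   to the `seq_lengths` attribute of `reads`).
#' @param cfg An [sv_config()].
#' @return `calls` with final `class` and added `depth_ratio` column.
#' @export
classify_deletion <- function(calls, reads,
                              seq_lengths = attr(reads, "seq_lengths"),
                              cfg = sv_config()) {
  if (nrow(calls) == 0L) {
    calls$depth_ratio <- numeric(0)
    return(calls)
  }
  calls$depth_ratio <- NA_real_
  idx <- depth_index(reads)
  for (i in which(calls$class != "interchromosomal")) {
    cn <- calls$chrom_a[i]
    int_s <- calls$end_a[i]
    int_e <- calls$start_b[i]
    if (int_e <= int_s) next
    if (int_e - int_s >= cfg$max_deletion_size) next
    clen <- if (!is.null(seq_lengths)) seq_lengths[[cn]] else Inf
    lf_s <- max(0L, calls$start_a[i] - cfg$flank)
    lf_e <- calls$start_a[i]
    rf_s <- calls$end_b[i]
    rf_e <- as.integer(min(clen, calls$end_b[i] + cfg$flank))
    flanks <- c(if (lf_e > lf_s) indexed_depth(idx, cn, lf_s, lf_e),
                if (rf_e > rf_s) indexed_depth(idx, cn, rf_s, rf_e))
    if (length(flanks) == 0L || mean(flanks) == 0) next
    r <- indexed_depth(idx, cn, int_s, int_e) / mean(flanks)
    calls$depth_ratio[i] <- r
    if (r < cfg$complete_ratio) {
      calls$class[i] <- "deletion-complete"
    } else if (r <= cfg$het_ratio) {
      calls$class[i] <- "deletion-heterozygous"
    }
  }
  calls
}

#' Run the whole structural-variant caller
#'
#' Flags duplicates, classifies aberrant pairs, builds and clusters
#' binsets, calls events and classifies deletions.
#'
#' @param reads Alignment data.frame (duplicates may be unflagged; they are
#'   re-marked here).
#' @param cfg An [sv_config()].
#' @param pair_cfg An [aberrant_pair_config()].
#' @param seq_lengths Chromosome lengths (defaults to the attribute on
#'   `reads`).
#' @return SV call data.frame with final classes.
#' @export
detect_svs <- function(reads, cfg = sv_config(),
                       pair_cfg = aberrant_pair_config(),
                       seq_lengths = attr(reads, "seq_lengths")) {
  reads <- mark_duplicates(reads)
  pairs <- pair_reads(reads)
  pairs <- pairs[!pairs$duplicate, , drop = FALSE]
  ab <- pairs[is_aberrant(pairs, pair_cfg), , drop = FALSE]
  bs <- build_binsets(ab, cfg)
  cl <- cluster_binsets(bs, cfg)
  calls <- call_structural_variants(cl, cfg)
  classify_deletion(calls, reads, seq_lengths, cfg)
}
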