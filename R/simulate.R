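# Synthetic diploid genomes with planted variants and rearrangements.
#
# The simulator emits alignment OUTCOMES (mapped mate-pair records in
# reference coordinates), not raw reads: the aligner is outside the
# pipeline's scope, and every downstream stage consumes mapped records.
# Reads are error-free copies of the donor haplotype, so planted variants
# are the only source of mismatches.

#' Mate-pair library parameters
#'
#' Defaults reproduce the long-insert library the pipeline targets:
#' 2x50-base mate pairs with inserts of 1-2 kb (mean ~1.45 kb), 16.4%
#' duplicate pairs and a <1/40 chimera rate.
#'
#' @param read_length Read length in bases.
#' @param insert_mean,insert_sd Mean and SD of the truncated-normal insert
#'   size distribution, in bases.
#' @param insert_min,insert_max Truncation bounds of the insert size.
#' @param physical_coverage Per-haplotype clone coverage: the expected
#'   number of insert spans crossing each haplotype position. A diploid
#'   locus is spanned by about twice this many clones in reference
#'   coordinates.
#' @param duplicate_rate Fraction of emitted pairs that are exact positional
#'   copies of another pair (PCR duplicate model).
#' @param chimera_rate Fraction of pairs whose second end is placed
#'   uniformly at random (library chimerism model).
#' @return A list of class `library_params`.
#' @export
library_params <- function(read_length = 50L, insert_mean = 1450,
                           insert_sd = 150, insert_min = 1000L,
                           insert_max = 2000L, physical_coverage = 30,
                           duplicate_rate = 0.164, chimera_rate = 0.025) {
  stopifnot(insert_min <= insert_mean, insert_mean <= insert_max,
            read_length >= 1L, duplicate_rate >= 0, duplicate_rate < 1,
            chimera_rate >= 0, chimera_rate <= 1)
  structure(list(read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 insert_min = as.integer(insert_min),
                 insert_max = as.integer(insert_max),
                 physical_coverage = physical_coverage,
                 duplicate_rate = duplicate_rate,
                 chimera_rate = chimera_rate),
            class = "library_params")
}

#' Small-variant planting rates
#'
#' @param theta_snv Heterozygous SNVs per base pair (diversity).
#' @param theta_indel Heterozygous indels per base pair.
#' @param hom_fraction Fraction of planted variants made homozygous.
#' @param max_indel_len Maximum indel length in bases (at most 20).
#' @param ts_fraction Probability that a planted SNV is a transition.
#' @return A list of class `variant_rates`.
#' @export
variant_rates <- function(theta_snv = 4.4e-4, theta_indel = 0.38e-4,
                          hom_fraction = 0.5, max_indel_len = 20L,
                          ts_fraction = 0.674) {
  stopifnot(theta_snv >= 0, theta_indel >= 0,
            hom_fraction >= 0, hom_fraction <= 1,
            max_indel_len >= 1L, max_indel_len <= 20L)
  structure(list(theta_snv = theta_snv, theta_indel = theta_indel,
                 hom_fraction = hom_fraction,
                 max_indel_len = as.integer(max_indel_len),
                 ts_fraction = ts_fraction),
            class = "variant_rates")
}

#' Generate a random reference genome
#'
#' @param lengths Integer vector of chromosome lengths; names become
#'   sequence names (defaults `chr1`, `chr2`, ...).
#' @param gc GC fraction of the generated sequence.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return Named character vector of sequences.
#' @export
generate_reference <- function(lengths, gc = 0.41, seed = 1L) {
  nm <- names(lengths)
  lengths <- as.integer(lengths)
  names(lengths) <- nm
  if (any(lengths < 1L)) stop("generate_reference: zero-length chromosome")
  if (is.null(names(lengths))) {
    names(lengths) <- paste0("chr", seq_along(lengths))
  }
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  codes <- as.raw(c(65L, 67L, 71L, 84L))  # A C G T
  ref <- vapply(lengths, function(L) {
    rawToChar(codes[sample.int(4L, L, replace = TRUE, prob = probs)])
  }, character(1))
  names(ref) <- names(lengths)
  ref
}

## ------------------------------------------------------ donor haplotypes

# A donor is the reference plus two edited haplotypes. Each haplotype
# chromosome stores its sequence, a per-base map back to reference
# coordinates (NA for inserted bases), and a segment table giving the
# reference chromosome of each donor segment (>1 segment only after a
# translocation).
new_donor_chrom <- function(seq, map, seg_starts, seg_chrom) {
  list(seq = seq, map = map, seg_starts = seg_starts, seg_chrom = seg_chrom)
}

donor_from_reference <- function(ref) {
  haps <- lapply(1:2, function(h) {
    out <- lapply(names(ref), function(cn) {
      new_donor_chrom(ref[[cn]], 0:(nchar(ref[[cn]]) - 1L), 0L, cn)
    })
    names(out) <- names(ref)
    out
  })
  structure(list(reference = ref, haplotypes = haps), class = "donor")
}

#' Plant heterozygous and homozygous small variants into a diploid donor
#'
#' SNV and indel counts are binomial draws at the configured per-bp rates
#' (`theta_*` govern the heterozygous counts; homozygous counts are scaled
#' by `hom_fraction/(1-hom_fraction)`, or replace the het draw entirely
#' when `hom_fraction = 1`). Indel lengths are drawn with weight
#' `len^-1.5`; when gene models are supplied, indels falling in coding
#' exons are frame-preserving (length a multiple of 3) with probability
#' `coding_frame_bias` and other indels with probability
#' `noncoding_frame_bias`. Variants are never planted on N bases and are
#' spaced so they cannot collide.
#'
#' @param ref Named character vector of reference sequences.
#' @param rates A [variant_rates()] object.
#' @param seed Integer seed.
#' @param genes Optional gene-model data.frame used for the coding frame
#'   bias.
#' @param coding_frame_bias,noncoding_frame_bias Probability that an indel
#'   length is a multiple of 3 in coding exons / elsewhere.
#' @param extra_variants Optional data.frame of variants to plant verbatim
#'   (columns `chrom`, `pos`, `ref`, `alt`, `vtype`, `zygosity`).
#' @return A list with elements `donor` (the edited diploid genome) and
#'   `truth` (data.frame of planted variants in reference coordinates).
#' @export
plant_small_variants <- function(ref, rates = variant_rates(), seed = 1L,
                                 genes = NULL,
                                 coding_frame_bias = 0.27,
                                 noncoding_frame_bias = 0.108,
                                 extra_variants = NULL) {
  set.seed(seed)
  L_tot <- sum(nchar(ref))
  counts <- function(theta) {
    hf <- rates$hom_fraction
    if (hf >= 1) {
      c(het = 0L, hom = stats::rbinom(1L, L_tot, min(theta, 1)))
    } else {
      c(het = stats::rbinom(1L, L_tot, min(theta, 1)),
        hom = stats::rbinom(1L, L_tot, min(theta * hf / (1 - hf), 1)))
    }
  }
  n_snv <- counts(rates$theta_snv)
  n_ind <- counts(rates$theta_indel)
  truth <- draw_small_variants(ref, n_snv, n_ind, rates, genes,
                               coding_frame_bias, noncoding_frame_bias)
  if (!is.null(extra_variants)) {
    cols <- c("chrom", "pos", "ref", "alt", "vtype", "zygosity")
    extra <- extra_variants[, cols, drop = FALSE]
    extra$pos <- as.integer(extra$pos)
    truth <- rbind(truth, extra)
  }
  truth <- truth[order(truth$chrom, truth$pos), , drop = FALSE]
  rownames(truth) <- NULL
  # haplotype assignment: hom on both, het on one chosen at random
  truth$hap1 <- truth$zygosity == "hom"
  truth$hap2 <- truth$zygosity == "hom"
  het <- which(truth$zygosity == "het")
  pick <- stats::runif(length(het)) < 0.5
  truth$hap1[het[pick]] <- TRUE
  truth$hap2[het[!pick]] <- TRUE
  donor <- donor_from_reference(ref)
  for (h in 1:2) {
    hv <- truth[truth[[paste0("hap", h)]], , drop = FALSE]
    for (cn in unique(hv$chrom)) {
      cv <- hv[hv$chrom == cn, , drop = FALSE]
      donor$haplotypes[[h]][[cn]] <-
        apply_small_variants_chrom(donor$haplotypes[[h]][[cn]], cv)
    }
  }
  list(donor = donor, truth = truth[, c("chrom", "pos", "ref", "alt",
                                        "vtype", "zygosity", "hap1", "hap2")])
}

draw_small_variants <- function(ref, n_snv, n_ind, rates, genes,
                                coding_frame_bias, noncoding_frame_bias) {
  n_total <- sum(n_snv) + sum(n_ind)
  if (n_total == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      vtype = character(), zygosity = character(),
                      stringsAsFactors = FALSE))
  }
  lens <- nchar(ref)
  # sample candidate positions genome-wide, enforce spacing, drop Ns.
  # Spacing exceeds a read window plus the largest indel so no single read
  # ever carries two planted variants.
  spacing <- 50L + rates$max_indel_len + 10L
  n_try <- 0L
  repeat {
    n_try <- n_try + 1L
    n_cand <- max(4L * n_total * n_try, n_total + 50L)
    chrom_i <- sample.int(length(ref), n_cand, replace = TRUE,
                          prob = lens / sum(lens))
    pos <- floor(stats::runif(n_cand) * (lens[chrom_i] - spacing))
    o <- order(chrom_i, pos)
    chrom_i <- chrom_i[o]; pos <- as.integer(pos[o])
    same <- c(FALSE, diff(chrom_i) == 0L)
    keep <- !(same & c(FALSE, diff(pos) < spacing))
    # greedy pass: recompute after dropping (one pass is enough in practice)
    chrom_i <- chrom_i[keep]; pos <- pos[keep]
    ok <- !vapply(seq_along(pos), function(i) {
      grepl("N", substr(ref[[chrom_i[i]]], pos[i] + 1L,
                        pos[i] + spacing), fixed = TRUE)
    }, logical(1))
    chrom_i <- chrom_i[ok]; pos <- pos[ok]
    if (length(pos) >= n_total) break
    if (n_try >= 10L) stop("plant_small_variants: variant rate too high ",
                           "for genome size (could not place variants)")
  }
  sel <- sort(sample.int(length(pos), n_total))
  chrom_i <- chrom_i[sel]; pos <- pos[sel]
  vtype <- sample(rep(c("SNV", "INS", "DEL", "SNV"),
                      c(n_snv["het"], ceiling(sum(n_ind) / 2),
                        floor(sum(n_ind) / 2), n_snv["hom"])))
  zyg_pool <- c(rep("het", n_snv["het"]), rep("hom", n_snv["hom"]))
  # assign zygosity within type so configured het/hom counts are honoured
  zygosity <- character(n_total)
  zygosity[vtype == "SNV"] <- sample(zyg_pool)
  ind_idx <- which(vtype != "SNV")
  zygosity[ind_idx] <- sample(c(rep("het", n_ind["het"]),
                                rep("hom", n_ind["hom"])))[seq_along(ind_idx)]
  chrom <- names(ref)[chrom_i]
  ref_allele <- alt_allele <- character(n_total)
  coding <- if (is.null(genes)) rep(FALSE, n_total) else {
    in_coding_exon(chrom, pos, genes)
  }
  for (i in seq_len(n_total)) {
    base <- substr(ref[[chrom_i[i]]], pos[i] + 1L, pos[i] + 1L)
    if (vtype[i] == "SNV") {
      ref_allele[i] <- base
      alt_allele[i] <- draw_alt_base(base, rates$ts_fraction)
    } else {
      p3 <- if (coding[i]) coding_frame_bias else noncoding_frame_bias
      len <- draw_indel_len(rates$max_indel_len, p3)
      if (vtype[i] == "DEL") {
        ref_allele[i] <- substr(ref[[chrom_i[i]]], pos[i] + 1L, pos[i] + len)
        alt_allele[i] <- "-"
      } else {
        ref_allele[i] <- "-"
        alt_allele[i] <- rawToChar(as.raw(c(65L, 67L, 71L, 84L))[
          sample.int(4L, len, replace = TRUE)])
      }
    }
  }
  data.frame(chrom = chrom, pos = pos, ref = ref_allele, alt = alt_allele,
             vtype = vtype, zygosity = zygosity, stringsAsFactors = FALSE)
}

transition_partner <- c(A = "G", G = "A", C = "T", T = "C")

draw_alt_base <- function(base, ts_fraction) {
  if (stats::runif(1) < ts_fraction) {
    transition_partner[[base]]
  } else {
    sample(setdiff(c("A", "C", "G", "T"),
                   c(base, transition_partner[[base]])), 1L)
  }
}

draw_indel_len <- function(max_len, p3) {
  lens <- seq_len(max_len)
  mult3 <- lens %% 3L == 0L
  if (any(mult3) && stats::runif(1) < p3) {
    pool <- lens[mult3]
  } else {
    pool <- lens[!mult3]
  }
  w <- pool^-1.5
  pool[sample.int(length(pool), 1L, prob = w / sum(w))]
}

in_coding_exon <- function(chrom, pos, genes) {
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(genes))) {
    es <- pmax(genes$exon_starts[[i]], genes$cds_start[i])
    ee <- pmin(genes$exon_ends[[i]], genes$cds_end[i])
    keep <- es < ee
    es <- es[keep]; ee <- ee[keep]
    on_chrom <- chrom == genes$chrom[i]
    if (!any(on_chrom) || length(es) == 0L) next
    hit <- vapply(pos[on_chrom], function(p) any(p >= es & p < ee),
                  logical(1))
    out[on_chrom] <- out[on_chrom] | hit
  }
  out
}

# Apply sorted small variants on one chromosome; returns a donor chromosome
# with an updated reference-coordinate map.
apply_small_variants_chrom <- function(dchrom, vars) {
  vars <- vars[order(vars$pos), , drop = FALSE]
  raw <- charToRaw(dchrom$seq)
  map <- dchrom$map
  n <- length(raw)
  chunks_seq <- vector("list", 2L * nrow(vars) + 1L)
  chunks_map <- vector("list", 2L * nrow(vars) + 1L)
  cur <- 0L; k <- 0L
  for (i in seq_len(nrow(vars))) {
    pos <- vars$pos[i]
    if (pos > cur) {
      k <- k + 1L
      chunks_seq[[k]] <- raw[(cur + 1L):pos]
      chunks_map[[k]] <- map[(cur + 1L):pos]
    }
    if (vars$vtype[i] == "SNV") {
      k <- k + 1L
      chunks_seq[[k]] <- charToRaw(vars$alt[i])
      chunks_map[[k]] <- map[pos + 1L]
      cur <- pos + 1L
    } else if (vars$vtype[i] == "DEL") {
      cur <- pos + nchar(vars$ref[i])
    } else {  # INS: inserted before the base at pos
      k <- k + 1L
      chunks_seq[[k]] <- charToRaw(vars$alt[i])
      chunks_map[[k]] <- rep(NA_integer_, nchar(vars$alt[i]))
      cur <- pos
    }
  }
  if (cur < n) {
    k <- k + 1L
    chunks_seq[[k]] <- raw[(cur + 1L):n]
    chunks_map[[k]] <- map[(cur + 1L):n]
  }
  new_donor_chrom(rawToChar(unlist(chunks_seq[seq_len(k)])),
                  as.integer(unlist(chunks_map[seq_len(k)])),
                  dchrom$seg_starts, dchrom$seg_chrom)
}

## ------------------------------------------------- structural variants

#' Specify structural events to plant
#'
#' @param class One of `"deletion-complete"`, `"deletion-heterozygous"`,
#'   `"translocation"` per event.
#' @param chrom,start,end Deleted interval (reference coordinates) for
#'   deletions; for translocations `chrom`/`start` give breakend A (the
#'   donor keeps `chrom[0, start)`).
#' @param chrom_b,pos_b Breakend B for translocations (the donor keeps
#'   `chrom_b[pos_b, end)`); NA for deletions.
#' @return Data.frame of class `sv_spec`.
#' @export
sv_spec <- function(class, chrom, start, end = NA_integer_,
                    chrom_b = NA_character_, pos_b = NA_integer_) {
  out <- data.frame(class = class, chrom = chrom, start = as.integer(start),
                    end = as.integer(end), chrom_b = chrom_b,
                    pos_b = as.integer(pos_b), stringsAsFactors = FALSE)
  bad <- !out$class %in% c("deletion-complete", "deletion-heterozygous",
                           "translocation")
  if (any(bad)) stop("sv_spec: unknown class ", out$class[bad][1])
  del <- grepl("^deletion", out$class)
  if (any(del & (is.na(out$end) | out$end <= out$start))) {
    stop("sv_spec: deletions need end > start")
  }
  if (any(!del & (is.na(out$chrom_b) | is.na(out$pos_b)))) {
    stop("sv_spec: translocations need chrom_b and pos_b")
  }
  class(out) <- c("sv_spec", "data.frame")
  out
}

#' Plant structural events into a donor genome
#'
#' Complete deletions are removed from both haplotypes, heterozygous
#' deletions from exactly one (chosen at random), and each translocation
#' replaces haplotype 1's two partner chromosomes with the fused derivative
#' `chromA[0, start) + chromB[pos_b, end)` plus the truncated
#' `chromB[0, pos_b)`.
#'
#' @param planted Result of [plant_small_variants()] (or a bare `donor`).
#' @param spec An [sv_spec()] data.frame; events must not overlap.
#' @param seed Integer seed (haplotype choice for het deletions).
#' @return A list with `donor` (rearranged) and `truth` (data.frame of
#'   breakends in reference coordinates: `class`, `chrom_a`, `pos_a`,
#'   `chrom_b`, `pos_b`).
#' @export
plant_structural_variants <- function(planted, spec, seed = 1L) {
  donor <- if (inherits(planted, "donor")) planted else planted$donor
  set.seed(seed)
  validate_sv_spec(spec, donor$reference)
  del <- spec[grepl("^deletion", spec$class), , drop = FALSE]
  tra <- spec[spec$class == "translocation", , drop = FALSE]
  truth <- data.frame(class = character(), chrom_a = character(),
                      pos_a = integer(), chrom_b = character(),
                      pos_b = integer(), stringsAsFactors = FALSE)
  if (nrow(del)) {
    del <- del[order(del$chrom, -del$start), , drop = FALSE]
    hap_choice <- sample(1:2, nrow(del), replace = TRUE)
    for (i in seq_len(nrow(del))) {
      haps <- if (del$class[i] == "deletion-complete") 1:2 else hap_choice[i]
      for (h in haps) {
        donor$haplotypes[[h]][[del$chrom[i]]] <- delete_ref_range(
          donor$haplotypes[[h]][[del$chrom[i]]], del$start[i], del$end[i])
      }
    }
    truth <- rbind(truth, data.frame(
      class = del$class, chrom_a = del$chrom, pos_a = del$start,
      chrom_b = del$chrom, pos_b = del$end, stringsAsFactors = FALSE))
  }
  for (i in seq_len(nrow(tra))) {
    donor <- apply_translocation(donor, tra$chrom[i], tra$start[i],
                                 tra$chrom_b[i], tra$pos_b[i])
  }
  if (nrow(tra)) {
    truth <- rbind(truth, data.frame(
      class = "interchromosomal", chrom_a = tra$chrom, pos_a = tra$start,
      chrom_b = tra$chrom_b, pos_b = tra$pos_b, stringsAsFactors = FALSE))
  }
  list(donor = donor, truth = truth)
}

validate_sv_spec <- function(spec, ref) {
  ends <- ifelse(grepl("^deletion", spec$class), spec$end, spec$start)
  if (any(!spec$chrom %in% names(ref)) ||
      any(spec$start < 0L) || any(ends > nchar(ref[spec$chrom]))) {
    stop("plant_structural_variants: event outside chromosome bounds")
  }
  del <- spec[grepl("^deletion", spec$class), , drop = FALSE]
  if (nrow(del) > 1L) {
    o <- order(del$chrom, del$start)
    same <- diff(match(del$chrom[o], unique(del$chrom))) == 0L
    if (any(same & del$start[o][-1] < del$end[o][-nrow(del)])) {
      stop("plant_structural_variants: overlapping planted events")
    }
  }
}

delete_ref_range <- function(dchrom, start, end) {
  idx <- which(!is.na(dchrom$map) & dchrom$map >= start & dchrom$map < end)
  if (length(idx) == 0L) return(dchrom)
  raw <- charToRaw(dchrom$seq)[-idx]
  new_donor_chrom(rawToChar(raw), dchrom$map[-idx],
                  dchrom$seg_starts, dchrom$seg_chrom)
}

apply_translocation <- function(donor, chrom_a, pos_a, chrom_b, pos_b) {
  h <- 1L
  da <- donor$haplotypes[[h]][[chrom_a]]
  db <- donor$haplotypes[[h]][[chrom_b]]
  if (is.null(da) || is.null(db) || length(da$seg_chrom) > 1L ||
      length(db$seg_chrom) > 1L) {
    stop("apply_translocation: partner chromosome already rearranged")
  }
  ia <- match(TRUE, !is.na(da$map) & da$map >= pos_a)  # first donor base kept out
  ib <- match(TRUE, !is.na(db$map) & db$map >= pos_b)  # first donor base kept in
  if (is.na(ib)) stop("apply_translocation: breakend B beyond sequence")
  prefix_len <- if (is.na(ia)) nchar(da$seq) else ia - 1L
  der_seq <- paste0(substr(da$seq, 1L, prefix_len),
                    substr(db$seq, ib, nchar(db$seq)))
  der_map <- c(da$map[seq_len(prefix_len)],
               db$map[ib:length(db$map)])
  der <- new_donor_chrom(der_seq, der_map,
                         c(0L, prefix_len), c(chrom_a, chrom_b))
  trunc_b <- new_donor_chrom(substr(db$seq, 1L, ib - 1L),
                             db$map[seq_len(ib - 1L)], 0L, chrom_b)
  donor$haplotypes[[h]][[chrom_a]] <- NULL
  donor$haplotypes[[h]][[chrom_b]] <- NULL
  donor$haplotypes[[h]][[paste0("der_", chrom_a, "_", chrom_b)]] <- der
  donor$haplotypes[[h]][[paste0("trunc_", chrom_b)]] <- trunc_b
  donor
}

## -------------------------------------------------------- read sampling

#' Simulate mapped mate-pair reads from a donor genome
#'
#' Insert lengths follow a truncated normal on
#' `[insert_min, insert_max]`; both ends are 50-base (by default) windows
#' at the insert's extremes, mapped back to reference coordinates through
#' the donor's coordinate maps. Pairs whose end overlaps a breakend
#' junction are dropped (a real aligner would leave them unmapped); pairs
#' straddling a junction between their ends map with aberrant separation
#' or to two chromosomes. A `duplicate_rate` fraction of emitted pairs are
#' positional copies; a `chimera_rate` fraction get a uniformly random
#' second end.
#'
#' @param donor A donor genome (from [plant_small_variants()] /
#'   [plant_structural_variants()], or their `$donor` element).
#' @param lib A [library_params()] object.
#' @param seed Integer seed.
#' @return Alignment data.frame (see [read_alignments()]) with a
#'   `seq_lengths` attribute for SAM output.
#' @export
simulate_mate_pairs <- function(donor, lib = library_params(), seed = 1L) {
  if (!inherits(donor, "donor")) donor <- donor$donor
  set.seed(seed)
  rl <- lib$read_length
  ref <- donor$reference
  ref_len <- nchar(ref)
  entries <- list()
  for (h in 1:2) {
    for (cn in names(donor$haplotypes[[h]])) {
      dc <- donor$haplotypes[[h]][[cn]]
      if (nchar(dc$seq) >= lib$insert_max) {
        entries[[length(entries) + 1L]] <- prep_entry(dc)
      }
    }
  }
  if (length(entries) == 0L) {
    stop("simulate_mate_pairs: no donor chromosome reaches insert_max")
  }
  ent_len <- vapply(entries, function(e) e$len, numeric(1))
  # physical_coverage is per-haplotype clone coverage: every haplotype
  # locus is spanned by ~physical_coverage inserts, so a diploid locus
  # sees about twice that many clones in reference coordinates
  n_pairs <- round(lib$physical_coverage * sum(ent_len) / lib$insert_mean)
  ent_i <- sample.int(length(entries), n_pairs, replace = TRUE,
                      prob = ent_len / sum(ent_len))
  insert <- round(rtruncnorm(n_pairs, lib$insert_mean, lib$insert_sd,
                             lib$insert_min, lib$insert_max))
  p <- floor(stats::runif(n_pairs) * (ent_len[ent_i] - insert))
  chim <- stats::runif(n_pairs) < lib$chimera_rate
  end1 <- resolve_ends(entries, ent_i, as.integer(p), rl)
  end2 <- resolve_ends(entries, ent_i, as.integer(p + insert - rl), rl)
  # chimeric pairs: second end uniform on the reference
  if (any(chim)) {
    ci <- which(chim)
    cc <- sample.int(length(ref), length(ci), replace = TRUE,
                     prob = ref_len / sum(ref_len))
    cp <- as.integer(floor(stats::runif(length(ci)) * (ref_len[cc] - rl)))
    end2$chrom[ci] <- names(ref)[cc]
    end2$start[ci] <- cp
    end2$cigar[ci] <- paste0(rl, "M")
    end2$seq[ci] <- substring(ref[cc], cp + 1L, cp + rl)
    end2$ok[ci] <- TRUE
  }
  keep <- end1$ok & end2$ok
  pairs <- data.frame(chrom1 = end1$chrom[keep], start1 = end1$start[keep],
                      cigar1 = end1$cigar[keep], seq1 = end1$seq[keep],
                      chrom2 = end2$chrom[keep], start2 = end2$start[keep],
                      cigar2 = end2$cigar[keep], seq2 = end2$seq[keep],
                      stringsAsFactors = FALSE)
  n_u <- nrow(pairs)
  n_dup <- round(n_u * lib$duplicate_rate / (1 - lib$duplicate_rate))
  if (n_dup > 0L) {
    src <- sample.int(n_u, n_dup, replace = TRUE)
    pairs <- rbind(pairs, pairs[src, , drop = FALSE])
  }
  n <- nrow(pairs)
  ids <- sprintf("p%08d", seq_len(n))
  reads <- data.frame(
    read_id = rep(ids, each = 2L),
    chrom = as.vector(rbind(pairs$chrom1, pairs$chrom2)),
    start = as.vector(rbind(pairs$start1, pairs$start2)),
    strand = rep(c("+", "-"), n),
    cigar = as.vector(rbind(pairs$cigar1, pairs$cigar2)),
    seq = as.vector(rbind(pairs$seq1, pairs$seq2)),
    mate_chrom = as.vector(rbind(pairs$chrom2, pairs$chrom1)),
    mate_start = as.vector(rbind(pairs$start2, pairs$start1)),
    mate_strand = rep(c("-", "+"), n),
    mapped = TRUE, mate_mapped = TRUE, paired = TRUE,
    first_in_pair = rep(c(TRUE, FALSE), n),
    duplicate = FALSE,
    stringsAsFactors = FALSE
  )
  attr(reads, "seq_lengths") <- stats::setNames(as.integer(ref_len),
                                                names(ref))
  reads
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

prep_entry <- function(dc) {
  map <- dc$map
  n <- length(map)
  # discontinuity between donor bases i and i+1 (1-based): insertion edge,
  # non-unit reference jump, or a segment boundary
  d <- is.na(map[-n]) | is.na(map[-1L]) | (map[-1L] != map[-n] + 1L)
  if (length(dc$seg_starts) > 1L) {
    d[dc$seg_starts[-1L]] <- TRUE  # donor offset s: boundary between s and s+1
  }
  list(seq = dc$seq, map = map, csum = c(0L, cumsum(d)),
       seg_starts = dc$seg_starts, seg_chrom = dc$seg_chrom, len = n)
}

# Map read windows [p, p+rl) (0-based donor offsets, parallel vectors
# ent_i/p) back to reference coordinates.
resolve_ends <- function(entries, ent_i, p, rl) {
  n <- length(p)
  chrom <- character(n); start <- integer(n)
  cigar <- character(n); seqs <- character(n); ok <- logical(n)
  for (e in unique(ent_i)) {
    idx <- which(ent_i == e)
    en <- entries[[e]]
    pe <- p[idx]
    seqs[idx] <- substring(en$seq, pe + 1L, pe + rl)
    # discontinuities strictly inside the window
    special <- (en$csum[pe + rl] - en$csum[pe + 1L]) > 0L
    si <- idx[!special]
    pe_s <- pe[!special]
    seg <- findInterval(pe_s, en$seg_starts)
    chrom[si] <- en$seg_chrom[seg]
    start[si] <- en$map[pe_s + 1L]
    cigar[si] <- paste0(rl, "M")
    ok[si] <- TRUE
    for (j in which(special)) {
      w <- walk_window(en, pe[j], rl)
      if (!is.null(w)) {
        k <- idx[j]
        chrom[k] <- w$chrom; start[k] <- w$start; cigar[k] <- w$cigar
        ok[k] <- TRUE
      }
    }
  }
  list(chrom = chrom, start = start, cigar = cigar, seq = seqs, ok = ok)
}

# Derive the CIGAR of a donor window containing small-variant edits.
# Returns NULL (drop the read) when the window crosses a segment boundary
# or a reference jump too large to be a small indel.
walk_window <- function(en, p, rl, max_jump = 20L) {
  r <- en$map[(p + 1L):(p + rl)]
  seg <- findInterval(c(p, p + rl - 1L), en$seg_starts)
  if (seg[1] != seg[2]) return(NULL)
  lens <- integer(0); ops <- character(0)
  i <- 1L
  first_ref <- NA_integer_
  while (i <= rl) {
    if (is.na(r[i])) {
      j <- i
      while (j < rl && is.na(r[j + 1L])) j <- j + 1L
      # insertions at the very start/end of a read have no anchor; the
      # aligner would soft-clip them — drop such windows
      if (i == 1L || j == rl) return(NULL)
      lens <- c(lens, j - i + 1L); ops <- c(ops, "I")
      i <- j + 1L
    } else {
      if (is.na(first_ref)) first_ref <- r[i]
      j <- i
      while (j < rl && !is.na(r[j + 1L]) && r[j + 1L] == r[j] + 1L) {
        j <- j + 1L
      }
      lens <- c(lens, j - i + 1L); ops <- c(ops, "M")
      if (j < rl && !is.na(r[j + 1L])) {
        jump <- r[j + 1L] - r[j] - 1L
        if (jump < 1L || jump > max_jump) return(NULL)
        lens <- c(lens, jump); ops <- c(ops, "D")
      }
      i <- j + 1L
    }
  }
  # merge adjacent same-op runs (I next to D boundaries can split M runs)
  keep_l <- integer(0); keep_o <- character(0)
  for (k in seq_along(ops)) {
    if (k > 1L && ops[k] == keep_o[length(keep_o)]) {
      keep_l[length(keep_l)] <- keep_l[length(keep_l)] + lens[k]
    } else {
      keep_l <- c(keep_l, lens[k]); keep_o <- c(keep_o, ops[k])
    }
  }
  list(chrom = en$seg_chrom[findInterval(p, en$seg_starts)],
       start = first_ref, cigar = runs_to_cigar(keep_l, keep_o))
}

## ----------------------------------------------------------- gene models

#' Generate gene models consistent with a reference
#'
#' Places non-overlapping multi-exon genes on both strands and edits the
#' handful of reference bases needed so every model's coding sequence
#' begins with ATG, ends with a stop codon and contains no internal stop
#' (random sequence would otherwise terminate most open reading frames
#' within ~20 codons). The edited reference is therefore returned alongside
#' the models.
#'
#' @param ref Named character vector of reference sequences.
#' @param n_genes Number of genes to place.
#' @param seed Integer seed.
#' @param tx_len_range,n_exon_range Ranges for transcript length (bases)
#'   and exon count.
#' @return A list with `reference` (edited) and `genes` (model data.frame).
#' @export
generate_gene_models <- function(ref, n_genes, seed = 1L,
                                 tx_len_range = c(1500L, 4000L),
                                 n_exon_range = c(2L, 4L)) {
  set.seed(seed)
  if (n_genes == 0L) {
    return(list(reference = ref, genes = empty_gene_models()))
  }
  lens <- nchar(ref)
  occupied <- lapply(ref, function(x) cbind(start = integer(0),
                                            end = integer(0)))
  rows <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    placed <- FALSE
    for (try in 1:200) {
      ci <- sample.int(length(ref), 1L, prob = lens / sum(lens))
      tx_len <- sample(tx_len_range[1]:tx_len_range[2], 1L)
      if (lens[ci] < tx_len + 200L) next
      tx_start <- sample.int(lens[ci] - tx_len, 1L) - 1L
      occ <- occupied[[ci]]
      if (any(overlap_width(tx_start - 2000L, tx_start + tx_len + 2000L,
                            occ[, 1], occ[, 2]) > 0L)) next
      model <- build_gene_model(sprintf("gene%04d", g), names(ref)[ci],
                                tx_start, tx_len,
                                sample(n_exon_range[1]:n_exon_range[2], 1L))
      if (is.null(model)) next
      occupied[[ci]] <- rbind(occ, c(tx_start, tx_start + tx_len))
      rows[[g]] <- model
      placed <- TRUE
      break
    }
    if (!placed) stop("generate_gene_models: genome too small to place ",
                      n_genes, " genes")
  }
  genes <- do.call(rbind, rows)
  genes$exon_starts <- lapply(rows, function(r) r$exon_starts[[1]])
  genes$exon_ends <- lapply(rows, function(r) r$exon_ends[[1]])
  ref <- edit_reference_for_genes(ref, genes)
  validate_gene_models(genes)
  list(reference = ref, genes = genes)
}

empty_gene_models <- function() {
  g <- data.frame(name = character(), symbol = character(),
                  chrom = character(), strand = character(),
                  tx_start = integer(), tx_end = integer(),
                  cds_start = integer(), cds_end = integer(),
                  stringsAsFactors = FALSE)
  g$exon_starts <- list(); g$exon_ends <- list()
  g
}

build_gene_model <- function(name, chrom, tx_start, tx_len, n_exons) {
  strand <- sample(c("+", "-"), 1L)
  # partition the transcript into exons separated by >= 100-base introns
  exon_w <- sample(150:400, n_exons, replace = TRUE)
  intron_w <- sample(100:500, n_exons - 1L, replace = TRUE)
  need <- sum(exon_w) + sum(intron_w)
  if (need > tx_len) return(NULL)
  starts <- tx_start + cumsum(c(0L, exon_w[-n_exons] + intron_w))
  ends <- starts + exon_w
  # CDS: trim a UTR margin off the first and last exon, then round the
  # coding length down to a codon multiple by moving cds_end
  utr5 <- sample(20:60, 1L); utr3 <- sample(20:60, 1L)
  cds_start <- starts[1] + utr5
  cds_end <- ends[n_exons] - utr3
  if (cds_end - cds_start < 120L) return(NULL)
  clen <- sum(overlap_width(starts, ends, cds_start, cds_end))
  cds_end <- cds_end - clen %% 3L
  if (cds_end <= cds_start) return(NULL)
  out <- data.frame(name = name, symbol = toupper(name), chrom = chrom,
                    strand = strand, tx_start = tx_start,
                    tx_end = tx_start + tx_len,
                    cds_start = cds_start, cds_end = cds_end,
                    stringsAsFactors = FALSE)
  out$exon_starts <- list(as.integer(starts))
  out$exon_ends <- list(as.integer(ends))
  out
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Genomic positions of the CDS in translation order (strand-aware).
coding_positions <- function(gene) {
  es <- pmax(gene$exon_starts[[1]], gene$cds_start)
  ee <- pmin(gene$exon_ends[[1]], gene$cds_end)
  keep <- es < ee
  pos <- unlist(lapply(which(keep), function(i) es[i]:(ee[i] - 1L)))
  if (gene$strand == "-") rev(pos) else pos
}

edit_reference_for_genes <- function(ref, genes) {
  raws <- lapply(ref, charToRaw)
  stops <- c("TAA", "TAG", "TGA")
  for (i in seq_len(nrow(genes))) {
    gene <- genes[i, , drop = FALSE]
    cp <- coding_positions(gene)
    cn <- gene$chrom
    minus <- gene$strand == "-"
    get_codon <- function(k) {
      b <- rawToChar(raws[[cn]][cp[(3 * k - 2):(3 * k)] + 1L])
      if (minus) chartr("ACGT", "TGCA", b) else b
    }
    set_codon <- function(k, codon) {
      b <- strsplit(if (minus) chartr("ACGT", "TGCA", codon) else codon,
                    "")[[1]]
      raws[[cn]][cp[(3 * k - 2):(3 * k)] + 1L] <<- charToRaw(paste(b,
                                                            collapse = ""))
    }
    n_codon <- length(cp) %/% 3L
    set_codon(1L, "ATG")
    set_codon(n_codon, "TAA")
    for (k in 2:(n_codon - 1L)) {
      if (get_codon(k) %in% stops) {
        # recode the stop as serine (TCx is never a stop)
        cd <- get_codon(k)
        substr(cd, 2, 2) <- "C"
        set_codon(k, cd)
      }
    }
  }
  out <- vapply(raws, rawToChar, character(1))
  names(out) <- names(ref)
  out
}

## ------------------------------------------------------------ end-to-end

#' Simulate a full synthetic study: reference, genes, variants, SVs, reads
#'
#' Convenience wrapper chaining [generate_reference()],
#' [generate_gene_models()], [plant_small_variants()],
#' [plant_structural_variants()] and [simulate_mate_pairs()].
#'
#' @param lengths Chromosome lengths for [generate_reference()].
#' @param n_genes Number of gene models to place.
#' @param rates A [variant_rates()] object.
#' @param lib A [library_params()] object.
#' @param spec Optional [sv_spec()] of structural events.
#' @param seed Integer seed controlling every stage.
#' @param gc GC fraction of the reference.
#' @return A list with `reference`, `genes`, `donor`, `reads`,
#'   `truth_small`, `truth_sv`.
#' @export
simulate_genome <- function(lengths, n_genes = 0L, rates = variant_rates(),
                            lib = library_params(), spec = NULL, seed = 1L,
                            gc = 0.41) {
  ref <- generate_reference(lengths, gc = gc, seed = seed)
  genes <- empty_gene_models()
  if (n_genes > 0L) {
    gm <- generate_gene_models(ref, n_genes, seed = seed + 1L)
    ref <- gm$reference
    genes <- gm$genes
  }
  sm <- plant_small_variants(ref, rates, seed = seed + 2L, genes =
                               if (n_genes > 0L) genes else NULL)
  donor <- sm$donor
  truth_sv <- data.frame(class = character(), chrom_a = character(),
                         pos_a = integer(), chrom_b = character(),
                         pos_b = integer(), stringsAsFactors = FALSE)
  if (!is.null(spec) && nrow(spec) > 0L) {
    sv <- plant_structural_variants(donor, spec, seed = seed + 3L)
    donor <- sv$donor
    truth_sv <- sv$truth
  }
  reads <- simulate_mate_pairs(donor, lib, seed = seed + 4L)
  list(reference = ref, genes = genes, donor = donor, reads = reads,
       truth_small = sm$truth, truth_sv = truth_sv)
}
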