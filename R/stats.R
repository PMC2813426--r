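# Summary statistics and significance procedures for characterising a
# rearranged genome: substitution spectra, indel size distributions,
# diversity, gene-proximity enrichment, Monte-Carlo exon overlap,
# proportion comparisons, genome-vs-genome Venn overlap, array
# concordance and validation-rate extrapolation.

#' Nucleotide substitution spectrum of SNV calls
#'
#' @param snvs Data.frame of SNVs with `ref` and `alt` single-base
#'   columns.
#' @return List with `directed` (12 directed substitution counts),
#'   `collapsed` (6 strand-collapsed counts, e.g. `A>G/T>C`),
#'   `ts_fraction`, `tv_fraction` and `ts_tv_ratio`. Transitions are
#'   A<->G and C<->T.
#' @export
substitution_spectrum <- function(snvs) {
  if (any(snvs$ref == snvs$alt)) {
    stop("substitution_spectrum: ref equals alt")
  }
  bases <- c("A", "C", "G", "T")
  lv <- unlist(lapply(bases, function(r) {
    paste0(r, ">", setdiff(bases, r))
  }))
  directed <- table(factor(paste0(snvs$ref, ">", snvs$alt), levels = lv))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pair_of <- function(x) {
    r <- substr(x, 1, 1); a <- substr(x, 3, 3)
    alt_x <- paste0(comp[r], ">", comp[a])
    ifelse(x <= alt_x, paste0(x, "/", alt_x), paste0(alt_x, "/", x))
  }
  collapsed <- tapply(as.integer(directed), pair_of(lv), sum)
  partner <- c(A = "G", G = "A", C = "T", T = "C")
  is_ts <- snvs$alt == partner[snvs$ref]  # A<->G, C<->T
  ts <- sum(is_ts); tv <- nrow(snvs) - ts
  list(directed = directed,
       collapsed = collapsed[order(names(collapsed))],
       ts_fraction = ts / nrow(snvs),
       tv_fraction = tv / nrow(snvs),
       ts_tv_ratio = ts / tv)
}

#' Indel size distribution by compartment
#'
#' @param sizes Integer vector of indel lengths (1-20 bases).
#' @param coding Logical vector: indel affects coding sequence.
#' @return List with per-size fraction tables (`coding`, `noncoding`) and
#'   the frame-preserving fractions (`frame_coding`,
#'   `frame_noncoding` — sizes that are multiples of 3); fractions are NA
#'   for an empty compartment.
#' @export
indel_size_histogram <- function(sizes, coding) {
  stopifnot(length(sizes) == length(coding))
  hist_of <- function(s) {
    if (length(s) == 0L) return(rep(NA_real_, 20L))
    as.numeric(table(factor(s, levels = 1:20))) / length(s)
  }
  frame_of <- function(s) {
    if (length(s) == 0L) return(NA_real_)
    mean(s %% 3L == 0L)
  }
  list(coding = hist_of(sizes[coding]),
       noncoding = hist_of(sizes[!coding]),
       frame_coding = frame_of(sizes[coding]),
       frame_noncoding = frame_of(sizes[!coding]))
}

#' Heterozygous diversity theta
#'
#' @param calls Variant-call data.frame (or anything with a `zygosity`
#'   column).
#' @param bp Number of base pairs surveyed.
#' @return List with `theta` (= het count / bp), `het_count`, `bp`.
#' @export
heterozygosity_theta <- function(calls, bp) {
  if (bp <= 0) stop("heterozygosity_theta: bp must be positive")
  het <- sum(calls$zygosity == "het")
  list(theta = het / bp, het_count = het, bp = bp)
}

#' Fraction of the genome within a flank of a gene
#'
#' @param genes Gene-model data.frame.
#' @param ref Named character vector of reference sequences (for total
#'   length and truncation).
#' @param flank Extension in bases on each side of the genic interval.
#' @return Fraction of genome bases inside the union of
#'   `[tx_start - flank, tx_end + flank)` intervals.
#' @export
genome_fraction_near_genes <- function(genes, ref, flank = 1000L) {
  total <- sum(nchar(ref))
  if (nrow(genes) == 0L) return(0)
  covered <- 0L
  for (cn in unique(genes$chrom)) {
    g <- genes[genes$chrom == cn, , drop = FALSE]
    s <- pmax(0L, g$tx_start - flank)
    e <- pmin(nchar(ref[[cn]]), g$tx_end + flank)
    covered <- covered + union_length(s, e)
  }
  covered / total
}

#' Exact binomial upper-tail test for breakend-gene proximity
#'
#' @param k Number of events near a gene.
#' @param n Total events.
#' @param p0 Background fraction of the genome near a gene.
#' @return Upper-tail probability P(X >= k | n, p0).
#' @export
breakend_proximity_test <- function(k, n, p0) {
  stopifnot(k >= 0, k <= n, p0 >= 0, p0 <= 1)
  if (k == 0L) return(1)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Monte-Carlo test for microdeletion-exon overlap
#'
#' Each simulation places `n_dels` deletions of `del_len` bases uniformly
#' on the genome (chromosome chosen proportionally to its placeable
#' length) and counts how many overlap at least one exon base; the
#' empirical p-value is the fraction of simulations whose count reaches
#' the observed count.
#'
#' @param n_dels Deletions placed per simulation.
#' @param del_len Deletion length in bases.
#' @param exons Data.frame of exon intervals (`chrom`, `start`, `end`).
#' @param ref Named character vector of reference sequences.
#' @param observed Observed overlap count.
#' @param n_sims Number of simulations.
#' @param seed Integer seed.
#' @param estimator `"plain"` reports count/n_sims; `"plus_one"` reports
#'   (count+1)/(n_sims+1).
#' @return List with `observed`, `n_sims`, `count_ge`, `p_empirical`.
#' @export
exon_overlap_monte_carlo <- function(n_dels, del_len, exons, ref, observed,
                                     n_sims = 10000L, seed = 1L,
                                     estimator = c("plain", "plus_one")) {
  estimator <- match.arg(estimator)
  set.seed(seed)
  lens <- nchar(ref)
  if (any(del_len > lens)) {
    stop("exon_overlap_monte_carlo: del_len exceeds a chromosome length")
  }
  placeable <- lens - del_len + 1L
  n_tot <- n_sims * n_dels
  ci <- sample.int(length(ref), n_tot, replace = TRUE,
                   prob = placeable / sum(placeable))
  s <- floor(stats::runif(n_tot) * placeable[ci])
  # a deletion starting at s overlaps exon [a,b) iff a - del_len < s < b;
  # merge those trigger windows per chromosome, then test membership
  hit <- logical(n_tot)
  for (j in seq_along(ref)) {
    ex <- exons[exons$chrom == names(ref)[j], , drop = FALSE]
    ii <- which(ci == j)
    if (nrow(ex) == 0L || length(ii) == 0L) next
    ws <- pmax(0L, ex$start - del_len + 1L)
    we <- pmin(placeable[j], ex$end)
    r <- IRanges::reduce(IRanges::IRanges(start = ws + 1L, end = we))
    fs <- IRanges::start(r) - 1L
    fe <- IRanges::end(r)
    idx <- findInterval(s[ii], fs)
    hit[ii] <- idx >= 1L & s[ii] < fe[pmax(idx, 1L)]
  }
  stat <- tabulate(rep(seq_len(n_sims), each = n_dels)[hit], nbins = n_sims)
  count_ge <- sum(stat >= observed)
  p <- if (estimator == "plain") count_ge / n_sims else
    (count_ge + 1) / (n_sims + 1)
  list(observed = observed, n_sims = n_sims, count_ge = count_ge,
       p_empirical = p)
}

#' Compare two proportions (2x2 chi-square without continuity correction)
#'
#' @param k1,n1 Successes and total of the first group.
#' @param k2,n2 Successes and total of the second group.
#' @return List with `ratio1`, `ratio2` (reported to 3 significant
#'   figures), `chi_square`, `p_value`.
#' @export
compare_proportions <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("compare_proportions: empty group")
  stopifnot(k1 <= n1, k2 <= n2)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2)
  if (k1 / n1 == k2 / n2) {
    chi <- 0; p <- 1
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    chi <- unname(ct$statistic); p <- ct$p.value
  }
  list(ratio1 = signif(k1 / n1, 3), ratio2 = signif(k2 / n2, 3),
       chi_square = chi, p_value = p)
}

#' Extrapolate a validation error rate to a whole call set
#'
#' @param errors Discordant calls among those tested.
#' @param tested Calls tested.
#' @param total Size of the full call set.
#' @return `floor(total * errors / tested)` expected false positives.
#' @export
extrapolate_false_positives <- function(errors, tested, total) {
  if (tested <= 0) stop("extrapolate_false_positives: tested must be > 0")
  stopifnot(errors <= tested)
  floor(total * errors / tested)
}

#' Validation rate as a percentage
#'
#' @param validated Number validated.
#' @param tested Number tested.
#' @return `100 * validated / tested` (unrounded).
#' @export
validation_rate <- function(validated, tested) {
  100 * validated / tested
}

#' Three-set Venn overlap of two genomes' variant calls and a catalog
#'
#' Calls match across genomes when position and allele agree, regardless
#' of zygosity. Catalog membership is taken from each call's `in_dbsnp`
#' flag (or computed from `catalog` when supplied) and propagated across
#' matched pairs: if either member of a matched pair is in the catalog,
#' both are.
#'
#' @param calls_a,calls_b Variant-call data.frames.
#' @param catalog Optional dbSNP-style catalog used to (re)compute
#'   membership before propagation.
#' @return Named list of the 7 disjoint region counts: `a_only_novel`,
#'   `a_only_dbsnp`, `b_only_novel`, `b_only_dbsnp`, `shared_novel`,
#'   `shared_dbsnp`, `dbsnp_only` (catalog entries matching neither set;
#'   0 when no catalog is supplied).
#' @export
genome_overlap_venn <- function(calls_a, calls_b, catalog = NULL) {
  key <- function(x) paste(x$chrom, x$pos, x$alt, sep = ":")
  ka <- key(calls_a); kb <- key(calls_b)
  in_db_a <- if (!is.null(catalog)) match_dbsnp(calls_a, catalog) else
    calls_a$in_dbsnp
  in_db_b <- if (!is.null(catalog)) match_dbsnp(calls_b, catalog) else
    calls_b$in_dbsnp
  shared_a <- ka %in% kb
  shared_b <- kb %in% ka
  # propagate catalog membership across matched pairs
  db_keys <- union(ka[in_db_a], kb[in_db_b])
  in_db_a <- in_db_a | (shared_a & ka %in% db_keys)
  in_db_b <- in_db_b | (shared_b & kb %in% db_keys)
  dbsnp_only <- if (!is.null(catalog)) {
    ckey <- paste(catalog$chrom, catalog$pos, catalog$allele, sep = ":")
    sum(!(ckey %in% c(ka, kb)))
  } else 0L
  list(a_only_novel = sum(!shared_a & !in_db_a),
       a_only_dbsnp = sum(!shared_a & in_db_a),
       b_only_novel = sum(!shared_b & !in_db_b),
       b_only_dbsnp = sum(!shared_b & in_db_b),
       shared_novel = sum(shared_a & !in_db_a),
       shared_dbsnp = sum(shared_a & in_db_a),
       dbsnp_only = dbsnp_only)
}

#' Concordance of sequencing calls with array heterozygous genotypes
#'
#' For array sites genotyped heterozygous reference/variant (restricted
#' upstream to two-copy regions), checks which alleles the filtered
#' sequencing calls exhibit. The variant allele is observed at a site
#' when a passing call's alternate allele matches the array's variant
#' allele; the reference allele is observed when the site was sequenced
#' and the call (if any) is not homozygous-alternate; both-allele sites
#' are those with a matching heterozygous call.
#'
#' @param array_sites Data.frame with `chrom`, `pos` (0-based), `ref`,
#'   `alt` describing the array het genotype.
#' @param seq_calls Filtered variant-call data.frame.
#' @param depth Numeric vector of sequencing depth at each array site.
#' @return List of class fractions: `n_array_het`, `frac_sequenced`,
#'   `frac_both_alleles`, `frac_variant_allele`, `frac_reference_allele`.
#' @export
array_concordance <- function(array_sites, seq_calls, depth) {
  n <- nrow(array_sites)
  stopifnot(length(depth) == n)
  skey <- paste(array_sites$chrom, array_sites$pos, array_sites$alt,
                sep = ":")
  ckey <- paste(seq_calls$chrom, seq_calls$pos, seq_calls$alt, sep = ":")
  m <- match(skey, ckey)
  sequenced <- depth >= 1
  variant_obs <- !is.na(m)
  zyg <- ifelse(is.na(m), NA_character_, seq_calls$zygosity[m])
  reference_obs <- sequenced & (is.na(m) | zyg != "hom")
  both <- variant_obs & reference_obs
  list(n_array_het = n,
       frac_sequenced = mean(sequenced),
       frac_both_alleles = mean(both),
       frac_variant_allele = mean(variant_obs),
       frac_reference_allele = mean(reference_obs))
}
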