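# Binning, binsets, clusters, calls and deletion classification.

test_that("bins_for_position enumerates the covering bins", {
  cfg <- sv_config()
  expect_equal(bins_for_position("chr1", 1234L, cfg)$start,
               c(800L, 900L, 1000L, 1100L, 1200L))
  expect_equal(bins_for_position("chr1", 50L, cfg)$start, 0L)
  expect_equal(bins_for_position("chr1", 400L, cfg)$start,
               c(0L, 100L, 200L, 300L, 400L))
})

test_that("binsets form around shared aberrant reads and are filtered", {
  cfg <- sv_config()
  five <- pair_reads(do.call(mk_reads, lapply(1:5, function(i) {
    mk_pair(sprintf("r%d", i), "chr1", 1200L, "chr2", 5000L)
  })))
  bs <- build_binsets(five, cfg)
  b12 <- bs[bs$src_chrom == "chr1" & bs$src_start == 1200L, ]
  expect_equal(nrow(b12), 1L)
  expect_equal(b12$count, 5L)
  expect_equal(b12$dst_chrom, "chr2")
  # symmetric construction: chr2 side is a source too
  expect_true(any(bs$src_chrom == "chr2"))

  three <- pair_reads(do.call(mk_reads, lapply(1:3, function(i) {
    mk_pair(sprintf("r%d", i), "chr1", 1200L, "chr2", 5000L)
  })))
  expect_equal(nrow(build_binsets(three, cfg)), 0L)
})

test_that("each source bin pairs with its majority destination bin", {
  cfg <- sv_config()
  # 4 mates in a far destination, 2 in another; same source bin
  pairs <- pair_reads(do.call(mk_reads, c(
    lapply(1:4, function(i) mk_pair(sprintf("a%d", i), "chr1", 1200L,
                                    "chr2", 5000L)),
    lapply(1:2, function(i) mk_pair(sprintf("b%d", i), "chr1", 1200L,
                                    "chr2", 50000L))
  )))
  bs <- build_binsets(pairs, cfg)
  b <- bs[bs$src_chrom == "chr1" & bs$src_start == 1200L, ]
  expect_equal(b$count, 4L)
  expect_true(b$dst_start <= 5000L & b$dst_start + cfg$bin_width > 5000L)
})

test_that("cluster acceptance applies the size and span windows", {
  cfg <- sv_config()
  mk_bs <- function(src_starts, dst_starts) {
    out <- data.frame(src_chrom = "chr1", src_start = src_starts,
                      dst_chrom = "chr2", dst_start = dst_starts,
                      count = 5L, stringsAsFactors = FALSE)
    out$read_ids <- lapply(seq_along(src_starts), function(i)
      paste0("r", i, "_", 1:5))
    out
  }
  # 12 binsets, source starts 1000..2100 -> span 1600, accepted
  cl <- cluster_binsets(mk_bs(seq(1000L, 2100L, by = 100L),
                              seq(9000L, 10100L, by = 100L)), cfg)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$src_span, 1600L)
  expect_equal(cl$n_binsets, 12L)

  # 8 tight binsets -> too few
  cl8 <- cluster_binsets(mk_bs(seq(1000L, 1700L, by = 100L),
                               seq(9000L, 9700L, by = 100L)), cfg)
  expect_equal(nrow(cl8), 0L)

  # 35 binsets spanning <= 3000 -> too many
  cl35 <- cluster_binsets(mk_bs(seq(1000L, 3100L, length.out = 35),
                                seq(9000L, 11100L, length.out = 35)), cfg)
  expect_equal(nrow(cl35), 0L)

  # binsets further than cluster_link apart split into two clusters
  far <- rbind(mk_bs(seq(1000L, 2100L, by = 100L),
                     seq(9000L, 10100L, by = 100L)),
               mk_bs(seq(20000L, 21100L, by = 100L),
                     seq(39000L, 40100L, by = 100L)))
  far$read_ids <- c(lapply(1:12, function(i) paste0("x", i, "_", 1:5)),
                    lapply(1:12, function(i) paste0("y", i, "_", 1:5)))
  expect_equal(nrow(cluster_binsets(far, cfg)), 2L)
})

test_that("mirror clusters sharing reads merge into one call", {
  cl <- data.frame(src_chrom = c("chr1", "chr2"),
                   src_start = c(1000L, 9000L),
                   src_end = c(2600L, 10600L),
                   dst_chrom = c("chr2", "chr1"),
                   dst_start = c(9000L, 1000L),
                   dst_end = c(10600L, 2600L),
                   n_binsets = c(12L, 12L), src_span = c(1600L, 1600L),
                   accepted = TRUE, stringsAsFactors = FALSE)
  ids <- paste0("r", 1:20)
  cl$read_ids <- list(ids[1:18], ids[3:20])
  calls <- call_structural_variants(cl, sv_config())
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$class, "interchromosomal")
  expect_equal(calls$chrom_a, "chr1")  # regions ordered by coordinates
  expect_equal(calls$support, 20L)

  # unrelated clusters stay separate
  cl$read_ids <- list(paste0("a", 1:18), paste0("b", 1:18))
  expect_equal(nrow(call_structural_variants(cl, sv_config())), 2L)
})

test_that("mean_depth counts footprints and is subdivision-consistent", {
  expect_equal(mean_depth(mk_reads(mk_read("a", "chr1", 0L)),
                          "chr2", 0L, 100L), 0)
  expect_equal(mean_depth(mk_reads(mk_read("a", "chr1", 20L)),
                          "chr1", 0L, 100L), 0.5)
  # deletion runs consume reference: 20M10D20M has a 50-base footprint
  expect_equal(mean_depth(mk_reads(mk_read("a", "chr1", 0L,
                                           cigar = "20M10D20M",
                                           seq = strrep("A", 40L))),
                          "chr1", 0L, 50L), 1)
  set.seed(8)
  reads <- do.call(mk_reads, lapply(1:40, function(i) {
    mk_read(sprintf("r%d", i), "chr1", sample.int(950L, 1) - 1L)
  }))
  whole <- mean_depth(reads, "chr1", 0L, 1000L)
  left <- mean_depth(reads, "chr1", 0L, 400L)
  right <- mean_depth(reads, "chr1", 400L, 1000L)
  expect_equal(whole, (400 * left + 600 * right) / 1000)
  expect_error(mean_depth(reads, "chr1", 10L, 10L), "empty")
})

test_that("deletion classification follows the depth-ratio windows", {
  # chromosome of 5000: flanks truncate to [0,1000) and [2200,5000)
  mk_cov <- function(n, start, len) {
    do.call(mk_reads, lapply(seq_len(n), function(i) {
      mk_read(sprintf("c%s_%d", start, i), "chr1", start,
              cigar = paste0(len, "M"), seq = strrep("A", len))
    }))
  }
  base_call <- data.frame(id = "sv001", class = "intrachromosomal-other",
                          chrom_a = "chr1", start_a = 1000L, end_a = 1100L,
                          chrom_b = "chr1", start_b = 2100L, end_b = 2200L,
                          support = 10L, stringsAsFactors = FALSE)
  classify_with <- function(n_int) {
    reads <- rbind(mk_cov(9L, 0L, 1000L),      # left flank depth 9
                   mk_cov(11L, 2200L, 2800L),  # right flank depth 11
                   if (n_int > 0) mk_cov(n_int, 1100L, 1000L))
    attr(reads, "seq_lengths") <- c(chr1 = 5000L)
    classify_deletion(base_call, reads, cfg = sv_config())
  }
  out <- classify_with(2L)   # interior 2 vs mean flank 10 -> 0.2
  expect_equal(out$class, "deletion-complete")
  expect_equal(out$depth_ratio, 0.2)
  expect_equal(classify_with(5L)$class, "deletion-heterozygous")
  expect_equal(classify_with(9L)$class, "intrachromosomal-other")

  # empty interior stays unclassified
  empty_int <- base_call
  empty_int$start_b <- 1100L; empty_int$end_b <- 1200L
  reads <- mk_cov(5L, 0L, 1000L)
  attr(reads, "seq_lengths") <- c(chr1 = 5000L)
  expect_equal(classify_deletion(empty_int, reads,
                                 cfg = sv_config())$class,
               "intrachromosomal-other")
})

test_that("caller is silent on a clean genome and recovers planted events", {
  lens <- c(chr1 = 1500000L, chr2 = 1000000L)
  lib <- library_params(physical_coverage = 30, chimera_rate = 0)
  clean <- simulate_genome(lens, seed = 41, lib = lib)
  expect_equal(nrow(detect_svs(clean$reads)), 0L)

  spec <- sv_spec(
    class = c("deletion-complete", "deletion-heterozygous",
              "translocation"),
    chrom = c("chr1", "chr1", "chr1"),
    start = c(400000L, 900000L, 1300000L),
    end = c(406000L, 905000L, NA),
    chrom_b = c(NA, NA, "chr2"), pos_b = c(NA, NA, 500000L))
  sim <- simulate_genome(lens, seed = 41, lib = lib, spec = spec)
  calls <- detect_svs(sim$reads)
  expect_equal(nrow(calls), 3L)
  expect_setequal(calls$class, c("deletion-complete",
                                 "deletion-heterozygous",
                                 "interchromosomal"))
  # breakend regions within insert_max of truth
  for (i in seq_len(nrow(sim$truth_sv))) {
    tr <- sim$truth_sv[i, ]
    cls <- if (tr$class == "interchromosomal") "interchromosomal" else
      tr$class
    m <- calls[calls$class == cls, ]
    expect_equal(nrow(m), 1L)
    expect_lt(min(abs(c(m$start_a, m$end_a) - tr$pos_a)), 2000L)
    expect_lt(min(abs(c(m$start_b, m$end_b) - tr$pos_b)), 2000L)
  }
})

test_that("event support matches expected spanning-pair counts", {
  lens <- c(chr1 = 1500000L)
  lib <- library_params(physical_coverage = 30, chimera_rate = 0,
                        duplicate_rate = 0)
  spec <- sv_spec("deletion-complete", "chr1", 700000L, 706000L)
  sim <- simulate_genome(lens, seed = 43, lib = lib, spec = spec)
  calls <- detect_svs(sim$reads)
  expect_equal(nrow(calls), 1L)
  # both haplotypes carry the junction: expected spanning clones is twice
  # the per-haplotype clone coverage, minus pairs lost to ends that cross
  # the junction
  lambda <- 2 * 30 * (1 - 2 * 50 / 1450)
  expect_lt(abs(calls$support - lambda), 3 * sqrt(lambda))
})

test_that("binned caller agrees with brute-force pair clustering", {
  # independent oracle: transitive closure over aberrant pairs whose
  # corresponding ends lie within cluster_link on both sides
  oracle_events <- function(pairs, link = 2000L) {
    n <- nrow(pairs)
    if (n == 0L) return(NULL)
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    near <- function(i, j) {
      same <- pairs$chrom1[i] == pairs$chrom1[j] &&
        pairs$chrom2[i] == pairs$chrom2[j] &&
        abs(pairs$start1[i] - pairs$start1[j]) <= link &&
        abs(pairs$start2[i] - pairs$start2[j]) <= link
      swap <- pairs$chrom1[i] == pairs$chrom2[j] &&
        pairs$chrom2[i] == pairs$chrom1[j] &&
        abs(pairs$start1[i] - pairs$start2[j]) <= link &&
        abs(pairs$start2[i] - pairs$start1[j]) <= link
      same || swap
    }
    for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
      if (near(i, j)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    comps <- split(seq_len(n), roots)
    comps <- Filter(function(ii) length(ii) >= 9L, comps)
    lapply(comps, function(ii) {
      chroms <- sort(c(pairs$chrom1[ii[1]], pairs$chrom2[ii[1]]))
      list(chroms = chroms, n = length(ii))
    })
  }
  lens <- c(chr1 = 1200000L, chr2 = 800000L)
  lib <- library_params(physical_coverage = 30, chimera_rate = 0)
  spec <- sv_spec(
    class = c("deletion-complete", "translocation"),
    chrom = c("chr1", "chr1"), start = c(400000L, 900000L),
    end = c(405000L, NA), chrom_b = c(NA, "chr2"),
    pos_b = c(NA, 300000L))
  sim <- simulate_genome(lens, seed = 47, lib = lib, spec = spec)
  reads <- mark_duplicates(sim$reads)
  pairs <- pair_reads(reads)
  pairs <- pairs[!pairs$duplicate, ]
  ab <- pairs[is_aberrant(pairs), ]
  expect_lt(nrow(ab), 1000L)
  ev <- oracle_events(ab)
  calls <- detect_svs(sim$reads)
  expect_equal(nrow(calls), length(ev))
  oracle_inter <- sum(vapply(ev, function(e)
    e$chroms[1] != e$chroms[2], logical(1)))
  expect_equal(sum(calls$class == "interchromosomal"), oracle_inter)
  # every oracle component's pair set matches one call's support set size
  expect_setequal(vapply(ev, function(e) e$n, integer(1)), calls$support)
})
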