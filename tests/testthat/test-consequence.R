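# Consequence tags on hand-translated toy genes, knockout rule, and
# SV-to-gene effects.

# Plus-strand toy gene on a 60-base chromosome:
#   tx [0,60), single exon [0,60), CDS [10,22) = ATG AAA TGG TAA
toy_ref <- function() {
  c(chr1 = paste0("GGGGGGGGGG", "ATGAAATGGTAA",
                  "CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC"))
}
toy_plus <- function() {
  toy_gene("g1", tx_start = 0L, tx_end = 60L, cds_start = 10L,
           cds_end = 22L, exon_starts = 0L, exon_ends = 60L)
}
snv <- function(pos, ref, alt) {
  data.frame(chrom = "chr1", pos = as.integer(pos), ref = ref, alt = alt,
             vtype = "SNV", stringsAsFactors = FALSE)
}

test_that("coding SNVs are translated to the right tags", {
  g <- toy_plus(); ref <- toy_ref()
  # codon 3 TGG -> TGA: premature stop
  expect_equal(annotate_small_variant(snv(18L, "G", "A"), g, ref),
               "early-termination")
  # codon 2 AAA -> AGA (K->R): nonsynonymous
  expect_equal(annotate_small_variant(snv(14L, "A", "G"), g, ref),
               "coding-nonsynonymous")
  # codon 2 AAA -> AAG (K): synonymous
  expect_equal(annotate_small_variant(snv(15L, "A", "G"), g, ref),
               "coding-synonymous")
  # start codon hit
  expect_equal(annotate_small_variant(snv(10L, "A", "C"), g, ref),
               "start-codon-loss")
  # stop codon TAA -> CAA
  expect_equal(annotate_small_variant(snv(19L, "T", "C"), g, ref),
               "stop-codon-loss")
  # stop codon TAA -> TGA: still a stop
  expect_equal(annotate_small_variant(snv(20L, "A", "G"), g, ref),
               "coding-synonymous")
  # exonic, outside CDS
  expect_equal(annotate_small_variant(snv(5L, "G", "A"), g, ref),
               "utr-mutation")
  # outside the transcript
  g2 <- toy_gene("g2", tx_start = 0L, tx_end = 30L, cds_start = 10L,
                 cds_end = 22L, exon_starts = 0L, exon_ends = 30L)
  expect_equal(annotate_small_variant(snv(45L, "C", "A"), g2, ref),
               character(0))
})

test_that("coding indels tag frameshift/inframe and premature stops", {
  g <- toy_plus(); ref <- toy_ref()
  del2 <- data.frame(chrom = "chr1", pos = 13L, ref = "AA", alt = "-",
                     vtype = "DEL", stringsAsFactors = FALSE)
  expect_true("frameshift" %in% annotate_small_variant(del2, g, ref))
  # deleting codon 2 entirely keeps the frame: AAA gone, no new stop
  del3 <- data.frame(chrom = "chr1", pos = 13L, ref = "AAT", alt = "-",
                     vtype = "DEL", stringsAsFactors = FALSE)
  tg3 <- annotate_small_variant(del3, g, ref)
  expect_true("inframe-indel" %in% tg3)
  expect_false("frameshift" %in% tg3)
  # inserting TAA after codon 1 (before pos 13) adds an in-frame stop
  ins <- data.frame(chrom = "chr1", pos = 13L, ref = "-", alt = "TAA",
                    vtype = "INS", stringsAsFactors = FALSE)
  tgi <- annotate_small_variant(ins, g, ref)
  expect_setequal(tgi, c("inframe-indel", "early-termination"))
})

test_that("splice-window variants are tagged by position", {
  # two exons, intron [20,40); donor window [20,22), acceptor [38,40)
  ref <- c(chr1 = paste(rep("A", 80), collapse = ""))
  g <- toy_gene("g1", tx_start = 0L, tx_end = 60L, cds_start = 5L,
                cds_end = 55L, exon_starts = c(0L, 40L),
                exon_ends = c(20L, 60L))
  expect_true("intron-splice-site-mutation" %in%
                annotate_small_variant(snv(20L, "A", "G"), g, ref))
  expect_true("intron-splice-site-mutation" %in%
                annotate_small_variant(snv(39L, "A", "G"), g, ref))
  # deep intron: no tag
  expect_equal(annotate_small_variant(snv(30L, "A", "G"), g, ref),
               character(0))
})

test_that("abnormal reference models suppress start/stop-loss", {
  # CDS does not start with ATG
  ref <- c(chr1 = paste0("GGGGGGGGGG", "TTGAAATGGTAA", strrep("C", 38)))
  g <- toy_plus()
  tg <- annotate_small_variant(snv(10L, "T", "C"), g, ref)
  expect_true("abnormal-ref-gene-model-lacking-start-codon" %in% tg)
  expect_false("start-codon-loss" %in% tg)
})

test_that("minus-strand annotation equals the reverse-complement construct", {
  set.seed(17)
  for (rep in 1:5) {
    # random CDS with no internal stop on the plus strand
    codons <- c("ATG", sample(setdiff(names(Biostrings::GENETIC_CODE),
                                      c("TAA", "TAG", "TGA")), 6,
                              replace = TRUE), "TAA")
    cds <- paste(codons, collapse = "")
    up <- paste(sample(c("A", "C"), 10, TRUE), collapse = "")
    dn <- paste(sample(c("A", "C"), 10, TRUE), collapse = "")
    plus_seq <- paste0(up, cds, dn)
    L <- nchar(plus_seq)
    ref_plus <- c(chr1 = plus_seq)
    g_plus <- toy_gene("g", tx_start = 0L, tx_end = L,
                       cds_start = 10L, cds_end = 10L + nchar(cds),
                       exon_starts = 0L, exon_ends = L)
    # the same construct on the minus strand of a reversed chromosome
    ref_minus <- c(chr1 = breakscan:::revcomp(plus_seq))
    g_minus <- toy_gene("g", strand = "-", tx_start = 0L, tx_end = L,
                        cds_start = L - (10L + nchar(cds)),
                        cds_end = L - 10L,
                        exon_starts = 0L, exon_ends = L)
    for (k in 1:8) {
      pos <- sample.int(L, 1) - 1L
      base <- substr(plus_seq, pos + 1L, pos + 1L)
      alt <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
      t_plus <- annotate_small_variant(snv(pos, base, alt), g_plus,
                                       ref_plus)
      mpos <- L - 1L - pos
      t_minus <- annotate_small_variant(
        snv(mpos, chartr("ACGT", "TGCA", base),
            chartr("ACGT", "TGCA", alt)), g_minus, ref_minus)
      expect_setequal(t_plus, t_minus)
    }
  }
})

test_that("knockout rule needs homozygosity and a truncating tag", {
  expect_true(is_knockout("frameshift", "hom"))
  expect_false(is_knockout("early-termination", "het"))
  expect_false(is_knockout("coding-nonsynonymous", "hom"))
  expect_false(is_knockout("inframe-indel", "hom"))
  expect_true(is_knockout(c("coding-nonsynonymous", "stop-codon-loss"),
                          "hom"))
})

test_that("annotation is independent of model order and condenses symbols", {
  ref <- toy_ref()
  g1 <- toy_plus()
  g2 <- toy_plus(); g2$name <- "g1b"; g2$symbol <- "G1"
  calls <- snv(18L, "G", "A")
  calls$zygosity <- "hom"
  a12 <- annotate_variants(calls, rbind(g1, g2), ref)
  a21 <- annotate_variants(calls, rbind(g2, g1), ref)
  expect_setequal(paste(a12$gene, a12$tags), paste(a21$gene, a21$tags))
  expect_equal(knockout_genes(a12), "G1")
})

test_that("planted knockout variants are recovered end to end", {
  sim <- simulate_genome(c(chr1 = 200000L), n_genes = 6L, seed = 61,
                         rates = variant_rates(theta_snv = 0,
                                               theta_indel = 0),
                         lib = library_params(physical_coverage = 150,
                                              chimera_rate = 0))
  genes <- sim$genes
  ref <- sim$reference
  # craft a homozygous frameshift in the first gene's CDS interior
  g <- genes[1, , drop = FALSE]
  cp <- breakscan:::coding_positions(g)
  cp <- sort(cp)
  pos <- cp[25]
  ko <- data.frame(chrom = g$chrom, pos = pos,
                   ref = substr(ref[[g$chrom]], pos + 1L, pos + 2L),
                   alt = "-", vtype = "DEL", zygosity = "hom",
                   stringsAsFactors = FALSE)
  pl <- plant_small_variants(ref, variant_rates(theta_snv = 0,
                                                theta_indel = 0),
                             seed = 62, extra_variants = ko)
  reads <- simulate_mate_pairs(pl$donor,
                               library_params(physical_coverage = 150,
                                              chimera_rate = 0),
                               seed = 63)
  calls <- filter_variants(call_small_variants(mark_duplicates(reads), ref))
  ann <- annotate_variants(calls, genes, ref)
  expect_true(g$symbol %in% knockout_genes(ann))
})

test_that("SV gene effects follow the breakend and deletion rules", {
  genes <- rbind(
    toy_gene("ga", tx_start = 10000L, tx_end = 14000L, cds_start = 10500L,
             cds_end = 13500L, exon_starts = c(10000L, 12000L),
             exon_ends = c(11000L, 14000L)),
    toy_gene("gb", tx_start = 30000L, tx_end = 34000L, cds_start = 30500L,
             cds_end = 33500L, exon_starts = 30000L, exon_ends = 34000L))
  mk_call <- function(class, sa, ea, sb, eb) {
    data.frame(id = "sv1", class = class, chrom_a = "chr1",
               start_a = sa, end_a = ea, chrom_b = "chr1",
               start_b = sb, end_b = eb, support = 20L,
               stringsAsFactors = FALSE)
  }
  # breakend in the 1kb upstream window
  up <- mk_call("interchromosomal", 9200L, 9900L, 50000L, 50500L)
  expect_equal(genes_hit_by_breakend(up, genes), "GA")
  # breakend 1.5kb upstream: no hit
  far <- mk_call("interchromosomal", 8000L, 8500L, 50000L, 50500L)
  expect_equal(genes_hit_by_breakend(far, genes), character(0))
  # breakend inside an intron still hits (genic interval includes introns)
  intron <- mk_call("intrachromosomal-other", 11200L, 11800L, 50000L,
                    50500L)
  expect_equal(genes_hit_by_breakend(intron, genes), "GA")

  # deletion clipping 10 bases of a coding exon
  clip <- mk_call("deletion-complete", 10300L, 10490L, 10510L, 10700L)
  expect_equal(genes_hit_by_deletion(clip, genes), "GA")
  # deletion entirely inside an intron: no coding exon lost
  intr_del <- mk_call("deletion-heterozygous", 11050L, 11100L, 11900L,
                      11950L)
  expect_equal(genes_hit_by_deletion(intr_del, genes), character(0))
  # utr-only deletion: exon lost but no CDS base
  utr_del <- mk_call("deletion-complete", 13500L, 13600L, 13900L, 13950L)
  expect_equal(genes_hit_by_deletion(utr_del, genes), character(0))

  both <- rbind(up, clip)
  both$id <- c("sv1", "sv2")
  eff <- sv_affected_genes(both, genes)
  expect_equal(eff$symbols, c("GA", "GA"))
})
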