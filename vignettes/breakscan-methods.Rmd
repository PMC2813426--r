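---
title: "breakscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{breakscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why
its defaults and numerical choices are what they are. Everything here is
implemented and exercised by the test suite; no empirical claim is made
beyond what the tests compute.

## The detection model

### Signal: aberrant mate pairs

A long-insert mate-pair library circularises ~1–2 kb fragments and
sequences 50 bases from each end, so the mapped separation of a pair
estimates the insert size. The package takes "bases apart" to be the
**outer span**: rightmost end-exclusive coordinate minus leftmost start.
A pair is *aberrant* when it maps to two chromosomes or its outer span is
strictly below 1000 or strictly above 2000 bases (`aberrant_pair_config`).
The boundaries are strict on both sides — a span of exactly 2000 is
concordant — because the window is stated as "less than 1000 or greater
than 2000".

Duplicates are flagged first (`mark_duplicates`): mate pairs are
duplicates when both ends share start positions, order-insensitively;
single-end records when they share a start (and, by default, a strand —
exposed as `single_end_use_strand`, since a start-only reading is also
defensible for single ends). Within a duplicate group the
lexicographically smallest read id survives, which makes the operation
deterministic, idempotent and independent of input order.

### Binsets and clusters

The genome is covered by 500-base bins stepped 100 bases apart, so every
read start falls in exactly five bins (fewer at a chromosome start). A
read is "in" a bin through its start position only, not its footprint:
that keeps bin membership constant-size and matches the stepping logic.
For each source bin, the destination bin receiving the most mates of its
aberrant reads forms a *binset*; ties break toward the lowest
(chromosome, start), making output deterministic. Binsets under
`min_binset_reads = 4` reads are discarded.

Binsets cluster by single linkage when both their source bins and their
destination bins lie within `cluster_link = 2000` bases (same
chromosomes). A cluster is accepted with 9–29 binsets and a source-bin
span (rightmost bin end minus leftmost bin start) of 1000–3000 bases.
The size/span windows are read conjunctively — too-few *and* under-spanned
clusters, or too-many *and* over-spanned ones, are both artifacts of the
insert-size distribution, and a cluster must satisfy both windows to
survive. Whether the span window should also bind the destination side
is genuinely open; the default enforces it on the source side only, with
`span_both_sides = TRUE` available, because the destination side of an
asymmetric event (e.g. a breakpoint in repetitive sequence) can be
systematically wider.

Because every pair contributes with either end as source, each event
produces two mirror-image clusters. Clusters sharing at least half of
their supporting reads (relative to the smaller set) merge into a single
call; the regions are ordered by coordinates. The 50% threshold is a
design choice — mirror clusters of a real event share essentially all
reads, while unrelated clusters share essentially none, so any
intermediate threshold behaves identically (the tests exercise both
regimes).

### Deletion classification by depth

Intrachromosomal calls whose interior — the gap between the two
breakpoint-flanking regions — is non-empty and under 1 Mb are assessed
for deletion status. The interior mean per-base depth (read footprints
from CIGAR M/D runs) is divided by the mean of two 200 kb exterior
flanks, truncated at chromosome ends; if a flank is empty the other is
used alone. A ratio below 0.25 is a complete (homozygous) deletion,
0.25–0.75 (inclusive) a heterozygous deletion, anything else stays
"other". An empty interior or zero flank coverage leaves the call
unclassified rather than erroring.

## Small-variant filters

Read-level eligibility mirrors how mismapped or locally misaligned reads
corrupt pileups:

* SNV support comes only from indel-free reads, and the last 5 bases *in
  sequencing order* are ignored — for a reverse-strand read these are its
  leftmost reference-facing bases.
* Indel support requires exactly one contiguous indel run, anchored by at
  least one aligned base on both sides, matching the site's position,
  length and (for insertions) sequence.

Site-level filters: consensus Phred ≥ 10; total eligible observations
≥ 4 and < 60; at least one observation per strand. The upper bound is
exclusive ("less than 60"); the two published phrasings disagree ("at
most 60" elsewhere) and the exclusive reading is the default
(`max_obs = 60`, exclusive — set 61 for the inclusive reading). The
strand requirement is applied to *eligible* counts, not raw ones; the
alternative is noted but raw counts would let a site pass on observations
the eligibility rules had already rejected.

Catalog (dbSNP-style) matching requires position *and* allele identity by
default; `require_allele = FALSE` gives the looser membership under which
a novel allele at a known position counts as known. Indels are
left-aligned within repetitive context before comparison when a
reference is supplied.

The consensus/genotyping model that produces calls upstream is *not*
reimplemented: `call_small_variants` is a deliberately naive pileup
caller for synthetic, error-free reads (alt fraction ≥ 0.75 ⇒ homozygous,
fixed consensus Phred), provided so end-to-end runs are possible. It is
plumbing, not a contribution.

## Consequence annotation

The CDS of a model is spliced from exon∩CDS intervals and
reverse-complemented for minus-strand genes. A coding SNV is
re-translated in its codon: a new stop before the annotated stop is
`early-termination`; any change in the ATG start is `start-codon-loss`; a
stop codon that stops stopping is `stop-codon-loss`; otherwise the
amino-acid comparison gives `coding-nonsynonymous`/`coding-synonymous`.
Coding indels are `frameshift` when the coding-affecting length is not a
multiple of 3, else `inframe-indel`, plus `early-termination` when the
edited CDS gains a premature stop (the edited sequence is rescanned from
the start; its final codon does not count as premature). Variants
touching the two intronic bases flanking any exon are
`intron-splice-site-mutation` regardless of whether the reference shows
canonical GT/AG — the rule is positional, since a non-canonical reference
dinucleotide signals a model problem rather than a benign variant.
Models whose reference CDS lacks an ATG start or a stop receive the two
`abnormal-ref-gene-model-*` tags and start/stop-loss calls are
suppressed for them.

A gene is **knocked out** by a homozygous call with at least one of:
`early-termination`, `frameshift`, `intron-splice-site-mutation`,
`start-codon-loss`, `stop-codon-loss`. `coding-nonsynonymous` and
`inframe-indel` are excluded — serious but not protein-abolishing. A
variant overlapping several models is tagged per model and the symbol is
knocked out if *any* model yields a knockout tag.

For structural variants, deletions affect a gene when ≥ 1 base of a
coding exon lies in the deleted interval; breakend-type events
(interchromosomal and "other" intrachromosomal) affect a gene when either
breakpoint region overlaps the gene ± 1 kb. The 1 kb rule is applied to
*transcript* bounds: "coding region" in the source description is used
loosely, and transcript bounds are the conservative (more inclusive)
reading.

## Statistics

* Proximity enrichment uses the exact binomial upper tail
  P(X ≥ k | n, p0); the background p0 is the genome fraction within 1 kb
  of a gene, computed by interval union.
* The exon-overlap Monte-Carlo places n deletions per simulation
  uniformly (chromosome ∝ placeable length) and reports the plain
  empirical p = count_ge / n_sims, matching the convention of quoting
  ".046"-style fractions; the positively biased (count+1)/(n+1)
  estimator is available by flag.
* Proportion comparisons use the 2×2 chi-square without continuity
  correction; the original test is unnamed, and the uncorrected
  chi-square is the reading that reproduces borderline p-values (e.g.
  0.04 for the SNV loss-of-function comparison) at these sample sizes.
* Report rounding: percentages to 1 decimal, ratios to 2, scientific
  values to 3 significant figures.

## The simulator

The simulator emits alignment *outcomes* — mapped mate-pair records in
reference coordinates — not raw reads. Aligner behaviour (colour-space
encoding, mapping ambiguity) is out of scope, and every downstream stage
consumes mapped records, so simulating the mapping keeps the testable
surface exactly on the package's own algorithms.

What it emulates, with defaults:

* diploid donor from a random (or supplied) reference; heterozygous SNVs
  at θ_SNV = 4.4×10⁻⁴/bp and indels at θ_indel = 0.38×10⁻⁴/bp
  (binomial counts), indel lengths 1–20 with weight len^-1.5 and a
  frame-preserving (multiple-of-3) probability of 0.27 in coding exons
  vs 0.108 elsewhere; transitions with probability 0.674;
* `hom_fraction = 0.5` of planted variants homozygous — no published
  value exists; the observed roughly even split of homozygous vs
  heterozygous coding variants in the motivating data motivates 0.5;
* structural events: complete deletions (both haplotypes), heterozygous
  deletions (one haplotype, chosen at random), and non-reciprocal
  translocations joining chrA[0, a) to chrB[b, end) on haplotype 1;
* 2×50 mate pairs with truncated-normal inserts on [1000, 2000], mean
  1450, sd 150 (the sd is not published; 150 puts ~95% of mass inside
  the stated range before truncation and is exposed as a parameter);
* duplicate pairs as exact positional copies (PCR model) at a 16.4%
  emitted fraction; chimeric pairs (second end uniform) at 2.5% (<1/40);
* mate orientation is not modelled: aberrancy is defined by span and
  chromosome only, which is how the detection criterion is stated.

**Coverage definition.** `physical_coverage` is *per-haplotype* clone
coverage: the pair count scales with the summed haplotype lengths, so
every haplotype locus is spanned by ~`physical_coverage` inserts and a
diploid locus by about twice that. This makes the guarantee uniform
across event classes — a heterozygous breakpoint, present on one
haplotype, is spanned by ~30 clones at 30×, safely above the 9-binset
cluster floor. Under a total-spans/haploid-length definition the same
setting would leave heterozygous events ~14 spanning pairs and their
recovery at the cluster floor's mercy.

Planted variants are spaced at least 80 bases apart (a read length plus
the largest indel plus margin), so no single read carries two planted
variants; at the default densities (mean spacing ≳ 2 kb) the constraint
is statistically invisible, and it keeps read-level eligibility rules
decoupled from variant collisions.

Reads whose own 50-base window crosses a breakend junction are dropped
(a real aligner would fail or clip them); pairs *straddling* a junction
between their ends are the detection signal and are kept. Insertions at
the very edge of a read window are likewise dropped, as unanchored.

`generate_gene_models` places non-overlapping multi-exon genes on both
strands and *edits the reference* at a handful of bases so each model's
CDS starts with ATG, ends with a stop, and contains no internal stop
(internal stops are recoded to serine). On random sequence, open reading
frames of realistic length essentially never occur by chance, so
returning an edited reference alongside the models is the only way to
produce models that translate cleanly; the function therefore returns
`list(reference, genes)`.

### What the simulator does not model

No sequencing errors or base qualities, no colour space, no copy-number
gains, no inversions or tandem duplications, no repeat-induced
mismapping, no GC or insert-size bias. Consequently, passing tests
demonstrate the *algorithms* — binning, clustering, classification,
filtering, annotation, statistics — under clean mapping, not robustness
to real-data artifacts: with error-free reads the small-variant suite has
zero false positives by construction, and SV specificity reflects only
chimera noise.

## Numerical and degenerate-input choices

* All internal coordinates are 0-based half-open; conversion happens only
  in the SAM/VCF-like readers and writers (refGene-style and BED/BEDPE
  formats are already 0-based).
* `pair_span` returns `Inf` for interchromosomal pairs so any finite
  window classifies them aberrant.
* Cluster spans are measured on bin starts plus the bin width; mirror
  merging unions read ids; call ordering is by (chromosome, start).
* Depth flanks truncate at chromosome ends; a zero-length flank defers to
  the other; zero exterior coverage leaves a call unclassified.
* Empty inputs return typed empty tables throughout; an empty indel
  histogram compartment reports NA rather than 0.
* The truncated normal is sampled by rejection (exact, and trivially fast
  at these truncation bounds).

## Problem sizes in the test suite

The suite runs on genomes of 40 kb–5 Mb: the SV sensitivity/specificity
checks use a 5 Mb two-chromosome genome at 30× per-haplotype clone
coverage (~470k reads, ~10 s to call), parameter-recovery checks use
1 Mb, and filter/annotation checks use sub-kilobase toy constructs where
expected outputs are hand-derivable. These sizes make every planted
event's support lie far from decision boundaries while keeping the whole
suite in a few minutes.

## Known limitations

* Breakpoint resolution is bin-level (~hundreds of bases), not base
  level; no split-read assembly is attempted.
* The cluster acceptance floor (9 binsets) implies a minimum spanning
  support; events on a single haplotype below ~20× clone coverage fade
  below it.
* Deletion zygosity classification assumes locally diploid flanks; in a
  genuinely aneuploid genome the 25%/75% ratio cutoffs shift with local
  copy number.
* The naive zygosity caller misclassifies a small fraction of
  heterozygous sites near the 0.75 alt-fraction cut at moderate depth;
  it exists only to drive end-to-end synthetic runs.
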