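# Consequence annotation of filtered variants against gene models, with
# the knockout rule (homozygous + truncating tag) and the gene-level
# effects of structural variants.

knockout_tags <- c("early-termination", "frameshift",
                   "intron-splice-site-mutation", "start-codon-loss",
                   "stop-codon-loss")

stop_codons <- c("TAA", "TAG", "TGA")

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Spliced CDS sequence of a model, in translation order (reverse
# complemented for minus-strand genes).
cds_sequence <- function(gene, ref) {
  es <- pmax(gene$exon_starts[[1]], gene$cds_start)
  ee <- pmin(gene$exon_ends[[1]], gene$cds_end)
  keep <- es < ee
  pieces <- substring(ref[[gene$chrom]], es[keep] + 1L, ee[keep])
  s <- paste(pieces, collapse = "")
  if (gene$strand == "-") revcomp(s) else s
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  ifelse(is.na(aa), "X", aa)
}

#' Annotate one small variant against one gene model
#'
#' Implements the tag vocabulary: `utr-mutation`, `coding-nonsynonymous`,
#' `coding-synonymous`, `frameshift`, `early-termination`, `inframe-indel`,
#' `intron-splice-site-mutation`, `stop-codon-loss`, `start-codon-loss`,
#' and the two `abnormal-ref-gene-model-*` tags for models whose reference
#' CDS lacks an ATG start or a stop (for which start/stop-loss calls are
#' suppressed). A coding SNV is re-translated in its codon on the gene
#' strand; a premature stop upstream of the annotated stop is
#' `early-termination`. A coding indel is `frameshift` when its length is
#' not a multiple of 3, else `inframe-indel`, plus `early-termination`
#' when the edited coding sequence gains a premature stop. Any variant
#' touching the two intronic bases flanking an exon is
#' `intron-splice-site-mutation` regardless of the reference dinucleotide.
#'
#' @param v One variant: list or one-row data.frame with `chrom`, `pos`,
#'   `ref`, `alt`, `vtype`.
#' @param gene One gene model row (as from [read_gene_models()]).
#' @param ref Named character vector of reference sequences.
#' @return Character vector of tags (empty when the variant lies outside
#'   the gene and its splice windows).
#' @export
annotate_small_variant <- function(v, gene, ref) {
  tags <- character(0)
  if (v$chrom != gene$chrom) return(tags)
  ref_len <- switch(v$vtype, SNV = 1L, DEL = nchar(v$ref), INS = 0L)
  v_s <- v$pos
  v_e <- v$pos + ref_len
  hits <- function(ws, we) {
    if (v$vtype == "INS") v_s > ws & v_s < we
    else overlap_width(v_s, v_e, ws, we) > 0L
  }
  es <- gene$exon_starts[[1]]; ee <- gene$exon_ends[[1]]
  n_ex <- length(es)
  # the 2 intronic bases after every exon but the last (5' splice site on
  # the + strand) and before every exon but the first (3' splice site)
  if (n_ex > 1L) {
    win_s <- c(ee[-n_ex], es[-1L] - 2L)
    win_e <- c(ee[-n_ex] + 2L, es[-1L])
    if (any(hits(win_s, win_e))) {
      tags <- c(tags, "intron-splice-site-mutation")
    }
  }
  if (!any(hits(gene$tx_start, gene$tx_end))) return(unique(tags))
  exonic <- any(hits(es, ee))
  ces <- pmax(es, gene$cds_start)
  cee <- pmin(ee, gene$cds_end)
  keep <- ces < cee
  in_cds <- any(keep) && any(hits(ces[keep], cee[keep]))
  if (exonic && !in_cds) tags <- c(tags, "utr-mutation")
  if (!in_cds) return(unique(tags))
  cds <- cds_sequence(gene, ref)
  abn_start <- substr(cds, 1L, 3L) != "ATG"
  abn_stop <- !substr(cds, nchar(cds) - 2L, nchar(cds)) %in% stop_codons
  if (abn_start) tags <- c(tags, "abnormal-ref-gene-model-lacking-start-codon")
  if (abn_stop) tags <- c(tags, "abnormal-ref-gene-model-lacking-stop-codon")
  if (v$vtype == "SNV") {
    tags <- c(tags, annotate_cds_snv(v, gene, cds, abn_start, abn_stop))
  } else {
    len <- if (v$vtype == "DEL") {
      # only the deleted bases that hit coding sequence shift the frame
      sum(overlap_width(v_s, v_e, ces[keep], cee[keep]))
    } else {
      nchar(v$alt)
    }
    tags <- c(tags, if (len %% 3L != 0L) "frameshift" else "inframe-indel")
    if (premature_stop_after_edit(v, gene, ref)) {
      tags <- c(tags, "early-termination")
    }
  }
  unique(tags)
}

annotate_cds_snv <- function(v, gene, cds, abn_start, abn_stop) {
  cp <- coding_positions(gene)
  i0 <- match(v$pos, cp)
  if (is.na(i0)) return(character(0))
  ci <- (i0 - 1L) %/% 3L + 1L
  within <- (i0 - 1L) %% 3L
  n_codons <- nchar(cds) %/% 3L
  old <- substr(cds, 3L * ci - 2L, 3L * ci)
  alt_b <- if (gene$strand == "-") chartr("ACGT", "TGCA", v$alt) else v$alt
  new <- old
  substr(new, within + 1L, within + 1L) <- alt_b
  if (ci == 1L && !abn_start) {
    return("start-codon-loss")  # any change to the ATG start
  }
  if (ci == n_codons && !abn_stop) {
    return(if (new %in% stop_codons) "coding-synonymous"
           else "stop-codon-loss")
  }
  if (new %in% stop_codons) return("early-termination")
  if (translate_codon(new) == translate_codon(old)) {
    "coding-synonymous"
  } else {
    "coding-nonsynonymous"
  }
}

# Does applying the indel to the CDS create a stop before the final codon?
premature_stop_after_edit <- function(v, gene, ref) {
  cp <- coding_positions(gene)
  minus <- gene$strand == "-"
  base_at <- function(p) {
    b <- substr(ref[[gene$chrom]], p + 1L, p + 1L)
    if (minus) chartr("ACGTN", "TGCAN", b) else b
  }
  chars <- vapply(cp, base_at, character(1))
  if (v$vtype == "DEL") {
    del <- cp >= v$pos & cp < v$pos + nchar(v$ref)
    chars <- chars[!del]
  } else {
    ins <- strsplit(if (minus) revcomp(v$alt) else v$alt, "")[[1]]
    if (minus) {
      at <- match(v$pos, cp)          # insert after the base at pos
      if (is.na(at)) return(FALSE)
      chars <- append(chars, ins, after = at)
    } else {
      at <- match(TRUE, cp >= v$pos)  # insert before the base at pos
      if (is.na(at)) return(FALSE)
      chars <- append(chars, ins, after = at - 1L)
    }
  }
  n_codons <- length(chars) %/% 3L
  if (n_codons < 2L) return(FALSE)
  codons <- vapply(seq_len(n_codons - 1L), function(k) {
    paste(chars[(3L * k - 2L):(3L * k)], collapse = "")
  }, character(1))
  any(codons[-1L] %in% stop_codons)
}

#' Knockout classification of an annotated variant
#'
#' @param tags Character vector of consequence tags.
#' @param zygosity `"hom"` or `"het"`.
#' @return TRUE iff the call is homozygous and carries at least one of
#'   `early-termination`, `frameshift`, `intron-splice-site-mutation`,
#'   `start-codon-loss`, `stop-codon-loss`.
#' @export
is_knockout <- function(tags, zygosity) {
  zygosity == "hom" && length(intersect(tags, knockout_tags)) > 0L
}

#' Annotate variant calls against all overlapping gene models
#'
#' @param calls Variant-call data.frame.
#' @param genes Gene-model data.frame.
#' @param ref Named character vector of reference sequences.
#' @return Data.frame with one row per (variant, model) pair carrying
#'   tags: `call_idx`, `chrom`, `pos`, `gene`, `symbol`, `tags`
#'   (comma-separated), `knockout`.
#' @export
annotate_variants <- function(calls, genes, ref) {
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    v <- calls[i, , drop = FALSE]
    near <- which(genes$chrom == v$chrom &
                    v$pos >= genes$tx_start - 25L &
                    v$pos < genes$tx_end + 25L)
    for (g in near) {
      tg <- annotate_small_variant(v, genes[g, , drop = FALSE], ref)
      if (length(tg) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        call_idx = i, chrom = v$chrom, pos = v$pos,
        gene = genes$name[g], symbol = genes$symbol[g],
        tags = paste(sort(tg), collapse = ","),
        knockout = is_knockout(tg, v$zygosity),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(call_idx = integer(), chrom = character(),
                      pos = integer(), gene = character(),
                      symbol = character(), tags = character(),
                      knockout = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gene symbols knocked out by annotated small variants
#'
#' A symbol is knocked out when any of its models yields a knockout tag
#' from a homozygous call (symbol-level condensation across models).
#'
#' @param annotations Output of [annotate_variants()].
#' @return Sorted character vector of symbols.
#' @export
knockout_genes <- function(annotations) {
  sort(unique(annotations$symbol[annotations$knockout]))
}

#' Genes affected by a breakend-type structural variant
#'
#' For interchromosomal and other (non-deletion) intrachromosomal events a
#' gene is affected when either breakpoint-flanking region overlaps the
#' genic interval extended by `flank` bases on each side.
#'
#' @param call One SV call row.
#' @param genes Gene-model data.frame.
#' @param flank Genic-interval extension in bases.
#' @return Character vector of affected symbols.
#' @export
genes_hit_by_breakend <- function(call, genes, flank = 1000L) {
  gs <- genes$tx_start - flank
  ge <- genes$tx_end + flank
  hit <- (genes$chrom == call$chrom_a &
            overlap_width(call$start_a, call$end_a, gs, ge) > 0L) |
    (genes$chrom == call$chrom_b &
       overlap_width(call$start_b, call$end_b, gs, ge) > 0L)
  sort(unique(genes$symbol[hit]))
}

#' Genes affected by a called deletion
#'
#' A gene is affected when at least one base of a coding exon (exon
#' intersected with the CDS interval) lies inside the deleted interval —
#' the gap between the two breakpoint-flanking regions.
#'
#' @param call One SV call row (class deletion-complete or
#'   deletion-heterozygous).
#' @param genes Gene-model data.frame.
#' @return Character vector of affected symbols.
#' @export
genes_hit_by_deletion <- function(call, genes) {
  del_s <- call$end_a
  del_e <- call$start_b
  if (del_e <= del_s) return(character(0))
  hit <- vapply(seq_len(nrow(genes)), function(g) {
    if (genes$chrom[g] != call$chrom_a) return(FALSE)
    ces <- pmax(genes$exon_starts[[g]], genes$cds_start[g])
    cee <- pmin(genes$exon_ends[[g]], genes$cds_end[g])
    any(overlap_width(ces, cee, del_s, del_e) > 0L)
  }, logical(1))
  sort(unique(genes$symbol[hit]))
}

#' Genes affected by each structural-variant call
#'
#' Applies the deletion rule to deletion classes and the breakend rule to
#' interchromosomal and other intrachromosomal events.
#'
#' @param calls SV call data.frame.
#' @param genes Gene-model data.frame.
#' @param flank Genic extension for the breakend rule.
#' @return Data.frame `id`, `class`, `symbols` (comma-separated, possibly
#'   empty).
#' @export
sv_affected_genes <- function(calls, genes, flank = 1000L) {
  syms <- vapply(seq_len(nrow(calls)), function(i) {
    call <- calls[i, , drop = FALSE]
    s <- if (grepl("^deletion", call$class)) {
      genes_hit_by_deletion(call, genes)
    } else {
      genes_hit_by_breakend(call, genes, flank)
    }
    paste(s, collapse = ",")
  }, character(1))
  data.frame(id = calls$id, class = calls$class, symbols = syms,
             stringsAsFactors = FALSE)
}
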