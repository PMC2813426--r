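# Readers and writers for every external format the pipeline touches.
# Internal coordinates are 0-based half-open throughout; SAM and VCF-like
# positions are converted at this boundary, BED/BEDPE and refGene-style
# tables are already 0-based half-open on disk.

## ---------------------------------------------------------------- FASTA

#' Read a reference genome from FASTA
#'
#' @param path Path to a FASTA file. Sequences may only contain A, C, G, T, N
#'   (case-insensitive; stored uppercase).
#' @return A named character vector, one element per sequence, in file order.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop("read_fasta: duplicate sequence names in ", path)
  }
  seqs <- toupper(as.character(ss))
  names(seqs) <- nm
  validate_reference(seqs)
  seqs
}

#' Write a reference genome to FASTA
#'
#' @param ref Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ref, path) {
  validate_reference(ref)
  ss <- Biostrings::DNAStringSet(ref)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

validate_reference <- function(ref) {
  if (is.null(names(ref)) || anyDuplicated(names(ref)) || any(!nzchar(names(ref)))) {
    stop("reference: sequence names must be unique and non-empty")
  }
  if (any(nchar(ref) < 1L)) stop("reference: zero-length sequence")
  bad <- grepl("[^ACGTN]", ref)
  if (any(bad)) {
    stop("reference: non-ACGTN characters in sequence ",
         names(ref)[bad][1])
  }
  invisible(ref)
}

## ------------------------------------------------------------------ SAM

# Columns of the internal alignment table. `start`/`mate_start` are 0-based;
# NA for unmapped sides. `seq` may be "*" when bases were not recorded.
read_columns <- c("read_id", "chrom", "start", "strand", "cigar", "seq",
                  "mate_chrom", "mate_start", "mate_strand",
                  "mapped", "mate_mapped", "paired", "first_in_pair",
                  "duplicate")

empty_reads <- function() {
  data.frame(read_id = character(), chrom = character(), start = integer(),
             strand = character(), cigar = character(), seq = character(),
             mate_chrom = character(), mate_start = integer(),
             mate_strand = character(), mapped = logical(),
             mate_mapped = logical(), paired = logical(),
             first_in_pair = logical(), duplicate = logical(),
             stringsAsFactors = FALSE)
}

#' Read aligned mate-pair reads from a SAM file
#'
#' Only the fields the pipeline uses are interpreted: QNAME, FLAG (paired,
#' unmapped, mate-unmapped, strand, mate-strand, first/last in pair,
#' duplicate), RNAME, POS, CIGAR, RNEXT, PNEXT and SEQ. The header must
#' declare every sequence used (`@SQ SN: LN:`); records whose POS lies
#' beyond the declared length, or on an undeclared sequence, are an error.
#' Reads flagged unmapped are retained with `mapped = FALSE`.
#'
#' @param path Path to a SAM text file.
#' @return A data.frame of alignments with 0-based `start` coordinates.
#' @export
read_alignments <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^@", lines)
  sq <- lines[grepl("^@SQ\\t", lines)]
  sn <- sub(".*\\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\\tLN:([0-9]+).*", "\\1", sq))
  names(ln) <- sn
  body <- lines[!hdr]
  if (length(body) == 0L) return(empty_reads())
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L)) stop("read_alignments: SAM record with < 11 fields")
  fld <- function(i) vapply(f, `[[`, character(1), i)
  flag <- as.integer(fld(2))
  rname <- fld(3)
  pos1 <- as.integer(fld(4))
  mapped <- bitwAnd(flag, 4L) == 0L
  paired <- bitwAnd(flag, 1L) > 0L
  if (any(mapped & !(rname %in% names(ln)))) {
    stop("read_alignments: record on undeclared sequence")
  }
  if (any(mapped & pos1 > ln[rname])) {
    stop("read_alignments: POS beyond declared sequence length")
  }
  rnext <- fld(7)
  rnext[rnext == "="] <- rname[rnext == "="]
  pnext <- as.integer(fld(8))
  mate_mapped <- paired & bitwAnd(flag, 8L) == 0L
  out <- data.frame(
    read_id = fld(1),
    chrom = ifelse(mapped, rname, NA_character_),
    start = ifelse(mapped, pos1 - 1L, NA_integer_),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    cigar = fld(6),
    seq = fld(10),
    mate_chrom = ifelse(mate_mapped, rnext, NA_character_),
    mate_start = ifelse(mate_mapped, pnext - 1L, NA_integer_),
    mate_strand = ifelse(bitwAnd(flag, 32L) > 0L, "-", "+"),
    mapped = mapped,
    mate_mapped = mate_mapped,
    paired = paired,
    first_in_pair = !paired | bitwAnd(flag, 64L) > 0L,
    duplicate = bitwAnd(flag, 1024L) > 0L,
    stringsAsFactors = FALSE
  )
  attr(out, "seq_lengths") <- ln
  out
}

#' Write aligned reads as SAM
#'
#' @param reads Alignment data.frame (see [read_alignments()]).
#' @param path Output path.
#' @param seq_lengths Named integer vector of sequence lengths for the
#'   header; defaults to the `seq_lengths` attribute of `reads`.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(reads, path, seq_lengths = attr(reads, "seq_lengths")) {
  if (is.null(seq_lengths)) {
    stop("write_alignments: seq_lengths required for the SAM header")
  }
  if (any(reads$mapped & !(reads$chrom %in% names(seq_lengths)))) {
    stop("write_alignments: read on sequence absent from seq_lengths")
  }
  flag <- ifelse(reads$paired, 1L, 0L) +
    ifelse(reads$mapped, 0L, 4L) +
    ifelse(reads$paired & !reads$mate_mapped, 8L, 0L) +
    ifelse(reads$strand == "-", 16L, 0L) +
    ifelse(reads$paired & reads$mate_strand == "-", 32L, 0L) +
    ifelse(reads$paired & reads$first_in_pair, 64L, 0L) +
    ifelse(reads$paired & !reads$first_in_pair, 128L, 0L) +
    ifelse(reads$duplicate, 1024L, 0L)
  rname <- ifelse(reads$mapped, reads$chrom, "*")
  rnext <- ifelse(reads$mate_mapped,
                  ifelse(!is.na(reads$chrom) & reads$mate_chrom == reads$chrom,
                         "=", reads$mate_chrom),
                  "*")
  body <- paste(reads$read_id, flag, rname,
                ifelse(reads$mapped, reads$start + 1L, 0L),
                ifelse(reads$mapped, 60L, 0L),
                reads$cigar, rnext,
                ifelse(reads$mate_mapped, reads$mate_start + 1L, 0L),
                0L, reads$seq, "*", sep = "\t")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(seq_lengths), "\tLN:", seq_lengths))
  writeLines(c(hdr, body), path)
  invisible(path)
}

## ---------------------------------------------------------- gene models

#' Read gene models from a refGene-style table
#'
#' Tab-separated columns: name, chrom, strand, txStart, txEnd, cdsStart,
#' cdsEnd, exonCount, exonStarts, exonEnds, and optionally an eleventh
#' column carrying the gene symbol (defaults to `name`). Coordinates are
#' 0-based half-open on disk, as in the UCSC tables, and are kept as-is.
#'
#' @param path Path to the table (no header line).
#' @return A data.frame with one row per transcript model; `exon_starts`
#'   and `exon_ends` are list columns of integer vectors.
#' @export
read_gene_models <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (!ncol(raw) %in% c(10L, 11L)) {
    stop("read_gene_models: expected 10 or 11 tab-separated columns")
  }
  g <- data.frame(
    name = raw[[1]],
    symbol = if (ncol(raw) == 11L) raw[[11]] else raw[[1]],
    chrom = raw[[2]],
    strand = raw[[3]],
    tx_start = as.integer(raw[[4]]),
    tx_end = as.integer(raw[[5]]),
    cds_start = as.integer(raw[[6]]),
    cds_end = as.integer(raw[[7]]),
    stringsAsFactors = FALSE
  )
  g$exon_starts <- lapply(raw[[9]], parse_int_list)
  g$exon_ends <- lapply(raw[[10]], parse_int_list)
  n_exons <- as.integer(raw[[8]])
  if (any(lengths(g$exon_starts) != n_exons) ||
      any(lengths(g$exon_ends) != n_exons)) {
    stop("read_gene_models: exonCount disagrees with exon lists")
  }
  validate_gene_models(g)
  g
}

parse_int_list <- function(s) {
  as.integer(strsplit(sub(",$", "", s), ",", fixed = TRUE)[[1]])
}

validate_gene_models <- function(g) {
  for (i in seq_len(nrow(g))) {
    es <- g$exon_starts[[i]]; ee <- g$exon_ends[[i]]
    if (g$cds_start[i] < g$tx_start[i] || g$cds_end[i] > g$tx_end[i] ||
        g$cds_start[i] > g$cds_end[i]) {
      stop("gene model ", g$name[i], ": CDS outside transcript bounds")
    }
    if (any(es >= ee) || is.unsorted(es, strictly = TRUE) ||
        any(es[-1] < ee[-length(ee)])) {
      stop("gene model ", g$name[i], ": exons unsorted or overlapping")
    }
    if (es[1] < g$tx_start[i] || ee[length(ee)] > g$tx_end[i]) {
      stop("gene model ", g$name[i], ": exons outside transcript bounds")
    }
  }
  invisible(g)
}

#' Write gene models as a refGene-style table
#' @param genes Gene model data.frame (see [read_gene_models()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    paste(genes$name[i], genes$chrom[i], genes$strand[i],
          genes$tx_start[i], genes$tx_end[i],
          genes$cds_start[i], genes$cds_end[i],
          length(genes$exon_starts[[i]]),
          paste0(paste(genes$exon_starts[[i]], collapse = ","), ","),
          paste0(paste(genes$exon_ends[[i]], collapse = ","), ","),
          genes$symbol[i], sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

## --------------------------------------------------------- variant calls

#' Read variant calls from the VCF-like 8-column dialect
#'
#' Columns CHROM, POS (1-based), ID, REF, ALT, QUAL, FILTER, INFO. The INFO
#' field carries `key=value` attributes `TYPE` (SNV/INS/DEL), `PHRED`,
#' `FWD`, `REV`, `ZYG` (hom/het) and `DBSNP` (0/1). Indels use "-" on the
#' empty side: a deletion has REF = deleted bases, ALT = "-"; an insertion
#' has REF = "-", ALT = inserted bases (placed before the base at POS).
#'
#' @param path Path to the tab-separated file; `#`-prefixed lines ignored.
#' @return A data.frame of calls with 0-based `pos`.
#' @export
read_variant_calls <- function(path) {
  lines <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  if (length(lines) == 0L) return(empty_variant_calls())
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 8L)) {
    stop("read_variant_calls: expected 8 tab-separated columns")
  }
  fld <- function(i) vapply(f, `[[`, character(1), i)
  info <- fld(8)
  iv <- function(key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    has <- grepl(paste0("(^|;)", key, "="), info)
    out <- rep(NA_character_, length(info))
    out[has] <- sub(paste0(".*", key, "="), "", m)
    out
  }
  calls <- data.frame(
    chrom = fld(1),
    pos = as.integer(fld(2)) - 1L,
    ref = fld(4),
    alt = fld(5),
    vtype = iv("TYPE"),
    phred = as.numeric(iv("PHRED")),
    fwd = as.integer(iv("FWD")),
    rev = as.integer(iv("REV")),
    zygosity = iv("ZYG"),
    in_dbsnp = iv("DBSNP") == "1",
    stringsAsFactors = FALSE
  )
  validate_variant_calls(calls)
  calls
}

empty_variant_calls <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), vtype = character(), phred = numeric(),
             fwd = integer(), rev = integer(), zygosity = character(),
             in_dbsnp = logical(), stringsAsFactors = FALSE)
}

validate_variant_calls <- function(calls) {
  if (any(!calls$vtype %in% c("SNV", "INS", "DEL"))) {
    stop("variant calls: TYPE must be SNV, INS or DEL")
  }
  if (any(calls$ref == calls$alt)) stop("variant calls: ALT equals REF")
  ins <- calls$vtype == "INS"; del <- calls$vtype == "DEL"
  if (any(nchar(calls$alt[ins]) < 1L | nchar(calls$alt[ins]) > 20L) ||
      any(nchar(calls$ref[del]) < 1L | nchar(calls$ref[del]) > 20L)) {
    stop("variant calls: indel allele length must be in [1, 20]")
  }
  invisible(calls)
}

#' Write variant calls in the VCF-like dialect
#' @param calls Variant-call data.frame (see [read_variant_calls()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_calls <- function(calls, path) {
  info <- paste0("TYPE=", calls$vtype,
                 ";PHRED=", calls$phred,
                 ";FWD=", calls$fwd,
                 ";REV=", calls$rev,
                 ";ZYG=", calls$zygosity,
                 ";DBSNP=", as.integer(calls$in_dbsnp))
  body <- paste(calls$chrom, calls$pos + 1L, ".", calls$ref, calls$alt,
                calls$phred, ".", info, sep = "\t")
  writeLines(c("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", body), path)
  invisible(path)
}

## ------------------------------------------------------------ SV calls

#' Write structural-variant calls as BEDPE
#'
#' Standard 10 BEDPE columns (both breakend-flanking regions, 0-based
#' half-open; name = event class; score = supporting pair count) plus an
#' eleventh column carrying the call id, so files round-trip.
#'
#' @param calls SV call data.frame with columns `id`, `class`, `chrom_a`,
#'   `start_a`, `end_a`, `chrom_b`, `start_b`, `end_b`, `support`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sv_calls <- function(calls, path) {
  body <- paste(calls$chrom_a, calls$start_a, calls$end_a,
                calls$chrom_b, calls$start_b, calls$end_b,
                calls$class, calls$support, ".", ".", calls$id, sep = "\t")
  writeLines(body, path)
  invisible(path)
}

#' Read structural-variant calls from BEDPE
#' @param path Path to a BEDPE file written by [write_sv_calls()].
#' @return SV call data.frame.
#' @export
read_sv_calls <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(empty_sv_calls())
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(!lengths(f) %in% c(10L, 11L))) {
    stop("read_sv_calls: expected 10 or 11 BEDPE columns")
  }
  fld <- function(i) vapply(f, `[[`, character(1), i)
  data.frame(
    id = if (lengths(f)[1] == 11L) fld(11) else as.character(seq_along(f)),
    class = fld(7),
    chrom_a = fld(1), start_a = as.integer(fld(2)), end_a = as.integer(fld(3)),
    chrom_b = fld(4), start_b = as.integer(fld(5)), end_b = as.integer(fld(6)),
    support = as.integer(fld(8)),
    stringsAsFactors = FALSE
  )
}

empty_sv_calls <- function() {
  data.frame(id = character(), class = character(),
             chrom_a = character(), start_a = integer(), end_a = integer(),
             chrom_b = character(), start_b = integer(), end_b = integer(),
             support = integer(), stringsAsFactors = FALSE)
}

## ------------------------------------------------------------ BED, dbSNP

#' Write intervals as BED (0-based half-open)
#' @param x data.frame with columns `chrom`, `start`, `end` and optionally
#'   `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  nm <- if ("name" %in% names(x)) x$name else "."
  writeLines(paste(x$chrom, x$start, x$end, nm, sep = "\t"), path)
  invisible(path)
}

#' Read a BED file of intervals
#' @param path Path to a BED file (first 3-4 columns used).
#' @return data.frame with `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  fld <- function(i) vapply(f, `[[`, character(1), i)
  data.frame(chrom = fld(1), start = as.integer(fld(2)),
             end = as.integer(fld(3)),
             name = if (all(lengths(f) >= 4L)) fld(4) else ".",
             stringsAsFactors = FALSE)
}

#' Read a dbSNP-style catalog
#'
#' Four tab-separated columns: chrom, position (1-based), allele, type
#' (SNV/INS/DEL). Membership tests key on all four fields.
#'
#' @param path Path to the catalog file.
#' @return data.frame with 0-based `pos`.
#' @export
read_dbsnp <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "#")
  if (ncol(raw) != 4L) stop("read_dbsnp: expected 4 columns")
  cat <- data.frame(chrom = raw[[1]], pos = as.integer(raw[[2]]) - 1L,
                    allele = raw[[3]], vtype = raw[[4]],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(cat)) stop("read_dbsnp: duplicate catalog entries")
  cat
}

#' Write a dbSNP-style catalog
#' @param cat Catalog data.frame (0-based `pos`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dbsnp <- function(cat, path) {
  writeLines(paste(cat$chrom, cat$pos + 1L, cat$allele, cat$vtype,
                   sep = "\t"), path)
  invisible(path)
}
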