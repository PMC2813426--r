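# CIGAR helpers. Only the operations the pipeline emits are supported:
# M (aligned), I (insertion to the reference), D (deletion from the reference).

cigar_ops_re <- "([0-9]+)([MID])"

#' Parse CIGAR strings into run tables
#'
#' @param cigar Character vector of CIGAR strings over the M/I/D alphabet.
#' @return A list (one element per input) of data.frames with columns
#'   `len` (integer run length) and `op` (character, one of M, I, D).
#' @export
cigar_runs <- function(cigar) {
  m <- gregexpr(cigar_ops_re, cigar)
  toks <- regmatches(cigar, m)
  lapply(seq_along(cigar), function(i) {
    tk <- toks[[i]]
    if (length(tk) == 0L || paste(tk, collapse = "") != cigar[i]) {
      stop("malformed CIGAR: ", cigar[i])
    }
    data.frame(len = as.integer(sub("[MID]$", "", tk)),
               op = sub("^[0-9]+", "", tk),
               stringsAsFactors = FALSE)
  })
}

#' Reference footprint length of CIGAR strings (M + D runs)
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector of reference lengths consumed.
#' @export
cigar_ref_len <- function(cigar) {
  vapply(sum_ops(cigar, c("M", "D")), identity, integer(1))
}

#' Read length implied by CIGAR strings (M + I runs)
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector of read lengths.
#' @export
cigar_read_len <- function(cigar) {
  vapply(sum_ops(cigar, c("M", "I")), identity, integer(1))
}

sum_ops <- function(cigar, ops) {
  runs <- cigar_runs(cigar)
  lapply(runs, function(r) sum(r$len[r$op %in% ops]))
}

# TRUE for CIGARs consisting of a single M run (the overwhelmingly common
# case); lets callers skip the run parser on hot paths.
cigar_is_simple <- function(cigar) {
  grepl("^[0-9]+M$", cigar)
}

runs_to_cigar <- function(len, op) {
  paste0(paste0(len, op), collapse = "")
}
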