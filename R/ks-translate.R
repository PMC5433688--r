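#' Translate a coding sequence
#'
#' Standard genetic code; the trailing stop codon, if present, is stripped.
#' An internal (premature) stop codon is not an error: it is reported via
#' attributes so that the gene-integrity screen can consume it as a
#' disablement signal.
#'
#' @param cds Character scalar, nucleotide CDS (A/C/G/T).
#' @param pseudogene_mode Logical. If `TRUE`, a CDS whose length is not a
#'   multiple of 3 is truncated to the last complete codon instead of
#'   raising an error, and translation proceeds through internal stops
#'   (reported as `*`).
#' @return Character scalar: the protein sequence up to (not including) the
#'   first stop codon, with attributes `premature_stop` (logical: a stop
#'   occurred before the final codon) and `stop_codon_index` (integer codon
#'   index of the first stop, `NA` if none), and `full_translation` (the
#'   complete translation including `*` for stops) when a premature stop or
#'   pseudogene mode applies.
#' @export
translate_cds <- function(cds, pseudogene_mode = FALSE) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    if (!pseudogene_mode) {
      stop("CDS length ", n, " is not a multiple of 3")
    }
    cds <- substr(cds, 1L, n - (n %% 3L))
  }
  codons <- split_codons(cds)
  if (length(codons) == 0L) {
    out <- ""
    attr(out, "premature_stop") <- FALSE
    attr(out, "stop_codon_index") <- NA_integer_
    return(out)
  }
  ct <- codon_tables()
  aa <- unname(ct$aa[codons])
  aa[is.na(aa)] <- "X"
  full <- paste(aa, collapse = "")
  stop_idx <- which(aa == "*")
  first_stop <- if (length(stop_idx)) stop_idx[1L] else NA_integer_
  premature <- !is.na(first_stop) && first_stop < length(codons)
  trimmed <- if (is.na(first_stop)) full else
    paste(aa[seq_len(first_stop - 1L)], collapse = "")
  out <- trimmed
  attr(out, "premature_stop") <- premature
  attr(out, "stop_codon_index") <- first_stop
  if (premature || pseudogene_mode) attr(out, "full_translation") <- full
  out
}

#' Predicted protein length of a possibly damaged CDS
#'
#' Translates from the first codon to the first stop in the annotated
#' frame, tolerating out-of-frame (indel-bearing) sequences. This is the
#' quantity the homeolog length-ratio screen compares.
#' @param cds Character scalar CDS.
#' @return Integer: number of residues before the first stop.
#' @export
predicted_protein_length <- function(cds) {
  p <- translate_cds(cds, pseudogene_mode = TRUE)
  nchar(p)
}
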