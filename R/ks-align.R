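# Protein-guided codon alignment: global protein alignment projected back
# onto codons. Gapped columns are excluded from site counting, so the NG86
# estimator only ever sees gap-free codon pairs.

.aln_params <- function() {
  list(matrix = "BLOSUM62", gap_open = 11, gap_ext = 1)
}

.blosum62 <- function() {
  if (is.null(.ha_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .ha_cache$BLOSUM62 <- e$BLOSUM62
  }
  .ha_cache$BLOSUM62
}

#' Protein-guided codon alignment of two coding sequences
#'
#' Both sequences must translate without internal stop codons. The protein
#' sequences are aligned globally (Needleman-Wunsch, BLOSUM62, affine
#' gaps), and the alignment is projected back onto the codons, so that all
#' gaps are in multiples of 3 nucleotides by construction.
#'
#' @param cds_a,cds_b In-frame coding sequences (character scalars).
#' @param id_a,id_b Optional sequence identifiers carried into the result.
#' @return A list of class `codon_alignment`: `gene_a`, `gene_b`,
#'   `codons_a`, `codons_b` (aligned gap-free codon columns),
#'   `n_codons_compared`, `n_gap_columns`.
#' @export
align_codons <- function(cds_a, cds_b, id_a = "a", id_b = "b") {
  pa <- translate_cds(cds_a)
  pb <- translate_cds(cds_b)
  if (attr(pa, "premature_stop") || attr(pb, "premature_stop")) {
    stop("cannot codon-align a CDS with an internal stop codon")
  }
  if (nchar(pa) == 0L || nchar(pb) == 0L) {
    stop("cannot codon-align an empty translation")
  }
  codons_a <- split_codons(toupper(cds_a))[seq_len(nchar(pa))]
  codons_b <- split_codons(toupper(cds_b))[seq_len(nchar(pb))]

  # equal-length, clearly homologous proteins align without gaps: the
  # column pairing is the identity and the DP is skipped
  if (nchar(pa) == nchar(pb)) {
    ident <- mean(strsplit(pa, "")[[1L]] == strsplit(pb, "")[[1L]])
    if (ident >= 0.7) {
      out <- list(
        gene_a = id_a, gene_b = id_b,
        codons_a = codons_a, codons_b = codons_b,
        n_codons_compared = length(codons_a), n_gap_columns = 0L
      )
      class(out) <- "codon_alignment"
      return(out)
    }
  }

  prm <- .aln_params()
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    substitutionMatrix = .blosum62(),
    gapOpening = prm$gap_open, gapExtension = prm$gap_ext,
    type = "global"
  )
  sa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  ia <- 0L; ib <- 0L
  keep_a <- integer(0L); keep_b <- integer(0L)
  ngap <- 0L
  for (k in seq_along(sa)) {
    ga <- sa[k] == "-"; gb <- sb[k] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (!ga && !gb) {
      keep_a <- c(keep_a, ia); keep_b <- c(keep_b, ib)
    } else {
      ngap <- ngap + 1L
    }
  }
  out <- list(
    gene_a = id_a, gene_b = id_b,
    codons_a = codons_a[keep_a], codons_b = codons_b[keep_b],
    n_codons_compared = length(keep_a), n_gap_columns = ngap
  )
  class(out) <- "codon_alignment"
  out
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("Codon alignment %s vs %s: %d codon columns (%d gapped excluded)\n",
              x$gene_a, x$gene_b, x$n_codons_compared, x$n_gap_columns))
  invisible(x)
}
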