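#' Simulate a parent genome
#'
#' Generates parent A: `n_chromosomes_per_parent` chromosomes carrying
#' `n_genes` protein-coding genes in total. Every gene is a valid CDS
#' (start codon, no internal stop, stop codon) on a random strand; genes
#' are separated by random intergenic spacers and every chromosome end
#' carries a tandem telomeric repeat array (left ends hold the reverse
#' complement of the unit, as on a real chromosome).
#'
#' @param config A [sim_config()].
#' @return A `sim_genome` (parent A); convert with [as_annotated_genome()].
#' @export
simulate_parent <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_chr <- config$n_chromosomes_per_parent
  n_genes <- config$n_genes
  # as-even-as-possible distribution of genes over chromosomes
  per <- rep(n_genes %/% n_chr, n_chr)
  extra <- n_genes %% n_chr
  if (extra > 0L) per[seq_len(extra)] <- per[seq_len(extra)] + 1L

  sense <- sense_codons()
  L <- config$gene_length_codons
  tel <- strrep(toupper(config$telomere_unit), config$telomere_copies)
  id_width <- max(4L, nchar(as.character(max(n_genes, 1L))))
  fmt <- paste0("g%0", id_width, "d")

  gid <- 0L
  chroms <- vector("list", n_chr)
  for (ci in seq_len(n_chr)) {
    ng <- per[ci]
    if (ng > 0L) {
      internal <- matrix(sample(sense, ng * (L - 2L), replace = TRUE),
                         nrow = ng)
      cds <- vapply(seq_len(ng), function(i) {
        paste0("ATG", paste(internal[i, ], collapse = ""), "TAA")
      }, character(1L))
      genes <- data.frame(
        gene_id = sprintf(fmt, gid + seq_len(ng)),
        cds = cds,
        strand = sample(c("+", "-"), ng, replace = TRUE),
        stringsAsFactors = FALSE
      )
      gid <- gid + ng
    } else {
      genes <- data.frame(gene_id = character(0L), cds = character(0L),
                          strand = character(0L), stringsAsFactors = FALSE)
    }
    spacers <- vapply(seq_len(ng + 1L), function(i) {
      random_dna(config$spacer_len)
    }, character(1L))
    chroms[[ci]] <- .sim_chromosome(
      name = sprintf("chrA_%02d", ci), genes = genes, spacers = spacers,
      tel_l = revcomp(tel), tel_r = tel
    )
  }
  .sim_genome(chroms, parent = "A")
}
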