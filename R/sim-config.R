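# Simulation configuration. The defaults are the study conditions the
# package is calibrated against: two 8-chromosome parents, ~1,000 genes,
# a synonymous divergence peak at Ks = 0.16, 17 pre-hybridization
# rearrangements, and a small number of post-hybridization LOH,
# recombination, BIR and gene-disablement events.

#' Mating-type cassette specification
#'
#' Describes the X/Z repeat architecture of the MAT, HML and HMR loci, the
#' idiomorph gene stubs placed between them (alpha1, alpha2, a2; there is
#' deliberately no a1 gene anywhere), and the target-site duplication
#' lengths of the HO-induced breakage junctions.
#'
#' @param x_len Length of the X repeat (654 bp).
#' @param z_len Length of the Z repeat (266 bp); the repeat always begins
#'   with the HO cleavage core `cgcagca`.
#' @param ho_core The HO cleavage-site core heptamer.
#' @param tsd_left_len Length of the target-site duplication taken from
#'   the non-MAT (intergenic) side of the breakage (default 5, the
#'   `acaac`-type duplication).
#' @param tsd_right_len Length of the duplication taken from the MAT side
#'   (default 2, the `ca`-type duplication).
#' @param mat_chrom Index (within each subgenome) of the chromosome that
#'   carries the cassettes (default 7).
#' @param breakage Whether to simulate the HO-catalysed breakage of the
#'   B-subgenome MAT locus (default `TRUE`).
#' @param x_repeat,z_repeat Optional explicit repeat sequences; generated
#'   from the run seed when `NULL`. A supplied `z_repeat` must begin with
#'   the core heptamer.
#' @return A list of class `mat_spec`.
#' @export
mat_spec <- function(x_len = 654L, z_len = 266L, ho_core = "cgcagca",
                     tsd_left_len = 5L, tsd_right_len = 2L,
                     mat_chrom = 7L, breakage = TRUE,
                     x_repeat = NULL, z_repeat = NULL) {
  stopifnot(x_len >= 200L, z_len >= nchar(ho_core) + 100L,
            tsd_left_len >= 0L, tsd_right_len >= 0L,
            tsd_right_len <= 4L) # drawn from within the 4-nt overhang core
  if (!is.null(z_repeat) &&
      toupper(substr(z_repeat, 1L, nchar(ho_core))) != toupper(ho_core)) {
    stop("z_repeat must begin with the HO core ", ho_core)
  }
  structure(list(
    x_len = as.integer(x_len), z_len = as.integer(z_len),
    ho_core = toupper(ho_core),
    tsd_left_len = as.integer(tsd_left_len),
    tsd_right_len = as.integer(tsd_right_len),
    mat_chrom = as.integer(mat_chrom), breakage = isTRUE(breakage),
    x_repeat = if (is.null(x_repeat)) NULL else toupper(x_repeat),
    z_repeat = if (is.null(z_repeat)) NULL else toupper(z_repeat)
  ), class = "mat_spec")
}

#' Hybrid-genome simulation configuration
#'
#' @param n_chromosomes_per_parent Chromosomes per parent (default 8).
#' @param n_genes Total genes per parent genome (default 1000).
#' @param gene_length_codons Codons per gene including start and stop
#'   (default 500).
#' @param spacer_len Intergenic spacer length in bp (default 200).
#' @param target_ks Expected synonymous divergence between the parents
#'   (default 0.16, the observed divergence peak); must be below the
#'   Jukes-Cantor saturation bound 0.75.
#' @param omega Acceptance probability of nonsynonymous changes during the
#'   divergence process, i.e. the Ka/Ks ratio of the simulation
#'   (default 0.05).
#' @param n_rearrangements Inversions + reciprocal translocations between
#'   the parents (default 17); each event creates 2 synteny breakpoints
#'   and no breakpoint is reused.
#' @param rearrangement_mix Fraction of events that are inversions, the
#'   remainder being reciprocal translocations (default 0.5).
#' @param loh_lengths Integer vector of LOH tract lengths in genes, one
#'   tract per element. The default plants ten tracts of 1 to 8 genes,
#'   including one 8-gene tract mirroring the multi-gene runs seen on real
#'   hybrid chromosomes.
#' @param p_loh_donor_a Probability that an LOH tract is an A-overwrites-B
#'   event (default 0.78, the observed A:A / (A:A + B:B) proportion).
#' @param n_recombinations Interhomeolog reciprocal crossovers (default 3).
#' @param bir_ends Break-induced replication events, each homogenising two
#'   chromosome ends (default 3).
#' @param bir_len_genes Genes copied per BIR event (default 8).
#' @param n_disablements_per_subgenome Disabling mutations (1-bp indels or
#'   premature stops) planted per subgenome (default 10).
#' @param telomere_unit Telomeric repeat unit (default `tgtgggtgggg`).
#' @param telomere_copies Tandem copies of the unit per chromosome end
#'   (default 20).
#' @param mat_spec A [mat_spec()].
#' @param seed Integer seed; the whole simulation is a deterministic
#'   function of the configuration including this seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes_per_parent = 8L,
                       n_genes = 1000L,
                       gene_length_codons = 500L,
                       spacer_len = 200L,
                       target_ks = 0.16,
                       omega = 0.05,
                       n_rearrangements = 17L,
                       rearrangement_mix = 0.5,
                       loh_lengths = c(8L, 5L, 4L, 4L, 3L, 3L, 3L, 2L, 2L, 1L),
                       p_loh_donor_a = 0.78,
                       n_recombinations = 3L,
                       bir_ends = 3L,
                       bir_len_genes = 8L,
                       n_disablements_per_subgenome = 10L,
                       telomere_unit = "tgtgggtgggg",
                       telomere_copies = 20L,
                       mat_spec = hybridarch::mat_spec(),
                       seed = 1L) {
  cfg <- list(
    n_chromosomes_per_parent = as.integer(n_chromosomes_per_parent),
    n_genes = as.integer(n_genes),
    gene_length_codons = as.integer(gene_length_codons),
    spacer_len = as.integer(spacer_len),
    target_ks = target_ks, omega = omega,
    n_rearrangements = as.integer(n_rearrangements),
    rearrangement_mix = rearrangement_mix,
    loh_lengths = as.integer(loh_lengths),
    p_loh_donor_a = p_loh_donor_a,
    n_recombinations = as.integer(n_recombinations),
    bir_ends = as.integer(bir_ends),
    bir_len_genes = as.integer(bir_len_genes),
    n_disablements_per_subgenome = as.integer(n_disablements_per_subgenome),
    telomere_unit = tolower(telomere_unit),
    telomere_copies = as.integer(telomere_copies),
    mat_spec = mat_spec,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_chromosomes_per_parent, cfg$n_genes,
              cfg$n_rearrangements, cfg$n_recombinations, cfg$bir_ends,
              cfg$n_disablements_per_subgenome, cfg$loh_lengths)
  if (any(counts < 0L)) stop("configuration error: negative count")
  if (cfg$n_chromosomes_per_parent < 1L) {
    stop("configuration error: need at least 1 chromosome")
  }
  if (cfg$target_ks < 0 || cfg$target_ks >= 0.75) {
    stop("configuration error: target_ks must lie in [0, 0.75) ",
         "(Jukes-Cantor saturation)")
  }
  if (cfg$omega < 0 || cfg$omega > 1) {
    stop("configuration error: omega must lie in [0, 1]")
  }
  if (cfg$rearrangement_mix < 0 || cfg$rearrangement_mix > 1) {
    stop("configuration error: rearrangement_mix must lie in [0, 1]")
  }
  if (cfg$gene_length_codons < 3L) {
    stop("configuration error: genes need start, one internal and stop codon")
  }
  invisible(TRUE)
}
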