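# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

small_cfg <- function(seed = 7) {
  sim_config(n_chromosomes_per_parent = 4L, n_genes = 120L,
             gene_length_codons = 100L, n_rearrangements = 4L,
             loh_lengths = c(8L, 3L), n_recombinations = 1L,
             bir_ends = 1L, bir_len_genes = 6L,
             n_disablements_per_subgenome = 2L,
             mat_spec = mat_spec(mat_chrom = 2L), seed = seed)
}

small_sim <- function() {
  if (is.null(.fixture_env$small_sim)) {
    .fixture_env$small_sim <- simulate_hybrid_genome(small_cfg())
  }
  .fixture_env$small_sim
}

small_pipeline <- function() {
  if (is.null(.fixture_env$small_pipe)) {
    .fixture_env$small_pipe <- run_pipeline(
      pipeline_config(seed = 7, sim = small_cfg())
    )
  }
  .fixture_env$small_pipe
}

# the default study-condition pipeline, shared by the acceptance tests
default_pipeline <- function() {
  if (is.null(.fixture_env$default_pipe)) {
    .fixture_env$default_pipe <- run_pipeline(pipeline_config(seed = 101))
  }
  .fixture_env$default_pipe
}

# order tables (named list of data.frame(gene_id, strand)) from an
# annotated genome, for the brute-force breakpoint oracle
orders_of <- function(genome) {
  lapply(split(genome$genes, genome$genes$chrom), function(df) {
    df <- df[order(df$index), , drop = FALSE]
    data.frame(gene_id = df$gene_id, strand = df$strand,
               stringsAsFactors = FALSE)
  })
}

# random in-frame CDS built from the oracle's code table
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- names(.oracle_code)[.oracle_code != "*"]
  paste0("ATG", paste(sample(sense, n_codons - 2, replace = TRUE),
                      collapse = ""), "TAA")
}
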