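# Orchestration: genome I/O round-trips, pipeline summary schema,
# determinism.

test_that("FASTA + GFF3 round-trip preserves sequences and gene models", {
  g <- small_sim()$genome
  fa <- tempfile(fileext = ".fa")
  gff <- tempfile(fileext = ".gff3")
  write_genome(g, fa, gff)
  back <- read_genome(fa, gff)
  expect_identical(back$seq, g$seq)
  m <- match(g$genes$gene_id, back$genes$gene_id)
  expect_false(anyNA(m))
  expect_equal(back$genes$start[m], g$genes$start)
  expect_equal(back$genes$end[m], g$genes$end)
  expect_equal(back$genes$strand[m], g$genes$strand)
  # coordinates extract the same coding sequences after the round trip
  expect_identical(extract_cds(back)[g$genes$gene_id],
                   extract_cds(g)[g$genes$gene_id])
})

test_that("the pipeline summary carries every stage section", {
  pipe <- small_pipeline()
  s <- pipe$summary
  expect_true(all(c("seed", "config_hash", "genome", "categories",
                    "pair_types", "breakpoints", "loh", "junctions",
                    "bir", "telomere", "mat", "integrity", "recovery")
                  %in% names(s)))
  expect_equal(s$genome$n_chromosomes, 8L)
  expect_equal(s$mat$n_regions, 6L)
  expect_equal(s$telomere$unit,
               hybridarch:::min_rotation("tgtgggtgggg"))
  p <- tempfile(fileext = ".json")
  write_summary(pipe, p)
  parsed <- jsonlite::read_json(p)
  expect_equal(parsed$genome$n_genes, s$genome$n_genes)
})

test_that("rerunning the pipeline with the same configuration is identical", {
  cfg <- pipeline_config(seed = 23, sim = small_cfg(seed = 23))
  r1 <- run_pipeline(cfg)
  r2 <- run_pipeline(cfg)
  j1 <- jsonlite::toJSON(r1$summary, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  j2 <- jsonlite::toJSON(r2$summary, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  expect_identical(as.character(j1), as.character(j2))
})
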