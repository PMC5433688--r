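# Hybrid-genome simulator: parents, divergence, rearrangements,
# hybridization, post-hybridization events, determinism.

test_that("simulate_parent produces valid genes and structure", {
  cfg <- sim_config(n_chromosomes_per_parent = 3, n_genes = 30,
                    gene_length_codons = 50, seed = 3)
  p <- simulate_parent(cfg)
  expect_length(p$chroms, 3L)
  g <- as_annotated_genome(p)
  expect_equal(nrow(g$genes), 30L)
  cds <- extract_cds(g)
  for (s in cds) {
    expect_equal(substr(s, 1, 3), "ATG")
    pr <- translate_cds(s)
    expect_false(attr(pr, "premature_stop"))
    expect_equal(nchar(pr), 49L)
  }
})

test_that("an empty gene complement is a valid genome", {
  cfg <- sim_config(n_chromosomes_per_parent = 2, n_genes = 0,
                    n_rearrangements = 0, seed = 1)
  g <- as_annotated_genome(simulate_parent(cfg))
  expect_length(g$seq, 2L)
  expect_equal(nrow(g$genes), 0L)
  expect_true(all(nchar(g$seq) > 0))
})

test_that("the same seed reproduces byte-identical output", {
  cfg <- small_cfg(seed = 19)
  r1 <- simulate_hybrid_genome(cfg)
  r2 <- simulate_hybrid_genome(cfg)
  expect_identical(r1$genome$seq, r2$genome$seq)
  expect_identical(r1$genome$genes, r2$genome$genes)
  expect_identical(r1$truth$genes, r2$truth$genes)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_simulation(r1, d1)
  write_simulation(r2, d2)
  for (f in c("hybrid.fa", "hybrid.gff3", "truth_genes.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("zero target divergence returns identical sequences", {
  cfg <- sim_config(n_chromosomes_per_parent = 2, n_genes = 10,
                    gene_length_codons = 50, seed = 5)
  p <- simulate_parent(cfg)
  b <- evolve_divergence(p, target_ks = 0, seed = 6)
  expect_identical(
    unname(extract_cds(as_annotated_genome(p))),
    unname(extract_cds(as_annotated_genome(b)))
  )
  expect_error(evolve_divergence(p, target_ks = 0.8), "saturat")
})

test_that("divergence realises the target Ks on re-estimation", {
  cfg <- sim_config(n_chromosomes_per_parent = 2, n_genes = 40,
                    gene_length_codons = 300, seed = 9)
  p <- simulate_parent(cfg)
  b <- evolve_divergence(p, target_ks = 0.16, omega = 0.05, seed = 10)
  cds_a <- extract_cds(as_annotated_genome(p))
  cds_b <- extract_cds(as_annotated_genome(b))
  ks <- vapply(seq_along(cds_a), function(i) {
    ks_between(cds_a[[i]], cds_b[[i]])$Ks
  }, numeric(1))
  se <- sd(ks) / sqrt(length(ks))
  expect_lt(abs(mean(ks) - 0.16), 3 * se + 0.005)
  # a nearly-undiverged parent is classified A-like
  b2 <- evolve_divergence(p, target_ks = 0.005, seed = 11)
  cds_b2 <- extract_cds(as_annotated_genome(b2))
  ks2 <- vapply(seq_along(cds_a), function(i) {
    ks_between(cds_a[[i]], cds_b2[[i]])$Ks
  }, numeric(1))
  expect_lte(mean(ks2), 0.05)
})

test_that("rearrangements create exactly two breakpoints each, no reuse", {
  cfg <- sim_config(n_chromosomes_per_parent = 3, n_genes = 90,
                    gene_length_codons = 20, seed = 13)
  p <- simulate_parent(cfg)
  before <- orders_of(as_annotated_genome(p))
  re0 <- apply_rearrangements(p, 0, seed = 14)
  expect_identical(.subset2(re0, "genome")$chroms[[1]]$genes$gene_id,
                   p$chroms[[1]]$genes$gene_id)
  for (n_ev in c(1L, 5L)) {
    re <- apply_rearrangements(p, n_ev, mix = 0.5, seed = 14)
    after <- orders_of(as_annotated_genome(re$genome))
    expect_equal(oracle_breakpoints(after, before), 2L * n_ev)
  }
})

test_that("the event log replays to the emitted gene order", {
  cfg <- sim_config(n_chromosomes_per_parent = 3, n_genes = 60,
                    gene_length_codons = 20, seed = 21)
  p <- simulate_parent(cfg)
  re <- apply_rearrangements(p, 6, seed = 22)
  replayed <- replay_rearrangements(orders_of(as_annotated_genome(p)),
                                    re$events)
  emitted <- orders_of(as_annotated_genome(re$genome))
  for (nm in names(emitted)) {
    expect_identical(replayed[[nm]]$gene_id, emitted[[nm]]$gene_id)
    expect_identical(replayed[[nm]]$strand, emitted[[nm]]$strand)
  }
})

test_that("hybridization unions chromosomes and initialises truth", {
  cfg <- sim_config(n_chromosomes_per_parent = 4, n_genes = 40,
                    gene_length_codons = 20, n_rearrangements = 2,
                    seed = 31)
  p <- simulate_parent(cfg)
  b <- apply_rearrangements(
    evolve_divergence(p, 0.16, seed = 32), 2, seed = 33)$genome
  hy <- hybridize(p, b)
  expect_length(hy$genome$chroms, 8L)
  expect_equal(nrow(hy$truth$genes), 80L)
  expect_setequal(unique(hy$truth$genes$true_subgenome), c("A", "B"))
  expect_equal(sum(hy$truth$genes$true_subgenome == "A"), 40L)
  expect_error(hybridize(p, p), "duplicate chromosome")
})

test_that("post-hybridization events are recorded and reversible cases hold", {
  # all event counts zero: hybrid unchanged
  cfg0 <- sim_config(n_chromosomes_per_parent = 2, n_genes = 30,
                     gene_length_codons = 30, n_rearrangements = 0,
                     loh_lengths = integer(0), n_recombinations = 0,
                     bir_ends = 0, n_disablements_per_subgenome = 0,
                     seed = 41)
  p <- simulate_parent(cfg0)
  b <- evolve_divergence(p, 0.16, seed = 42)
  hy <- hybridize(p, b)
  ph <- apply_posthyb_events(hy$genome, hy$truth, cfg0, seed = 43)
  expect_identical(as_annotated_genome(ph$genome)$seq,
                   as_annotated_genome(hy$genome)$seq)
  expect_identical(ph$truth$genes, hy$truth$genes)
})

test_that("a planted LOH tract overwrites sequence and truth", {
  sim <- small_sim()
  tr <- sim$truth$loh[[1]]
  expect_equal(tr$length, 8L)
  cds <- extract_cds(sim$genome)
  for (i in seq_along(tr$gene_ids)) {
    expect_identical(cds[[tr$gene_ids[i]]], cds[[tr$partner_ids[i]]])
  }
  tg <- sim$truth$genes
  rownames(tg) <- tg$gene_id
  expect_true(all(tg[tr$gene_ids, "true_subgenome"] == tr$donor))
  expect_true(all(tg[tr$gene_ids, "true_category"] ==
                    paste0(tr$donor, "-in-", tr$donor, ":", tr$donor)))
})

test_that("BIR leaves the two chromosome ends identical to the telomere", {
  sim <- small_sim()
  ev <- sim$truth$bir[[1]]
  sd_ <- sim$genome$seq[[ev$donor_chrom]]
  sr_ <- sim$genome$seq[[ev$recipient_chrom]]
  n <- 2000L  # deep into the copied terminal segment
  if (ev$donor_side == "R") {
    expect_identical(substr(sd_, nchar(sd_) - n + 1L, nchar(sd_)),
                     substr(sr_, nchar(sr_) - n + 1L, nchar(sr_)))
  } else {
    expect_identical(substr(sd_, 1L, n), substr(sr_, 1L, n))
  }
})

test_that("gene count and reading frames survive the full scenario", {
  sim <- small_sim()
  cfg <- small_cfg()
  expected <- 2L * cfg$n_genes  # copies replace deleted genes 1:1
  expect_equal(nrow(sim$genome$genes), expected)
  # every gene in the emitted genome appears exactly once in the truth
  expect_setequal(sim$genome$genes$gene_id, sim$truth$genes$gene_id)
  # undisabled genes still translate cleanly
  disabled <- sim$truth$disabled_table$gene_id
  cds <- extract_cds(sim$genome)
  ok <- setdiff(names(cds), disabled)
  bad <- vapply(cds[ok], function(s) {
    nchar(s) %% 3L != 0L ||
      isTRUE(attr(translate_cds(s, pseudogene_mode = TRUE),
                  "premature_stop"))
  }, logical(1))
  expect_false(any(bad))
})
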