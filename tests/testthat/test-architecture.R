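# Gene-order comparison, breakpoints, LOH tracts, junctions, BIR flags,
# telomere consensus.

toy_order <- function(ids, chrom = "c1", strands = NULL) {
  data.frame(gene_id = ids, chrom = chrom, index = seq_along(ids),
             strand = if (is.null(strands)) rep("+", length(ids)) else
               strands,
             stringsAsFactors = FALSE)
}

test_that("identical orders have zero breakpoints and one block", {
  x <- toy_order(paste0("g", 1:10))
  bp <- count_breakpoints(x, x)
  expect_equal(bp$count, 0L)
  blocks <- build_synteny_blocks(x, x)
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$orientation, "+")
  expect_equal(blocks$n_genes, 10L)
})

test_that("one inversion gives two breakpoints and a reversed middle block", {
  x <- toy_order(paste0("g", 1:9))
  y <- toy_order(c("g1", "g2", "g6", "g5", "g4", "g3", "g7", "g8", "g9"),
                 strands = c("+", "+", "-", "-", "-", "-", "+", "+", "+"))
  bp <- count_breakpoints(x, y)
  expect_equal(bp$count, 2L)
  blocks <- build_synteny_blocks(x, y)
  expect_equal(nrow(blocks), 3L)
  expect_equal(blocks$orientation, c("+", "-", "+"))
})

test_that("one reciprocal translocation gives two breakpoints", {
  x <- rbind(toy_order(paste0("a", 1:5), "c1"),
             toy_order(paste0("b", 1:5), "c2"))
  y <- rbind(toy_order(c("a1", "a2", "b4", "b5"), "d1"),
             toy_order(c("b1", "b2", "b3", "a3", "a4", "a5"), "d2"))
  bp <- count_breakpoints(x, y)
  expect_equal(bp$count, 2L)
  # direction symmetry for one-to-one maps
  expect_equal(count_breakpoints(y, x)$count, 2L)
})

test_that("breakpoint counting agrees with the adjacency oracle on random permutations", {
  set.seed(77)
  for (rep in 1:10) {
    ids <- paste0("g", 1:30)
    x <- list(c1 = data.frame(gene_id = ids[1:15], strand = "+"),
              c2 = data.frame(gene_id = ids[16:30], strand = "+"))
    shuffled <- sample(ids)
    y <- list(c1 = data.frame(gene_id = shuffled[1:15],
                              strand = sample(c("+", "-"), 15, TRUE)),
              c2 = data.frame(gene_id = shuffled[16:30],
                              strand = sample(c("+", "-"), 15, TRUE)))
    to_tab <- function(lst) do.call(rbind, lapply(names(lst), function(nm) {
      data.frame(gene_id = lst[[nm]]$gene_id, chrom = nm,
                 index = seq_len(nrow(lst[[nm]])),
                 strand = lst[[nm]]$strand, stringsAsFactors = FALSE)
    }))
    expect_equal(count_breakpoints(to_tab(x), to_tab(y))$count,
                 oracle_breakpoints(x, y))
  }
})

test_that("event estimation halves the breakpoint count", {
  expect_equal(estimate_events(0), 0L)
  expect_equal(estimate_events(34), 17L)
  expect_warning(ev <- estimate_events(7), "odd")
  expect_equal(ev, 3L)
  expect_error(estimate_events(-2), "negative")
})

toy_track <- function(labels, categories, chrom = "c1") {
  data.frame(gene_id = paste0(chrom, "_g", seq_along(labels)),
             chrom = chrom, index = seq_along(labels),
             label = labels, category = categories,
             stringsAsFactors = FALSE)
}

test_that("LOH segmentation finds multi-gene runs and obeys min_run", {
  # homogeneous chromosome: nothing to report
  t1 <- toy_track(rep("B", 10), rep("B-in-A:B", 10))
  expect_equal(nrow(segment_loh_tracts(t1)), 0L)
  # an 8-gene A:A run inside a B background
  labs <- c(rep("B", 5), rep("A", 8), rep("B", 5))
  cats <- c(rep("B-in-A:B", 5), rep("A-in-A:A", 8), rep("B-in-A:B", 5))
  tr <- segment_loh_tracts(toy_track(labs, cats))
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$start_index, 6L)
  expect_equal(tr$end_index, 13L)
  expect_equal(tr$length, 8L)
  expect_equal(tr$tract_class, "A")
  expect_equal(tr$background, "B")
  # alternating genes never reach min_run 3
  alt <- toy_track(rep(c("A", "B"), 6),
                   rep(c("A-in-A:A", "B-in-A:B"), 6))
  expect_equal(nrow(segment_loh_tracts(alt, min_run = 3)), 0L)
})

test_that("N genes are transparent inside an LOH run", {
  labs <- c(rep("B", 4), "A", "A", "N", "A", "A", rep("B", 4))
  cats <- c(rep("B-in-A:B", 4), rep("A-in-A:A", 2), "N",
            rep("A-in-A:A", 2), rep("B-in-A:B", 4))
  tr <- segment_loh_tracts(toy_track(labs, cats), min_run = 3)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$length, 4L)        # 4 A:A genes, N not counted
  expect_equal(tr$start_index, 5L)
  expect_equal(tr$end_index, 9L)     # spans the transparent N gene
})

test_that("junction detection distinguishes crossovers from LOH", {
  # single crossover mid-chromosome
  labs <- c(rep("A", 6), rep("B", 6))
  cats <- paste0(labs, "-in-A:B")
  j <- detect_recombination_junctions(toy_track(labs, cats))
  expect_equal(nrow(j), 1L)
  expect_equal(j$left_index, 6L)
  expect_equal(j$right_index, 7L)
  # pure chromosome: nothing
  expect_equal(nrow(detect_recombination_junctions(
    toy_track(rep("A", 10), rep("A-in-A:B", 10)))), 0L)
  # an LOH tract internal to a B chromosome is not a crossover
  labs2 <- c(rep("B", 5), rep("A", 4), rep("B", 5))
  cats2 <- c(rep("B-in-A:B", 5), rep("A-in-A:A", 4), rep("B-in-A:B", 5))
  expect_equal(nrow(detect_recombination_junctions(
    toy_track(labs2, cats2))), 0L)
})

test_that("BIR flags pair identical homogenised ends", {
  pipe <- small_pipeline()
  ev <- pipe$sim$truth$bir[[1]]
  fl <- pipe$bir$flags
  expect_equal(nrow(fl), 1L)
  ends <- c(paste0(fl$chrom, fl$side),
            paste0(fl$partner_chrom, fl$partner_side))
  expect_setequal(ends, c(paste0(ev$donor_chrom, ev$donor_side),
                          paste0(ev$recipient_chrom, ev$recipient_side)))
  expect_gte(fl$identity, 0.95)
})

test_that("telomere consensus recovers the repeat unit up to rotation", {
  unit <- "tgtgggtgggg"
  ends <- rep(toupper(strrep(unit, 25)), 4)
  res <- telomere_consensus(ends)
  expect_equal(res$unit, hybridarch:::min_rotation(unit))
  # poly-A ends reduce to unit "a"
  resA <- telomere_consensus(rep(strrep("A", 120), 3))
  expect_equal(resA$unit, "a")
  # mixed units: majority wins, minority reported
  six <- strrep("ACGTTG", 40)
  mixed <- c(rep(toupper(strrep(unit, 25)), 3), six, six)
  resM <- telomere_consensus(mixed)
  expect_equal(resM$unit, hybridarch:::min_rotation(unit))
  expect_equal(nrow(resM$units), 2L)
  expect_equal(sort(resM$units$n_ends), c(2L, 3L))
  # full genome: all simulated ends carry the configured unit
  g <- small_sim()$genome
  resG <- telomere_consensus(g)
  expect_equal(resG$unit, hybridarch:::min_rotation(unit))
})
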