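# Subgenome labels, pair types, 7-category map, BED round-trip.

test_that("label thresholds are inclusive at the boundaries", {
  expect_equal(assign_subgenome(0.03), "A")
  expect_equal(assign_subgenome(0.05), "A")
  expect_equal(assign_subgenome(0.0500001), "B")
  expect_equal(assign_subgenome(0.16), "B")
  expect_equal(assign_subgenome(0.25), "B")
  expect_equal(assign_subgenome(0.2500001), "N")
  expect_equal(assign_subgenome(0.30), "N")
  expect_equal(assign_subgenome(NA_real_), "N")
  expect_error(assign_subgenome(-0.1), "negative")
  # idempotent, order-independent, vectorised
  ks <- c(0.01, 0.2, 0.4, NA)
  expect_equal(assign_subgenome(ks), c("A", "B", "N", "N"))
  expect_equal(assign_subgenome(rev(ks)), rev(assign_subgenome(ks)))
})

test_that("pair typing follows member labels", {
  expect_equal(type_pairs("A", "B"), "A:B")
  expect_equal(type_pairs("B", "A"), "A:B")
  expect_equal(type_pairs("A", "A"), "A:A")
  expect_equal(type_pairs("B", "B"), "B:B")
  expect_equal(type_pairs("A", "N"), "other")
  expect_equal(type_pairs(c("A", "N"), c("B", "N")), c("A:B", "other"))
})

test_that("categorization partitions the gene set", {
  genes <- data.frame(
    gene_id = paste0("g", 1:8),
    chrom = rep(c("c1", "c2"), each = 4),
    index = rep(1:4, 2),
    start = rep(c(10, 110, 210, 310), 2),
    end = rep(c(100, 200, 300, 400), 2),
    stringsAsFactors = FALSE
  )
  labels <- c(g1 = "A", g2 = "B", g3 = "A", g4 = "A",
              g5 = "B", g6 = "N", g7 = "A", g8 = "B")
  pairs <- data.frame(gene_a = c("g1", "g3", "g5"),
                      gene_b = c("g2", "g4", "g6"))
  cz <- categorize(genes, labels, pairs)
  got <- stats::setNames(cz$genes$category, cz$genes$gene_id)
  expect_equal(got[["g1"]], "A-in-A:B")
  expect_equal(got[["g2"]], "B-in-A:B")
  expect_equal(got[["g3"]], "A-in-A:A")
  expect_equal(got[["g4"]], "A-in-A:A")
  expect_equal(got[["g5"]], "B-unpaired")  # paired with an N gene
  expect_equal(got[["g6"]], "N")
  expect_equal(got[["g7"]], "A-unpaired")
  expect_equal(sum(cz$counts), nrow(genes))
  expect_error(
    categorize(genes, labels,
               data.frame(gene_a = c("g1", "g1"), gene_b = c("g2", "g3"))),
    "two pairs"
  )
})

test_that("an empty chromosome yields an empty track", {
  genes <- data.frame(gene_id = "g1", chrom = "c1", index = 1L,
                      start = 1L, end = 30L, stringsAsFactors = FALSE)
  cz <- categorize(genes, c(g1 = "A"),
                   data.frame(gene_a = character(0),
                              gene_b = character(0)))
  expect_length(cz$tracks, 1L)
  expect_equal(nrow(cz$tracks[["c1"]]), 1L)
})

test_that("BED export is 0-based half-open and round-trips", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "c1",
                      start = c(101L, 501L), end = c(400L, 900L),
                      category = c("A-in-A:B", "B-in-A:B"),
                      stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".bed")
  write_category_bed(genes, path)
  raw <- read.table(path, sep = "\t")
  expect_equal(raw$V2, c(100L, 500L))  # 0-based starts
  expect_equal(raw$V3, c(400L, 900L))  # half-open ends
  back <- read_category_bed(path)
  expect_equal(back$start, genes$start)
  expect_equal(back$end, genes$end)
  expect_equal(back$category, genes$category)
})

test_that("subgenome labels reach 99% accuracy under the default conditions", {
  rec <- default_pipeline()$recovery
  expect_gte(rec$label_accuracy, 0.99)
})

test_that("classification recovers truth on a clean simulated hybrid", {
  pipe <- small_pipeline()
  rec <- pipe$recovery
  # at 100-codon genes a few percent of B genes stray over the N
  # threshold purely by estimation noise; the bulk must be correct
  expect_gte(rec$label_accuracy, 0.9)
  expect_gte(rec$category_accuracy, 0.85)
  expect_equal(sum(pipe$classification$counts),
               nrow(pipe$sim$genome$genes))
})
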