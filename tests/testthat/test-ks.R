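# Synonymous divergence estimation: translation, codon alignment, NG86
# counting with Jukes-Cantor correction.

test_that("translation follows the standard code and flags damage", {
  expect_equal(as.character(translate_cds("ATGGGGTAA")), "MG")
  expect_false(attr(translate_cds("ATGGGGTAA"), "premature_stop"))
  expect_error(translate_cds("ATGGGGTAAA"), "multiple of 3")
  p <- translate_cds("ATGTAAGGGTAA")
  expect_true(attr(p, "premature_stop"))
  expect_equal(attr(p, "stop_codon_index"), 2L)
  expect_equal(as.character(p), "M")
  # pseudogene mode tolerates out-of-frame tails
  expect_equal(predicted_protein_length("ATGGGGTAAA"), 2L)
})

test_that("identical sequences give zero divergence", {
  cds <- random_cds(60, seed = 1)
  e <- ks_between(cds, cds)
  expect_equal(e$Ks, 0)
  expect_equal(e$Ka, 0)
  expect_equal(e$Sd, 0)
  expect_equal(e$Nd, 0)
})

test_that("fourfold-degenerate codons count per NG86", {
  # 100 glycine codons; 3 third-position differences. Each GGN codon has
  # exactly one synonymous site (the third position), so S = 100, Sd = 3.
  a <- rep("GGA", 100)
  b <- a
  b[c(5, 50, 95)] <- "GGC"
  e <- estimate_ks(list(codons_a = a, codons_b = b))
  expect_equal(e$S, 100)
  expect_equal(e$Sd, 3)
  expect_equal(e$Nd, 0)
  expect_equal(e$Ks, -0.75 * log(1 - (4 / 3) * 0.03))
})

test_that("site counts are conserved and the estimate is symmetric", {
  set.seed(42)
  sense <- names(.oracle_code)[.oracle_code != "*"]
  for (rep in 1:5) {
    a <- sample(sense, 50, replace = TRUE)
    b <- sample(sense, 50, replace = TRUE)
    e <- estimate_ks(list(codons_a = a, codons_b = b))
    expect_equal(e$S + e$N, 3 * e$n_codons)
    r <- estimate_ks(list(codons_a = b, codons_b = a))
    expect_equal(e$S, r$S)
    expect_equal(e$Sd, r$Sd)
    expect_equal(e$Nd, r$Nd)
    expect_equal(e$Ks, r$Ks)
  }
})

test_that("adding a synonymous difference never decreases Ks", {
  a <- rep("CTA", 80)  # leucine, 4-fold third position (within CTN)
  b <- a
  prev <- 0
  for (i in seq(1, 41, by = 5)) {
    b[i] <- "CTG"
    e <- estimate_ks(list(codons_a = a, codons_b = b))
    expect_gte(e$Ks, prev)
    prev <- e$Ks
  }
})

test_that("saturation is flagged and Ks undefined beyond the JC bound", {
  # serine TCx vs AGy pairs pile up synonymous differences: build a
  # saturated comparison from fourfold sites instead
  a <- rep("GGA", 10)
  b <- rep("GGC", 10)  # every synonymous site differs: ps = 1 > 3/4
  e <- estimate_ks(list(codons_a = a, codons_b = b))
  expect_true(e$saturated)
  expect_true(is.na(e$Ks))
  expect_equal(e$ps, 1)
})

test_that("protein-guided codon alignment projects gaps in codon units", {
  a <- "ATGAAACCCGGGTTTTAA"
  # one codon (CCC) deleted in b
  b <- "ATGAAAGGGTTTTAA"
  al <- align_codons(a, b)
  expect_equal(al$n_gap_columns, 1L)
  expect_equal(al$n_codons_compared, 4L)  # ATG AAA GGG TTT
  # identical sequences: no gaps
  al2 <- align_codons(a, a)
  expect_equal(al2$n_gap_columns, 0L)
  expect_equal(al2$n_codons_compared, nchar(a) / 3 - 1)  # minus stop
  expect_error(align_codons("ATGAA", b), "multiple of 3")
  expect_error(align_codons("ATGTAACCCTAA", b), "internal stop")
})

test_that("NG86 counts match the pathway-enumeration oracle on samples", {
  set.seed(11)
  sense <- names(.oracle_code)[.oracle_code != "*"]
  pairs <- cbind(sample(sense, 150, replace = TRUE),
                 sample(sense, 150, replace = TRUE))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    e <- estimate_ks(list(codons_a = a, codons_b = b), min_codons = 1)
    o <- oracle_pair_diffs(a, b)
    expect_equal(e$Sd, unname(o["sd"]), tolerance = 1e-12)
    expect_equal(e$Nd, unname(o["nd"]), tolerance = 1e-12)
    expect_equal(e$S, (oracle_syn_sites(a) + oracle_syn_sites(b)) / 2,
                 tolerance = 1e-12)
  }
})
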