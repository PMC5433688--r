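# Homolog search and reciprocal-best-hit pairing.

test_that("identical proteomes hit themselves; within mode excludes self", {
  prots <- c(p1 = "MKVLAEQWRTYHNDSGFK", p2 = "MTTRRQQEELLPPGGSAV",
             p3 = "MCCWHYDNSKIARELVFT")
  hits <- find_best_hits(prots, prots, min_shared = 1)
  expect_equal(hits$subject_id[match(names(prots), hits$query_id)],
               names(prots))
  within <- find_best_hits(prots, prots, min_shared = 1,
                           exclude_self = TRUE)
  # unrelated proteins share no 5-mers: no within-proteome hits at all
  expect_equal(nrow(within), 0L)
})

test_that("queries without shared k-mers get no hit", {
  q <- c(q1 = "MAAAAAAAAAAAAAAAAA")
  s <- c(s1 = "MWWWWWWWWWWWWWWWWW")
  expect_equal(nrow(find_best_hits(q, s, min_shared = 1)), 0L)
  expect_warning(find_best_hits(character(0), s), "empty")
})

test_that("local alignment scores match the affine-gap DP oracle on toys", {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  toys <- list(
    c("MKVLAEQWRT", "MKVLAEQWRT"),
    c("MKVLAEQWRT", "MKVLEQWRT"),    # one deletion
    c("MKVRAEQWRT", "MKVLAEQWRTMKV"),
    c("MHHHKVLAEQ", "MKVLAEQ")
  )
  for (t in toys) {
    hits <- find_best_hits(stats::setNames(t[1], "q"),
                           stats::setNames(t[2], "s"),
                           min_shared = 1, min_coverage = 0)
    oracle <- oracle_local_align_score(t[1], t[2], e$BLOSUM62,
                                       gap_open = 11, gap_ext = 1)
    expect_equal(hits$score, oracle)
  }
})

test_that("reciprocal best hits pair symmetrically and exclude asymmetry", {
  ab <- data.frame(query_id = c("a1", "a2", "a3"),
                   subject_id = c("b1", "b2", "b3"))
  ba <- data.frame(query_id = c("b1", "b2", "b3"),
                   subject_id = c("a1", "a2", "a1"))
  pairs <- reciprocal_best_pairs(ab, ba)
  expect_equal(nrow(pairs), 2L)
  expect_setequal(pairs$gene_a, c("a1", "a2"))
  # a3 -> b3 but b3 -> a1: excluded
  expect_false("a3" %in% pairs$gene_a)
})

test_that("homeolog pairing on a clean simulated hybrid recovers truth", {
  sim <- small_sim()
  truth <- sim$truth$genes
  prot <- extract_proteome(sim$genome)
  pairs <- pair_within(prot)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  truth_pairs <- truth[!is.na(truth$partner) & truth$gene_id < truth$partner,
                       c("gene_id", "partner")]
  called <- key(pairs$gene_a, pairs$gene_b)
  expected <- key(truth_pairs$gene_id, truth_pairs$partner)
  precision <- mean(called %in% expected)
  recall <- mean(expected %in% called)
  expect_gte(precision, 0.99)
  expect_gte(recall, 0.99)
})
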