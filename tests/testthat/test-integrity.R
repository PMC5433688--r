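# Gene-integrity screening: length-ratio screen, mechanism typing,
# cross-strain comparison, in-frame introns, +1 frameshift sites.

test_that("the length-ratio screen applies a strict 90% threshold", {
  prots <- c(a = strrep("K", 211), b = strrep("K", 57),
             c = strrep("K", 100), d = strrep("K", 95),
             e = strrep("K", 100), f = strrep("K", 89))
  pairs <- data.frame(gene_a = c("a", "c", "e"),
                      gene_b = c("b", "d", "f"))
  calls <- screen_pairs(pairs, prots)
  expect_setequal(calls$gene_id, c("b", "f"))       # 0.27 and 0.89 flagged
  expect_false("d" %in% calls$gene_id)              # 0.95 passes
  expect_equal(calls$length_ratio[calls$gene_id == "b"], 57 / 211)
  # the screen is symmetric in pair order
  calls_r <- screen_pairs(data.frame(gene_a = pairs$gene_b,
                                     gene_b = pairs$gene_a), prots)
  expect_setequal(calls_r$gene_id, calls$gene_id)
  # a ratio of exactly 0.9 passes (strict inequality)
  prots2 <- c(x = strrep("K", 100), y = strrep("K", 90))
  expect_equal(nrow(screen_pairs(data.frame(gene_a = "x", gene_b = "y"),
                                 prots2)), 0L)
})

test_that("mechanisms are typed from the coding sequences", {
  intact <- random_cds(60, seed = 101)
  # single inserted base: frameshift
  ins <- hybridarch:::str_insert_at(intact, 31L, "A")
  m1 <- detect_mechanism(ins, intact)
  expect_equal(m1$mechanism, "frameshift-indel")
  expect_equal(m1$position, 31L)
  # CAA -> TAA style in-frame stop
  stopmut <- hybridarch:::str_replace_at(intact, 61L, "TAA")
  m2 <- detect_mechanism(stopmut, intact)
  expect_equal(m2$mechanism, "premature-stop")
  expect_equal(m2$position, 21L)
  expect_error(detect_mechanism(intact, intact), "identical")
})

test_that("shared disablements between strains are recognised", {
  genes <- paste0("g", 1:13)
  mech <- rep(c("frameshift-indel", "premature-stop"), length.out = 13)
  s1 <- data.frame(gene_id = genes[1:11], mechanism = mech[1:11])
  s2 <- data.frame(gene_id = c(genes[1:8], "g20", "g21"),
                   mechanism = c(mech[1:8], "premature-stop",
                                 "frameshift-indel"))
  cmp <- compare_strains(s1, s2)
  expect_equal(nrow(cmp$shared), 8L)
  expect_equal(nrow(cmp$unique_1), 3L)
  expect_equal(nrow(cmp$unique_2), 2L)
  # disjoint sets share nothing; identical sets share everything
  cmp2 <- compare_strains(s1, data.frame(gene_id = "g99",
                                         mechanism = "premature-stop"))
  expect_equal(nrow(cmp2$shared), 0L)
  cmp3 <- compare_strains(s1, s1)
  expect_equal(nrow(cmp3$shared), nrow(s1))
})

test_that("simulated disablements are all recovered with their mechanism", {
  pipe <- small_pipeline()
  expect_equal(pipe$recovery$screen$recall, 1)
  expect_equal(pipe$recovery$screen$mechanism_accuracy, 1)
})

test_that("in-frame introns require length 3k and no in-frame stop", {
  set.seed(71)
  exon1 <- random_cds(20)                       # 60 nt incl stop; strip it
  exon1 <- substr(exon1, 1, 57)
  exon2 <- paste0(substr(random_cds(20), 4, 57), "TAA")
  make_gene <- function(intron) {
    seqg <- paste0(exon1, intron, exon2)
    list(model = list(gene_id = "g", exons = data.frame(
      start = c(1L, nchar(exon1) + nchar(intron) + 1L),
      end = c(nchar(exon1), nchar(seqg)))), seq = seqg)
  }
  # 69-bp stop-free intron (codon-safe content): reported
  good <- paste0("GTAAGT", strrep("CAC", 19), "CACAAG")  # 6+57+6 = 69
  g1 <- make_gene(good)
  r1 <- find_inframe_introns(list(g1$model), g1$seq)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$length, 69L)
  # 68-bp intron: not a multiple of 3
  g2 <- make_gene(substr(good, 1, 68))
  expect_equal(nrow(find_inframe_introns(list(g2$model), g2$seq)), 0L)
  # 69-bp intron containing an in-frame TAA: rejected
  bad <- paste0("GTAAGT", "TAA", strrep("CAC", 18), "CACAAG")
  g3 <- make_gene(bad)
  expect_equal(nrow(find_inframe_introns(list(g3$model), g3$seq)), 0L)
  # brute-force oracle over all three: length %% 3 and phased stop scan
  for (g in list(g1, g2, g3)) {
    intron_len <- g$model$exons$start[2] - g$model$exons$end[1] - 1L
    unspliced <- substr(g$seq, 1, nchar(g$seq))
    phased_ok <- intron_len %% 3L == 0L && {
      cods <- substring(unspliced, seq(1, nchar(unspliced) - 2, 3),
                        seq(3, nchar(unspliced), 3))
      stops <- which(cods %in% c("TAA", "TAG", "TGA"))
      length(stops) == 1L && stops == length(cods)
    }
    expect_equal(nrow(find_inframe_introns(list(g$model), g$seq)) == 1L,
                 phased_ok)
  }
})

test_that("+1 frameshift sites need the motif plus an open +1 frame", {
  set.seed(81)
  sense_no_stop <- function(n) {
    paste(sample(setdiff(names(.oracle_code)[.oracle_code != "*"], "CTT"),
                 n, replace = TRUE), collapse = "")
  }
  # dual-frame design: after CTT-A, the +1 frame reads GTT AAT + 33 sense
  # codons; the zero frame reads AGT TAA (stop right after the motif)
  cds2 <- paste0("ATG", sense_no_stop(6), "CTT", "A", "GTT", "AAT",
                 sense_no_stop(33), "TAA")
  hits2 <- find_plus1_sites(c(g = cds2), min_ext = 30, near_stop = 5)
  expect_equal(nrow(hits2), 1L)
  expect_equal(hits2$motif, "CTT-A-GTT")
  expect_equal(hits2$pos, 22L)
  # no motif: nothing
  expect_equal(nrow(find_plus1_sites(c(g = paste0("ATG", sense_no_stop(30),
                                                  "TAA")))), 0L)
  # motif present but the +1 frame closes immediately: rejected
  cds3 <- paste0("ATG", sense_no_stop(6), "CTT", "A", "GTT", "TAA",
                 sense_no_stop(5), "TAA")
  expect_equal(nrow(find_plus1_sites(c(g = cds3), min_ext = 30)), 0L)
})
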