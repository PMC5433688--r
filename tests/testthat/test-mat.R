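# MAT locus forensics: cataloguing, HO cleavage, NHEJ junctions, splice
# shifts.

test_that("the catalog finds 6 regions with the B MAT broken in two", {
  sim <- small_sim()
  cls_labels <- stats::setNames(sim$truth$genes$true_subgenome,
                                sim$truth$genes$gene_id)
  cat <- catalog_mat_loci(sim$genome, gene_labels = cls_labels)
  expect_equal(nrow(cat$loci), 6L)
  expect_equal(sum(cat$loci$intact), 5L)
  expect_equal(sum(!cat$loci$intact), 1L)
  expect_equal(nrow(cat$fragments), 2L)
  expect_setequal(cat$fragments$flank, c("X", "Z"))
  # all full-length X copies are identical in sequence
  expect_equal(cat$x_identity, 1)
  expect_equal(nrow(cat$x_copies), 6L)
  # kinds: one expressed MAT and two silent cassettes per subgenome
  intact <- cat$loci[cat$loci$intact, ]
  expect_equal(sort(table(intact$kind), decreasing = TRUE),
               sort(table(c("HML", "HML", "HMR", "HMR", "MAT")),
                    decreasing = TRUE))
  # idiomorphs: alpha cassettes carry two gene stubs, a cassettes one;
  # no a1 gene exists anywhere in the architecture
  expect_setequal(intact$idiomorph[intact$kind == "HMR"], "a")
  expect_setequal(intact$idiomorph[intact$kind != "HMR"], "alpha")
})

test_that("disabling the breakage leaves all six loci intact", {
  cfg <- sim_config(n_chromosomes_per_parent = 4, n_genes = 120,
                    gene_length_codons = 100, n_rearrangements = 4,
                    loh_lengths = integer(0), n_recombinations = 0,
                    bir_ends = 0, n_disablements_per_subgenome = 0,
                    mat_spec = mat_spec(mat_chrom = 2, breakage = FALSE),
                    seed = 61)
  sim <- simulate_hybrid_genome(cfg)
  expect_null(sim$truth$mat$breakage)
  expect_false(any(sim$genome$features$type == "nhej_junction"))
  ct <- catalog_mat_loci(sim$genome)
  expect_equal(nrow(ct$loci), 6L)
  expect_true(all(ct$loci$intact))
  expect_equal(nrow(ct$fragments), 0L)
  expect_equal(nrow(locate_ho_sites(sim$genome, catalog = ct)), 6L)
})

test_that("a genome without cassettes yields an empty catalog", {
  cfg <- sim_config(n_chromosomes_per_parent = 2, n_genes = 20,
                    gene_length_codons = 50, n_rearrangements = 0,
                    seed = 55)
  g <- as_annotated_genome(simulate_parent(cfg))
  expect_warning(cat <- catalog_mat_loci(g), "empty MAT catalog")
  expect_equal(nrow(cat$loci), 0L)
})

test_that("HO sites sit at Z starts and are strand-aware", {
  sim <- small_sim()
  cat <- catalog_mat_loci(sim$genome)
  ho <- locate_ho_sites(sim$genome, catalog = cat)
  expect_equal(nrow(ho), 5L)  # broken Z fragment has lost its core
  for (i in seq_len(nrow(ho))) {
    expect_equal(substr(sim$genome$seq[[ho$chrom[i]]], ho$pos[i],
                        ho$pos[i] + 6L), "CGCAGCA")
  }
  # scan mode finds a reverse-strand core
  s <- paste0(strrep("AT", 20), "CGCAGCA", strrep("GA", 20))
  rc <- hybridarch:::revcomp(s)
  fwd <- locate_ho_sites(c(chr = s))
  rev <- locate_ho_sites(c(chr = rc))
  expect_equal(fwd$strand, "+")
  expect_equal(rev$strand, "-")
  expect_equal(rev$pos, nchar(s) - (fwd$pos + 6L) + 1L)
  expect_equal(nrow(locate_ho_sites(c(chr = strrep("AT", 30)))), 0L)
})

test_that("HO cleavage yields a 4-nt 3' overhang and re-ligates exactly", {
  set.seed(8)
  flank_l <- hybridarch:::random_dna(26)
  flank_r <- hybridarch:::random_dna(27)
  duplex <- paste0(flank_l, "CGCAGCA", flank_r)  # core at position 27
  cut <- cleave_ho(duplex, 27L)
  expect_equal(cut$overhang_len, 4L)
  expect_equal(cut$polarity, "3'")
  expect_equal(cut$overhang_seq, "CGCA")
  # documented registration applied by hand: top strand severed after the
  # 4th core base (position 30), bottom strand at the 5' core boundary
  expect_equal(cut$top_cut, 30L)
  expect_equal(cut$bottom_cut, 26L)
  expect_equal(cut$fragments$left$top, paste0(flank_l, "CGCA"))
  expect_equal(religate_ho(cut), duplex)
  expect_error(cleave_ho(duplex, 2L), "too close")
})

test_that("junction constructor and analyzer are mutually inverse", {
  set.seed(31)
  rnd <- hybridarch:::random_dna
  # the three planted signature types, checked individually
  dl <- rnd(60); dr <- rnd(60)
  blunt <- make_nhej_junction(dl, dr, 30L, 30L)
  sig <- analyze_junction(blunt, dl, dr, cut_left = 30L, cut_right = 30L)
  expect_equal(sig$microhomology, 0L)
  expect_equal(nrow(sig$tsds), 0L)
  expect_equal(sig$inserted, "")

  j5 <- make_nhej_junction(dl, dr, 30L, 30L, tsd_right = 5L)
  sig5 <- analyze_junction(j5, dl, dr, cut_left = 30L, cut_right = 30L)
  expect_equal(sig5$tsds$len, 5L)
  expect_equal(sig5$tsds$source, "right")
  expect_equal(sig5$tsds$seq, tolower(substr(dr, 26, 30)))

  # a 3-nt overlap shared by both donors is microhomology 3
  dl2 <- paste0(rnd(27), "GCT")
  dr2 <- paste0(rnd(27), "GCT", rnd(30))
  jm <- make_nhej_junction(dl2, dr2, 30L, 27L, microhomology = 3L)
  sigm <- analyze_junction(jm, dl2, dr2, cut_left = 30L, cut_right = 27L)
  expect_equal(sigm$microhomology, 3L)
})

test_that("combined left and right duplications are decomposed", {
  # junction built with a 5-nt duplication from the right donor and a
  # 2-nt tandem duplication from the left donor
  dl <- "AAAACCCCGGGGTTTTACGT"        # 20 nt, cut_left = 20, tail "GT"
  dr <- "CATTGACCAGTACGATCCGGAATTCCGG" # cut_right = 10, preceding 5 = "ACCAG"
  j <- make_nhej_junction(dl, dr, 20L, 10L, tsd_left = 2L, tsd_right = 5L)
  expect_equal(j, paste0(dl, "GT", "ACCAG", substr(dr, 11, nchar(dr))))
  sig <- analyze_junction(j, dl, dr, cut_left = 20L, cut_right = 10L)
  expect_equal(sig$microhomology, 0L)
  expect_equal(sort(sig$tsds$len), c(2L, 5L))
  expect_setequal(sig$tsds$source, c("left", "right"))
})

test_that("the simulated breakage reproduces the expected junction pattern", {
  sim <- small_sim()
  br <- sim$truth$mat$breakage
  expect_equal(br$tsd_left$seq, "ACAAC")
  expect_equal(br$tsd_right$seq, "CA")
  # junction 2 carries the 5-bp intergenic duplication
  j2 <- make_nhej_junction(br$donor_b_spacer, br$donor_a_spacer,
                           br$b_cut, br$a_cut,
                           tsd_right = br$tsd_left$len)
  s2 <- analyze_junction(j2, br$donor_b_spacer, br$donor_a_spacer,
                         cut_left = br$b_cut, cut_right = br$a_cut)
  expect_equal(s2$microhomology, 0L)
  expect_equal(s2$tsds$len, 5L)
  expect_equal(s2$tsds$seq, "acaac")
  # junction 1 carries the 2-bp MAT-side duplication
  j1 <- make_nhej_junction(br$donor_a_spacer, br$donor_b_spacer,
                           br$a_cut, br$b_cut,
                           tsd_right = br$tsd_right$len)
  s1 <- analyze_junction(j1, br$donor_a_spacer, br$donor_b_spacer,
                         cut_left = br$a_cut, cut_right = br$b_cut)
  expect_equal(s1$tsds$len, 2L)
  expect_equal(s1$tsds$seq, "ca")
  expect_equal(s1$microhomology, 0L)
})

alpha2_report <- function(sim, locus) {
  mm <- Filter(function(x) x$locus == locus, sim$truth$mat$alpha2_models)[[1]]
  f <- sim$genome$features
  row <- f[f$name == paste0(locus, ":alpha2"), ]
  gm <- list(exons = data.frame(start = mm$exons$start + row$start - 1L,
                                end = mm$exons$end + row$start - 1L))
  analyze_splice_shift(gm, sim$genome$seq[[row$chrom]])
}

test_that("the splice-shift analysis reproduces the 57 vs 211 aa pattern", {
  sim <- small_sim()
  a <- alpha2_report(sim, "MAT_A")
  expect_equal(a$shift, 0L)
  expect_equal(a$protein_length, 211L)
  b <- alpha2_report(sim, "HML_B")
  expect_equal(b$shift, 2L)
  expect_false(b$frame_preserved)
  expect_equal(b$acceptor_dinucleotide, "AC")
  expect_equal(b$protein_length, 57L)
})

test_that("frame preservation follows shift mod 3 exhaustively", {
  # toy gene: 2 exons; engineer acceptors shifted by 0..9 nt
  set.seed(91)
  for (s in 0:9) {
    exon1 <- paste0("ATG", "AAA", "CCC")                # 9 nt
    # intron whose annotated acceptor is AG only when s == 0
    pad <- paste(rep("C", s), collapse = "")
    intron <- paste0("GTAAGT", "TTTTTTTTTT",
                     if (s == 0) "AG" else paste0("AT", pad, "AG"))
    exon2 <- paste0("GGG", "TTT", "TAA")
    seqg <- paste0(exon1, intron, exon2)
    model <- list(exons = data.frame(
      start = c(1L, nchar(exon1) + nchar(intron) + 1L -
                  (if (s == 0) 0L else s)),
      end = c(nchar(exon1), nchar(seqg))
    ))
    # annotated acceptor = s nt upstream of the real AG when s > 0
    rep <- analyze_splice_shift(model, seqg)
    expect_equal(rep$shift, s)
    expect_equal(rep$frame_preserved, s %% 3L == 0L)
  }
})
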