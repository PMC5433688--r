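# Mating-type cassette architecture and the HO-catalysed breakage.
#
# Each subgenome receives one expressed MAT locus plus two silent
# cassettes (HML-alpha near the left telomere, HMR-a near the right
# telomere) on a designated chromosome. Every cassette is X-repeat +
# idiomorph genes (Y region) + Z-repeat; all X copies are identical, as
# are all Z copies, and the Z repeat always begins with the HO cleavage
# core. The alpha1 reading frame runs across the Y/Z boundary so that the
# core heptamer encodes the conserved FAQQ protein motif. There is no a1
# gene anywhere. The alpha2 gene carries two spliceosomal introns; in the
# B-subgenome copies the intron-2 AG acceptor is mutated to AC, which
# shifts splicing 2 nt downstream, truncating the protein from 211 to 57
# residues.
#
# Breakage model: HO cleaves the B MAT locus within the core at the Z
# boundary; nonhomologous end joining with a cut in an A-subgenome
# intergenic region produces a reciprocal translocation whose two
# junctions carry target-site duplications (5 bp from the intergenic
# side, 2 bp from the MAT side) and no microhomology.

.rand_sense <- function(n) {
  paste(sample(sense_codons(), n, replace = TRUE), collapse = "")
}

# Z repeat: core heptamer first, alpha1 frame continues through it.
.build_z_repeat <- function(spec) {
  core <- toupper(spec$ho_core)           # CGCAGCA
  # layout: [core 1-7][A][codons 9..86][TAA 87-89][random 90..z_len]
  z <- paste0(core, "A", .rand_sense(26L), "TAA",
              random_dna(spec$z_len - 89L))
  stopifnot(nchar(z) == spec$z_len)
  z
}

# alpha2 gene: 5 blocks; returns genomic sequences (A and B variants) and
# the exon model (1-based coordinates relative to gene start).
.build_alpha2 <- function() {
  exon1 <- paste0("ATG", .rand_sense(29L))                      # 90 nt
  intron1 <- paste0("GTAAGT", random_dna(31L), "TACTAAC",
                    random_dna(2L), "AG")                       # 48 nt
  exon2 <- .rand_sense(26L)                                     # 78 nt
  intron2 <- paste0("GTAAGT", random_dna(43L), "TACTAAC",
                    "TT", "AG")                                 # 60 nt
  # exon3 begins AG GCA TAA G: the AG provides the cryptic acceptor used
  # after the B mutation; the -2 frame then terminates after one codon.
  exon3 <- paste0("AGGCATAAG", .rand_sense(152L), "TAA")        # 468 nt
  genomic_a <- paste0(exon1, intron1, exon2, intron2, exon3)
  genomic_b <- paste0(exon1, intron1, exon2,
                      paste0(substr(intron2, 1L, 58L), "AC"), exon3)
  l1 <- nchar(exon1); l2 <- nchar(intron1); l3 <- nchar(exon2)
  l4 <- nchar(intron2)
  starts <- c(1L, l1 + l2 + 1L, l1 + l2 + l3 + l4 + 1L)
  ends <- c(l1, l1 + l2 + l3, nchar(genomic_a))
  list(genomic_a = genomic_a, genomic_b = genomic_b,
       exons = data.frame(start = starts, end = ends))
}

# Build the shared cassette building blocks (deterministic given the RNG
# state at call time).
.build_mat_parts <- function(spec) {
  x <- if (is.null(spec$x_repeat)) random_dna(spec$x_len) else spec$x_repeat
  z <- if (is.null(spec$z_repeat)) .build_z_repeat(spec) else spec$z_repeat
  stopifnot(nchar(x) == spec$x_len, nchar(z) == spec$z_len)
  alpha2 <- .build_alpha2()
  # alpha1: ATG + 47 codons + TTT + G; the frame continues into Z as
  # G|cg = GCG(A), cag = CAG(Q), caa = CAA(Q), giving ...F A Q Q...
  alpha1_in_y <- paste0("ATG", .rand_sense(47L), "TTTG")        # 148 nt
  a2 <- paste0("ATG", .rand_sense(117L), "TAA")                 # 360 nt
  linker1 <- random_dna(15L)
  linker2 <- random_dna(15L)
  list(x = x, z = z, alpha2 = alpha2, alpha1_in_y = alpha1_in_y,
       a2 = a2, linker1 = linker1, linker2 = linker2)
}

# assemble one cassette; returns sequence + component offsets (1-based,
# relative to cassette start)
.assemble_cassette <- function(parts, idiomorph, subgenome) {
  if (idiomorph == "alpha") {
    a2g <- if (subgenome == "B") parts$alpha2$genomic_b else
      parts$alpha2$genomic_a
    y <- paste0(parts$linker1, a2g, parts$linker2, parts$alpha1_in_y)
    alpha2_off <- nchar(parts$x) + nchar(parts$linker1) + 1L
  } else {
    y <- paste0(parts$linker1, parts$a2, parts$linker2)
    alpha2_off <- NA_integer_
  }
  seq <- paste0(parts$x, y, parts$z)
  list(seq = seq, len = nchar(seq),
       x_off = 1L, x_len = nchar(parts$x),
       z_off = nchar(parts$x) + nchar(y) + 1L, z_len = nchar(parts$z),
       alpha2_off = alpha2_off, idiomorph = idiomorph)
}

#' Install MAT/HML/HMR cassettes and simulate the HO-catalysed breakage
#'
#' Inserts, per subgenome, one MAT locus (mid-chromosome) and HML/HMR
#' silent cassettes (telomere-proximal) on the designated cassette
#' chromosome; then, unless `spec$breakage` is `FALSE`, cleaves the
#' B-subgenome MAT locus at the Z-region boundary and rejoins the ends
#' with an A-subgenome intergenic cut as a reciprocal translocation whose
#' junctions carry the configured target-site duplications and zero
#' microhomology.
#'
#' @param hybrid Hybrid `sim_genome`.
#' @param truth Matching `sim_truth`.
#' @param spec A [mat_spec()].
#' @param seed Integer seed.
#' @return list with updated `genome` and `truth`.
#' @export
build_mat_architecture_and_breakage <- function(hybrid, truth, spec,
                                                seed = 1L) {
  set.seed(as.integer(seed))
  sim <- hybrid
  chrom_names <- vapply(sim$chroms, `[[`, character(1L), "name")
  parts <- .build_mat_parts(spec)
  feats <- list()
  loci <- list()
  alpha2_models <- list()

  for (sub in c("A", "B")) {
    cname <- sprintf("chr%s_%02d", sub, spec$mat_chrom)
    ci <- .chrom_idx(sim, cname)
    if (length(ci) != 1L) {
      stop("cassette chromosome ", cname, " not present")
    }
    n <- nrow(sim$chroms[[ci]]$genes)
    if (n < 4L) stop("cassette chromosome too short")
    placements <- list(
      list(kind = "HML", idiomorph = "alpha", spacer = 1L),
      list(kind = "MAT", idiomorph = "alpha",
           spacer = max(2L, min(n, (n + 1L) %/% 2L))),
      list(kind = "HMR", idiomorph = "a", spacer = n + 1L)
    )
    for (pl in placements) {
      cass <- .assemble_cassette(parts, pl$idiomorph, sub)
      sp <- sim$chroms[[ci]]$spacers[pl$spacer]
      off <- max(1L, nchar(sp) %/% 2L)
      sim$chroms[[ci]]$spacers[pl$spacer] <- str_insert_at(sp, off + 1L,
                                                           cass$seq)
      nm <- paste0(pl$kind, "_", sub)
      feats[[length(feats) + 1L]] <- data.frame(
        name = nm, type = "mat_locus", chrom = cname,
        spacer_index = pl$spacer, offset = off + 1L, len = cass$len,
        stringsAsFactors = FALSE
      )
      feats[[length(feats) + 1L]] <- data.frame(
        name = paste0(nm, ":X"), type = "x_repeat", chrom = cname,
        spacer_index = pl$spacer, offset = off + cass$x_off,
        len = cass$x_len, stringsAsFactors = FALSE
      )
      feats[[length(feats) + 1L]] <- data.frame(
        name = paste0(nm, ":Z"), type = "z_repeat", chrom = cname,
        spacer_index = pl$spacer, offset = off + cass$z_off,
        len = cass$z_len, stringsAsFactors = FALSE
      )
      loci[[length(loci) + 1L]] <- list(
        name = nm, kind = pl$kind, idiomorph = pl$idiomorph,
        subgenome = sub, chrom = cname, intact = TRUE
      )
      if (pl$idiomorph == "alpha") {
        feats[[length(feats) + 1L]] <- data.frame(
          name = paste0(nm, ":alpha2"), type = "alpha2_gene",
          chrom = cname, spacer_index = pl$spacer,
          offset = off + cass$alpha2_off,
          len = max(parts$alpha2$exons$end), stringsAsFactors = FALSE
        )
        alpha2_models[[length(alpha2_models) + 1L]] <- list(
          locus = nm, chrom = cname, spacer_index = pl$spacer,
          gene_offset = off + cass$alpha2_off,
          exons = parts$alpha2$exons,
          mutated = sub == "B"
        )
      }
    }
  }
  sim$features <- do.call(rbind, feats)
  breakage_rec <- NULL

  if (spec$breakage) {
    tL <- spec$tsd_left_len
    tR <- spec$tsd_right_len
    # cut 1: inside the B MAT cassette, within the HO core at the Z
    # boundary (after the 4th core nucleotide = after the 3' overhang)
    bname <- sprintf("chrB_%02d", spec$mat_chrom)
    bi <- .chrom_idx(sim, bname)
    fB <- sim$features
    zrow <- which(fB$name == "MAT_B:Z")
    mrow <- which(fB$name == "MAT_B")
    sB <- fB$spacer_index[zrow]
    cutB <- fB$offset[zrow] + 3L
    nB <- nrow(sim$chroms[[bi]]$genes)

    # cut 2: a mid-chromosome intergenic site on a non-cassette
    # A-subgenome chromosome
    a_cands <- grep("^chrA_", chrom_names, value = TRUE)
    a_cands <- setdiff(a_cands, sprintf("chrA_%02d", spec$mat_chrom))
    a_cands <- a_cands[vapply(a_cands, function(nm) {
      nrow(sim$chroms[[.chrom_idx(sim, nm)]]$genes) >= 3L
    }, logical(1L))]
    # avoid cutting inside an LOH tract or at a recombination junction
    avoid <- unique(c(
      unlist(lapply(truth$loh, function(x) c(x$gene_ids, x$partner_ids))),
      unlist(lapply(truth$recombination, function(x) {
        c(x$left_gene_1, x$right_gene_1, x$left_gene_2, x$right_gene_2)
      }))
    ))
    tga <- truth$genes
    rownames(tga) <- tga$gene_id
    a_cands <- if (length(a_cands) > 1L) sample(a_cands) else a_cands
    aname <- NA_character_
    sA <- NA_integer_
    for (cand_chrom in a_cands) {
      ai <- .chrom_idx(sim, cand_chrom)
      nA <- nrow(sim$chroms[[ai]]$genes)
      gidsA <- sim$chroms[[ai]]$genes$gene_id
      mid <- max(2L, min(nA, (nA + 1L) %/% 2L))
      cand_s <- order(abs(seq(2L, nA) - mid)) + 1L
      for (s in cand_s) {
        # the cut must land in bona fide A-subgenome territory (flanks of
        # simple A:B genes on both sides) so the resulting junction is a
        # genuine A|B boundary, and must not bisect an earlier event
        win <- gidsA[max(1L, s - 3L):min(nA, s + 2L)]
        ok <- !any(win %in% avoid) &&
          all(tga[win, "true_subgenome"] == "A") &&
          all(tga[win, "true_category"] == "A-in-A:B")
        if (isTRUE(ok)) {
          sA <- s
          break
        }
      }
      if (!is.na(sA)) {
        aname <- cand_chrom
        break
      }
    }
    if (is.na(sA)) stop("no intergenic site available for the MAT breakage")
    ai <- .chrom_idx(sim, aname)
    nA <- nrow(sim$chroms[[ai]]$genes)
    spA <- sim$chroms[[ai]]$spacers[sA]
    oA <- nchar(spA) %/% 2L
    # plant the left-side target-site duplication sequence (the acaac-type
    # motif) in the intergenic region immediately 5' of the cut
    tsdA_seq <- if (tL == 5L) "ACAAC" else
      if (tL > 0L) random_dna(tL) else ""
    if (tL > 0L) {
      spA <- str_replace_at(spA, oA - tL + 1L, tsdA_seq)
      sim$chroms[[ai]]$spacers[sA] <- spA
    }
    spB <- sim$chroms[[bi]]$spacers[sB]
    tsdB_seq <- if (tR > 0L) substr(spB, cutB - tR + 1L, cutB) else ""

    LA <- substr(spA, 1L, oA); RA <- substr(spA, oA + 1L, nchar(spA))
    LB <- substr(spB, 1L, cutB); RB <- substr(spB, cutB + 1L, nchar(spB))
    chA <- sim$chroms[[ai]]; chB <- sim$chroms[[bi]]

    j1_spacer <- paste0(LA, tsdB_seq, RB)
    j2_spacer <- paste0(LB, tsdA_seq, RA)
    g1 <- rbind(chA$genes[seq_len(sA - 1L), , drop = FALSE],
                chB$genes[sB:nB, , drop = FALSE])
    g2 <- rbind(chB$genes[seq_len(sB - 1L), , drop = FALSE],
                chA$genes[sA:nA, , drop = FALSE])
    rownames(g1) <- rownames(g2) <- NULL
    sp1 <- c(chA$spacers[seq_len(sA - 1L)], j1_spacer,
             chB$spacers[(sB + 1L):(nB + 1L)])
    sp2 <- c(chB$spacers[seq_len(sB - 1L)], j2_spacer,
             chA$spacers[(sA + 1L):(nA + 1L)])
    sim$chroms[[ai]] <- .sim_chromosome(aname, g1, sp1, chA$tel_l,
                                        chB$tel_r)
    sim$chroms[[bi]] <- .sim_chromosome(bname, g2, sp2, chB$tel_l,
                                        chA$tel_r)

    # re-anchor features
    f <- sim$features
    for (i in seq_len(nrow(f))) {
      if (f$chrom[i] == bname && f$spacer_index[i] > sB) {
        f$chrom[i] <- aname
        f$spacer_index[i] <- sA + (f$spacer_index[i] - sB)
      } else if (f$chrom[i] == bname && f$spacer_index[i] == sB) {
        if (f$offset[i] <= cutB) {
          # stays in LB on the (renamed) B product, same anchor
        } else {
          f$chrom[i] <- aname
          f$spacer_index[i] <- sA
          f$offset[i] <- f$offset[i] - cutB + nchar(LA) + nchar(tsdB_seq)
        }
      }
    }
    # split the broken MAT_B locus into its two fragments
    mb <- f[f$name == "MAT_B", , drop = FALSE]
    frag_xy <- mb
    frag_xy$name <- "MAT_B:fragment_XY"
    frag_xy$type <- "mat_fragment"
    frag_xy$len <- cutB - mb$offset + 1L
    zb <- f[f$name == "MAT_B:Z", , drop = FALSE]
    frag_z <- zb
    frag_z$name <- "MAT_B:fragment_Z"
    frag_z$type <- "mat_fragment"
    frag_z$chrom <- aname
    frag_z$spacer_index <- sA
    frag_z$offset <- nchar(LA) + nchar(tsdB_seq) + 1L
    frag_z$len <- spec$z_len - 4L
    f <- f[f$name != "MAT_B", , drop = FALSE]
    # the Z-repeat copy of MAT_B is now the truncated fragment copy
    f$offset[f$name == "MAT_B:Z"] <- frag_z$offset
    f$len[f$name == "MAT_B:Z"] <- frag_z$len
    f$chrom[f$name == "MAT_B:Z"] <- aname
    f$spacer_index[f$name == "MAT_B:Z"] <- sA
    jrows <- data.frame(
      name = c("junction_1", "junction_2"), type = "nhej_junction",
      chrom = c(aname, bname), spacer_index = c(sA, sB),
      offset = c(nchar(LA) + 1L, nchar(LB) + 1L),
      len = pmax(1L, c(nchar(tsdB_seq), nchar(tsdA_seq))),
      stringsAsFactors = FALSE
    )
    f <- rbind(f, frag_xy, frag_z, jrows)
    rownames(f) <- NULL
    sim$features <- f
    for (li in seq_along(loci)) {
      if (loci[[li]]$name == "MAT_B") loci[[li]]$intact <- FALSE
    }

    junction_genes <- list(
      j1 = c(left = chA$genes$gene_id[sA - 1L],
             right = chB$genes$gene_id[sB]),
      j2 = c(left = chB$genes$gene_id[sB - 1L],
             right = chA$genes$gene_id[sA])
    )
    breakage_rec <- list(
      b_chrom = bname, b_spacer = sB, b_cut = cutB,
      a_chrom = aname, a_spacer = sA, a_cut = oA,
      tsd_left = list(seq = tsdA_seq, len = tL, source = "intergenic-A"),
      tsd_right = list(seq = tsdB_seq, len = tR, source = "MAT-Z"),
      donor_a_spacer = spA, donor_b_spacer = spB,
      junction_1 = list(chrom = aname, spacer_index = sA,
                        flank_left_len = nchar(LA),
                        insert = tsdB_seq),
      junction_2 = list(chrom = bname, spacer_index = sB,
                        flank_left_len = nchar(LB),
                        insert = tsdA_seq),
      junction_genes = junction_genes
    )
  }

  truth$mat <- list(loci = loci, parts = parts,
                    alpha2_models = alpha2_models,
                    breakage = breakage_rec, spec = spec)
  list(genome = sim, truth = truth)
}
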