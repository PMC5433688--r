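# Mating-type locus forensics: de novo discovery of the X/Z cassette
# repeats, locus cataloguing (intact vs broken), the HO endonuclease
# cleavage model, NHEJ junction signature analysis, and splice-site-shift
# disablement analysis.

# ---- k-mer repeat discovery -------------------------------------------

# numeric 2-bit encoding of all k-mers of a sequence; NA for non-ACGT
.kmer_codes <- function(seq, k) {
  v <- utf8ToInt(seq)
  lut <- rep(NA_real_, 128L)
  lut[utf8ToInt("A")] <- 0; lut[utf8ToInt("C")] <- 1
  lut[utf8ToInt("G")] <- 2; lut[utf8ToInt("T")] <- 3
  lut[utf8ToInt("a")] <- 0; lut[utf8ToInt("c")] <- 1
  lut[utf8ToInt("g")] <- 2; lut[utf8ToInt("t")] <- 3
  b <- lut[v]
  n <- length(b) - k + 1L
  if (n < 1L) return(numeric(0L))
  code <- numeric(n)
  for (j in 0L:(k - 1L)) {
    code <- code * 4 + b[(1L + j):(n + j)]
  }
  code
}

# intervals (per chromosome) of positions whose k-mer occurs >= min_copies
# times genome-wide
.multicopy_intervals <- function(seqs, k = 16L, min_copies = 3L,
                                 merge_gap = 40L, min_len = 100L) {
  codes <- lapply(seqs, .kmer_codes, k = k)
  all_codes <- unlist(codes, use.names = FALSE)
  all_codes <- all_codes[!is.na(all_codes)]
  if (length(all_codes) == 0L) return(NULL)
  srt <- sort(all_codes, method = "quick")
  r <- rle(srt)
  rep_codes <- r$values[r$lengths >= min_copies]
  out <- list()
  for (nm in names(seqs)) {
    cd <- codes[[nm]]
    hit <- !is.na(cd) & cd %in% rep_codes
    if (!any(hit)) next
    pos <- which(hit)
    gaps <- which(diff(pos) > merge_gap)
    starts <- pos[c(1L, gaps + 1L)]
    ends <- pos[c(gaps, length(pos))] + k - 1L
    # density: fraction of k-mer start positions in the interval that are
    # repeated; true repeat copies are near 1, diverged homeologous
    # duplications are diffuse
    grp <- findInterval(pos, starts)
    n_hits <- tabulate(grp, nbins = length(starts))
    dens <- n_hits / pmax(1L, ends - starts - k + 2L)
    keep <- (ends - starts + 1L) >= min_len
    if (!any(keep)) next
    out[[nm]] <- data.frame(chrom = nm, start = starts[keep],
                            end = ends[keep],
                            density = pmin(1, dens[keep]),
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.seq_identity <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0)
  mean(strsplit(substr(a, 1L, n), "")[[1L]] ==
         strsplit(substr(b, 1L, n), "")[[1L]])
}

# scan a window for a probe allowing mismatches; returns best start or NA
.probe_best_hit <- function(probe, window, max_mismatch) {
  pl <- nchar(probe)
  wl <- nchar(window)
  if (wl < pl) return(NULL)
  pv <- strsplit(probe, "")[[1L]]
  wv <- strsplit(window, "")[[1L]]
  best <- NULL
  for (s in 1L:(wl - pl + 1L)) {
    mm <- sum(wv[s:(s + pl - 1L)] != pv)
    if (mm <= max_mismatch && (is.null(best) || mm < best$mm)) {
      best <- list(start = s, mm = mm)
    }
  }
  best
}

#' Catalogue MAT/HML/HMR loci from genome sequence
#'
#' Discovers the X and Z cassette repeats de novo as multi-copy
#' near-identical elements (at least `min_copies` copies, length at least
#' `min_repeat_len`), using a locus that carries two separated repeat
#' blocks (an HMR-type cassette, where the short a-specific Y region is
#' below copy-number threshold) to derive clean X and Z probes: the longer
#' repeat is X (654 bp here), the shorter is Z (266 bp). Every discovered
#' repeat copy is then assigned to a locus by proximity; a locus with both
#' flanks and an idiomorph region between them is intact, a lone flank is
#' a fragment of a broken locus. Complementary X-side and Z-side fragments
#' are paired into one broken locus. Idiomorphs are called from the Y
#' region (two gene stubs = alpha, one = a); a locus within
#' `telomere_proximal` bp of a chromosome end is a silent cassette (HML if
#' alpha, HMR if a), otherwise MAT.
#'
#' @param genome An [annotated_genome()].
#' @param gene_labels Optional named vector (gene_id -> subgenome label)
#'   used to annotate each locus with the subgenome of its neighbourhood.
#' @param min_copies Minimum repeat copy number (default 3).
#' @param min_repeat_len Minimum repeat length (default 200).
#' @param id_min Minimum identity for probe matching (default 0.95).
#' @param cluster_gap Maximum distance between repeat copies of one locus
#'   (default 4000).
#' @param telomere_proximal Distance from a chromosome end under which a
#'   locus is called silent; `NULL` (default) uses the smaller of 30 kb
#'   and 12% of the median chromosome length.
#' @param alpha_y_min Y regions longer than this are called alpha
#'   (two-stub) idiomorphs (default 600).
#' @return A list of class `mat_catalog`: `loci` (one row per MAT-related
#'   region), `fragments`, `x_copies`, `z_copies`, `x_identity`,
#'   `z_identity`.
#' @export
catalog_mat_loci <- function(genome, gene_labels = NULL, min_copies = 3L,
                             min_repeat_len = 200L, id_min = 0.95,
                             cluster_gap = 4000L,
                             telomere_proximal = NULL,
                             alpha_y_min = 600L) {
  if (is.null(telomere_proximal)) {
    telomere_proximal <- min(30000L,
                             round(0.12 * stats::median(nchar(genome$seq))))
  }
  empty <- structure(list(
    loci = data.frame(), fragments = data.frame(),
    x_copies = data.frame(), z_copies = data.frame(),
    x_identity = NA_real_, z_identity = NA_real_
  ), class = "mat_catalog")

  iv <- .multicopy_intervals(genome$seq, min_copies = min_copies,
                             min_len = min_repeat_len %/% 2L)
  if (is.null(iv)) {
    warning("no multi-copy repeats found: empty MAT catalog")
    return(empty)
  }
  # drop simple tandem arrays (telomeric repeats): a short period explains
  # the start of the interval
  is_tandem <- function(s, max_period = 30L, probe_len = 66L) {
    # interval boundaries can overshoot a repeat array by a few bases, so
    # test periodicity from several start offsets
    for (off in 0L:5L) {
      n <- min(nchar(s) - off, probe_len)
      if (n < 22L) next
      ch <- strsplit(substr(s, 1L + off, off + n), "")[[1L]]
      for (p in seq_len(min(max_period, n %/% 2L))) {
        if (all(ch[seq_len(n - p)] == ch[(p + 1L):n])) return(TRUE)
      }
    }
    FALSE
  }
  tandem <- vapply(seq_len(nrow(iv)), function(i) {
    is_tandem(substr(genome$seq[[iv$chrom[i]]], iv$start[i], iv$end[i]))
  }, logical(1L))
  iv <- iv[!tandem, , drop = FALSE]
  if (nrow(iv) == 0L) {
    warning("no cassette-like repeats found: empty MAT catalog")
    return(empty)
  }

  # cluster intervals into candidate loci by proximity
  iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
  iv$cluster <- cumsum(c(1L, as.integer(
    iv$chrom[-1L] != iv$chrom[-nrow(iv)] |
      iv$start[-1L] - iv$end[-nrow(iv)] > cluster_gap
  )))

  # derive X and Z probes from a cluster with two separated repeat blocks
  probe_x <- probe_z <- NULL
  for (cl in unique(iv$cluster)) {
    sub <- iv[iv$cluster == cl, , drop = FALSE]
    if (nrow(sub) == 2L && all(sub$density >= 0.9) &&
        sub$start[2L] - sub$end[1L] >= 100L) {
      s1 <- substr(genome$seq[[sub$chrom[1L]]], sub$start[1L], sub$end[1L])
      s2 <- substr(genome$seq[[sub$chrom[2L]]], sub$start[2L], sub$end[2L])
      if (nchar(s1) >= min_repeat_len && nchar(s2) >= min_repeat_len %/% 2L) {
        if (nchar(s1) >= nchar(s2)) {
          probe_x <- s1; probe_z <- s2
        } else {
          probe_x <- s2; probe_z <- s1
        }
        break
      }
    }
  }
  if (is.null(probe_x)) {
    warning("could not derive X/Z probes: empty MAT catalog")
    return(empty)
  }

  # locate all near-identical copies of each probe within the candidate
  # regions (margins absorb truncated copies)
  find_copies <- function(probe) {
    rows <- list()
    for (cl in unique(iv$cluster)) {
      sub <- iv[iv$cluster == cl, , drop = FALSE]
      w_start <- max(1L, min(sub$start) - 100L)
      w_end <- min(nchar(genome$seq[[sub$chrom[1L]]]),
                   max(sub$end) + 100L)
      window <- substr(genome$seq[[sub$chrom[1L]]], w_start, w_end)
      pos <- 1L
      while (TRUE) {
        hit <- .probe_best_hit(probe, substr(window, pos, nchar(window)),
                               max_mismatch = ceiling((1 - id_min) *
                                                        nchar(probe)))
        if (is.null(hit)) break
        st <- w_start + pos - 1L + hit$start - 1L
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = sub$chrom[1L], start = st,
          end = st + nchar(probe) - 1L, mismatches = hit$mm,
          cluster = cl, stringsAsFactors = FALSE
        )
        pos <- pos + hit$start - 1L + nchar(probe)
        if (pos > nchar(window)) break
      }
    }
    if (length(rows) == 0L) return(data.frame())
    do.call(rbind, rows)
  }
  # refine each probe by anchor extension: take a k-mer from the middle
  # of the seed interval, find its exact occurrences genome-wide, and
  # extend outward while a supermajority of occurrences agree per column.
  # This places the probe boundaries exactly on the repeat, clipping
  # flank contamination (linkers, adjacent spacer) and tolerating a
  # truncated fragment copy among the occurrences.
  refine_probe <- function(probe, anchor_k = 24L, min_frac = 0.8) {
    mid <- nchar(probe) %/% 2L
    anchor <- substr(probe, mid - anchor_k %/% 2L,
                     mid + anchor_k %/% 2L)
    occ <- list()
    for (nm in names(genome$seq)) {
      for (p in str_find_all(anchor, genome$seq[[nm]])) {
        occ[[length(occ) + 1L]] <- c(nm, p)
      }
    }
    if (length(occ) < min_copies) return(probe)
    col_at <- function(delta) {
      vapply(occ, function(o) {
        s <- genome$seq[[o[1L]]]
        p <- as.integer(o[2L]) + delta
        if (p < 1L || p > nchar(s)) "" else substr(s, p, p)
      }, character(1L))
    }
    extend <- function(dir) {
      d <- 0L
      repeat {
        d <- d + dir
        cols <- col_at(d)
        cols <- cols[cols != ""]
        if (length(cols) < min_copies) return(d - dir)
        tab <- sort(table(cols), decreasing = TRUE)
        if (tab[1L] / length(cols) < min_frac) return(d - dir)
        if (abs(d) > 5000L) return(d)
      }
    }
    lo <- extend(-1L)
    hi <- extend(+1L)
    # majority sequence over the extended range, read from the first
    # full-length occurrence
    best <- NULL
    for (o in occ) {
      s <- genome$seq[[o[1L]]]
      p <- as.integer(o[2L])
      if (p + lo >= 1L && p + hi <= nchar(s)) {
        cand <- substr(s, p + lo, p + hi)
        if (is.null(best) || TRUE) {
          # prefer the modal full-length variant
          best <- c(best, cand)
        }
      }
    }
    if (is.null(best)) return(probe)
    names(sort(table(best), decreasing = TRUE))[1L]
  }
  probe_x <- refine_probe(probe_x)
  probe_z <- refine_probe(probe_z)
  x_copies <- find_copies(probe_x)
  z_copies <- find_copies(probe_z)

  pair_identity <- function(copies) {
    if (nrow(copies) < 2L) return(NA_real_)
    seqs <- substr(genome$seq[copies$chrom], copies$start, copies$end)
    ref <- seqs[1L]
    mean(vapply(seqs[-1L], .seq_identity, numeric(1L), a = ref))
  }

  # build loci from clusters
  loci <- list(); fragments <- list()
  label_of <- function(chrom, pos) {
    if (is.null(gene_labels)) return(NA_character_)
    g <- genome$genes[genome$genes$chrom == chrom, , drop = FALSE]
    if (nrow(g) == 0L) return(NA_character_)
    nearest <- order(abs((g$start + g$end) / 2 - pos))[seq_len(min(3L,
                                                                   nrow(g)))]
    labs <- gene_labels[g$gene_id[nearest]]
    labs <- labs[labs %in% c("A", "B")]
    if (length(labs) == 0L) return(NA_character_)
    names(sort(table(labs), decreasing = TRUE))[1L]
  }
  # pair every X copy with the next following Z copy on the same
  # chromosome (within cluster_gap): an X..Z pair with a Y region between
  # is an intact locus; an unpaired flank is a fragment of a broken locus
  copies <- rbind(
    if (nrow(x_copies)) cbind(x_copies, flank = "X") else NULL,
    if (nrow(z_copies)) cbind(z_copies, flank = "Z") else NULL
  )
  if (!is.null(copies) && nrow(copies)) {
    copies <- copies[order(copies$chrom, copies$start), , drop = FALSE]
    i <- 1L
    while (i <= nrow(copies)) {
      ci <- copies[i, ]
      paired <- FALSE
      if (ci$flank == "X" && i < nrow(copies)) {
        nx <- copies[i + 1L, ]
        paired <- nx$flank == "Z" && nx$chrom == ci$chrom &&
          nx$start > ci$end && nx$start - ci$end <= cluster_gap
      }
      chrom <- ci$chrom
      clen <- nchar(genome$seq[[chrom]])
      if (paired) {
        nx <- copies[i + 1L, ]
        lo <- ci$start; hi <- nx$end
        telo <- min(lo - 1L, clen - hi) <= telomere_proximal
        y_len <- nx$start - ci$end - 1L
        idio <- if (y_len >= alpha_y_min) "alpha" else "a"
        kind <- if (telo) (if (idio == "alpha") "HML" else "HMR") else "MAT"
        loci[[length(loci) + 1L]] <- data.frame(
          chrom = chrom, start = lo, end = hi, kind = kind,
          idiomorph = idio, subgenome = label_of(chrom, (lo + hi) / 2),
          intact = TRUE,
          x_start = ci$start, x_end = ci$end,
          z_start = nx$start, z_end = nx$end,
          stringsAsFactors = FALSE
        )
        i <- i + 2L
      } else {
        # an X-side fragment may retain its Y region (idiomorph callable
        # from the extent of cassette-like repeated sequence after X)
        idio <- "unknown"
        if (ci$flank == "X") {
          near <- iv[iv$chrom == chrom & iv$start >= ci$start - 50L &
                       iv$start <= ci$end + cluster_gap, , drop = FALSE]
          if (nrow(near) && max(near$end) - ci$end >= alpha_y_min) {
            idio <- "alpha"
          }
        }
        fragments[[length(fragments) + 1L]] <- data.frame(
          chrom = chrom, start = ci$start, end = ci$end, flank = ci$flank,
          idiomorph = idio,
          subgenome = label_of(chrom, (ci$start + ci$end) / 2),
          stringsAsFactors = FALSE
        )
        i <- i + 1L
      }
    }
  }
  loci_df <- if (length(loci)) do.call(rbind, loci) else data.frame()
  frag_df <- if (length(fragments)) do.call(rbind, fragments) else
    data.frame()

  # pair complementary fragments into broken loci
  if (nrow(frag_df) > 0L) {
    xf <- which(frag_df$flank == "X")
    zf <- which(frag_df$flank == "Z")
    n_pair <- min(length(xf), length(zf))
    for (i in seq_len(n_pair)) {
      fx <- frag_df[xf[i], ]; fz <- frag_df[zf[i], ]
      loci_df <- rbind(loci_df, data.frame(
        chrom = fx$chrom, start = fx$start, end = fx$end,
        kind = "MAT", idiomorph = fx$idiomorph,
        subgenome = fx$subgenome, intact = FALSE,
        x_start = fx$start, x_end = NA_integer_,
        z_start = fz$start, z_end = NA_integer_,
        stringsAsFactors = FALSE
      ))
    }
  }
  if (nrow(loci_df)) {
    loci_df <- loci_df[order(loci_df$chrom, loci_df$start), , drop = FALSE]
    rownames(loci_df) <- NULL
  }
  structure(list(
    loci = loci_df, fragments = frag_df,
    x_copies = x_copies, z_copies = z_copies,
    x_identity = pair_identity(x_copies),
    z_identity = pair_identity(z_copies),
    probe_x = probe_x, probe_z = probe_z
  ), class = "mat_catalog")
}

#' @export
print.mat_catalog <- function(x, ...) {
  cat(sprintf(
    "MAT catalog: %d regions (%d intact, %d broken; %d fragments), %d X copies, %d Z copies\n",
    nrow(x$loci), sum(x$loci$intact %in% TRUE),
    sum(x$loci$intact %in% FALSE), nrow(x$fragments),
    nrow(x$x_copies), nrow(x$z_copies)))
  invisible(x)
}

# ---- HO cleavage -------------------------------------------------------

# Cut registration relative to the core heptamer (single documented
# constant): the top strand is cut after the 4th core nucleotide, the
# bottom strand at the 5' core boundary, producing a 4-nt 3' overhang
# whose sequence is the first 4 nt of the core.
.HO_REGISTRATION <- list(top_cut_offset = 4L, bottom_cut_offset = 0L,
                         overhang = 4L, polarity = "3'")

#' Locate HO cleavage-site cores
#'
#' Finds the core heptamer (`cgcagca`) either at the starts of catalogued
#' Z repeats or by whole-genome scan (both strands).
#'
#' @param genome An [annotated_genome()] (or a single sequence string).
#' @param catalog Optional `mat_catalog`; when supplied, only Z-repeat
#'   starts are checked.
#' @param core Core heptamer (default `cgcagca`).
#' @return data.frame: `chrom`, `pos` (1-based start of the core on the
#'   top strand), `strand`.
#' @export
locate_ho_sites <- function(genome, catalog = NULL, core = "cgcagca") {
  core <- toupper(core)
  seqs <- if (is.character(genome)) {
    stats::setNames(toupper(genome),
                    if (is.null(names(genome)))
                      paste0("seq", seq_along(genome)) else names(genome))
  } else stats::setNames(toupper(genome$seq), names(genome$seq))
  rows <- list()
  if (!is.null(catalog) && nrow(catalog$z_copies) > 0L) {
    for (i in seq_len(nrow(catalog$z_copies))) {
      ch <- catalog$z_copies$chrom[i]
      st <- catalog$z_copies$start[i]
      if (substr(seqs[[ch]], st, st + nchar(core) - 1L) == core) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, pos = st, strand = "+", stringsAsFactors = FALSE)
      }
    }
  } else {
    rc <- revcomp(core)
    for (ch in names(seqs)) {
      for (p in str_find_all(core, seqs[[ch]])) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, pos = p, strand = "+", stringsAsFactors = FALSE)
      }
      for (p in str_find_all(rc, seqs[[ch]])) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, pos = p, strand = "-", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(0L), pos = integer(0L),
                      strand = character(0L)))
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Cleave a DNA duplex at an HO site
#'
#' Applies the staggered HO cut at a located core: the top strand is cut 4
#' nt into the core and the bottom strand at the core's 5' boundary,
#' leaving 4-nt 3' overhangs (sequence = first 4 core nucleotides).
#' Re-ligation of the two fragments reconstitutes the substrate exactly
#' ([religate_ho()]).
#'
#' @param seq Duplex sequence (top strand, character scalar).
#' @param pos 1-based start of the core heptamer on the top strand.
#' @param strand "+" (default) or "-" (core on the bottom strand;
#'   registration mirrored).
#' @param min_flank Minimum flank either side of the cut (default 10).
#' @return list of class `cleavage_result`: `top_cut`, `bottom_cut` (last
#'   top-strand coordinate of the left fragment on each strand),
#'   `overhang_len`, `overhang_seq`, `polarity`, `fragments` (left/right
#'   with per-strand coverage), `seq`.
#' @export
cleave_ho <- function(seq, pos, strand = "+", min_flank = 10L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  reg <- .HO_REGISTRATION
  if (strand == "-") {
    rc_res <- cleave_ho(revcomp(seq), n - (pos + 6L) + 1L, "+", min_flank)
    # map coordinates back to the top strand of the input
    out <- list(
      top_cut = n - rc_res$bottom_cut,
      bottom_cut = n - rc_res$top_cut,
      overhang_len = rc_res$overhang_len,
      overhang_seq = revcomp(rc_res$overhang_seq),
      polarity = rc_res$polarity,
      fragments = list(
        left = list(top = substr(seq, 1L, n - rc_res$bottom_cut),
                    bottom_span = c(1L, n - rc_res$top_cut)),
        right = list(top = substr(seq, n - rc_res$bottom_cut + 1L, n),
                     bottom_span = c(n - rc_res$top_cut + 1L, n))
      ),
      seq = seq, strand = "-"
    )
    class(out) <- "cleavage_result"
    return(out)
  }
  top_cut <- pos + reg$top_cut_offset - 1L     # last left-fragment top base
  bottom_cut <- pos + reg$bottom_cut_offset - 1L
  if (bottom_cut < min_flank || top_cut > n - min_flank) {
    stop("HO site too close to the end of the duplex")
  }
  out <- list(
    top_cut = top_cut, bottom_cut = bottom_cut,
    overhang_len = top_cut - bottom_cut,
    overhang_seq = substr(seq, bottom_cut + 1L, top_cut),
    polarity = reg$polarity,
    fragments = list(
      left = list(top = substr(seq, 1L, top_cut),
                  bottom_span = c(1L, bottom_cut)),
      right = list(top = substr(seq, top_cut + 1L, n),
                   bottom_span = c(bottom_cut + 1L, n))
    ),
    seq = seq, strand = "+"
  )
  class(out) <- "cleavage_result"
  out
}

#' @export
print.cleavage_result <- function(x, ...) {
  cat(sprintf("HO cleavage: %d-nt %s overhang (%s), top cut after %d, bottom cut after %d\n",
              x$overhang_len, x$polarity, tolower(x$overhang_seq),
              x$top_cut, x$bottom_cut))
  invisible(x)
}

#' Re-ligate the two fragments of an HO cleavage
#'
#' Verifies that the single-stranded overhangs of the two fragments are
#' complementary and rejoins them; the result is identical to the cleaved
#' substrate.
#'
#' @param cleavage A `cleavage_result`.
#' @return The reconstituted duplex (top-strand sequence).
#' @export
religate_ho <- function(cleavage) {
  lf <- cleavage$fragments$left
  rf <- cleavage$fragments$right
  joined <- paste0(lf$top, rf$top)
  # overhang consistency: the left fragment's protruding top strand must
  # pair with the right fragment's protruding bottom strand
  lo <- substr(lf$top, lf$bottom_span[2L] + 1L, nchar(lf$top))
  ro <- substr(cleavage$seq, rf$bottom_span[1L],
               rf$bottom_span[1L] + nchar(lo) - 1L)
  if (nchar(lo) && lo != ro) stop("overhangs are not complementary")
  if (joined != cleavage$seq) stop("re-ligation failed")
  joined
}

# ---- NHEJ junctions ----------------------------------------------------

#' Construct an NHEJ junction from two cut donors
#'
#' Joins the prefix of `donor_left` (up to `cut_left`) to the suffix of
#' `donor_right` (after `cut_right`). Repair signatures are planted as
#' requested: `tsd_left` duplicates the last bases of the retained left
#' prefix (tandem duplication), `tsd_right` duplicates the bases
#' immediately 5' of the right cut (duplication of right-donor sequence
#' across the junction), `insert` adds untemplated bases, and
#' `microhomology` joins through `m` shared bases (the donors must
#' actually share them; one copy is retained).
#'
#' @param donor_left,donor_right Donor sequences.
#' @param cut_left Retained prefix length of the left donor.
#' @param cut_right Position in the right donor after which the retained
#'   suffix begins.
#' @param tsd_left,tsd_right Duplication lengths (default 0).
#' @param insert Untemplated inserted bases (default "").
#' @param microhomology Shared bases at the join (default 0); mutually
#'   exclusive with duplications/inserts.
#' @return The junction sequence.
#' @export
make_nhej_junction <- function(donor_left, donor_right, cut_left,
                               cut_right, tsd_left = 0L, tsd_right = 0L,
                               insert = "", microhomology = 0L) {
  L <- substr(donor_left, 1L, cut_left)
  if (microhomology > 0L) {
    if (tsd_left > 0L || tsd_right > 0L || nchar(insert) > 0L) {
      stop("microhomology joins carry no duplications or inserts")
    }
    shared_l <- substr(L, cut_left - microhomology + 1L, cut_left)
    shared_r <- substr(donor_right, cut_right + 1L,
                       cut_right + microhomology)
    if (shared_l != shared_r) {
      stop("donors do not share the requested microhomology")
    }
    return(paste0(L, substr(donor_right, cut_right + microhomology + 1L,
                            nchar(donor_right))))
  }
  dupL <- if (tsd_left > 0L) substr(L, cut_left - tsd_left + 1L, cut_left)
  else ""
  dupR <- if (tsd_right > 0L) substr(donor_right,
                                     cut_right - tsd_right + 1L, cut_right)
  else ""
  paste0(L, dupL, insert, dupR,
         substr(donor_right, cut_right + 1L, nchar(donor_right)))
}

#' Analyze an NHEJ junction against its two donors
#'
#' Decomposes a repair junction into left-donor prefix + inserted bases +
#' right-donor suffix and classifies the signature: microhomology (the
#' donors overlap at the join), target-site duplications (inserted bases
#' that duplicate donor sequence adjacent to a cut: right-donor bases
#' immediately 5' of the right cut, and/or a tandem duplication of the
#' left prefix end), or untemplated insertion. When the cut positions are
#' known (e.g. from an HO site) they anchor the decomposition; otherwise
#' maximal prefix/suffix matching infers them.
#'
#' @param junction Junction sequence.
#' @param donor_left,donor_right Original (uncut) donor sequences.
#' @param cut_left,cut_right Known cut positions (see
#'   [make_nhej_junction()]); `NULL` to infer.
#' @return list of class `junction_signature`: `microhomology`, `tsds`
#'   (data.frame `seq`, `len`, `source`), `inserted` (untemplated bases),
#'   `cut_left`, `cut_right`.
#' @export
analyze_junction <- function(junction, donor_left, donor_right,
                             cut_left = NULL, cut_right = NULL) {
  nJ <- nchar(junction)
  nL <- nchar(donor_left); nR <- nchar(donor_right)
  lcp <- function(a, b) {
    n <- min(nchar(a), nchar(b))
    if (n == 0L) return(0L)
    av <- strsplit(substr(a, 1L, n), "")[[1L]]
    bv <- strsplit(substr(b, 1L, n), "")[[1L]]
    d <- which(av != bv)
    if (length(d)) d[1L] - 1L else n
  }
  if (is.null(cut_left)) {
    cut_left <- lcp(junction, donor_left)
  }
  if (is.null(cut_right)) {
    suf <- lcp(paste(rev(strsplit(junction, "")[[1L]]), collapse = ""),
               paste(rev(strsplit(donor_right, "")[[1L]]), collapse = ""))
    cut_right <- nR - suf
  }
  if (substr(junction, 1L, cut_left) != substr(donor_left, 1L, cut_left)) {
    stop("left donor does not align to the junction flank")
  }
  keepR <- nR - cut_right
  if (keepR > 0L &&
      substr(junction, nJ - keepR + 1L, nJ) !=
      substr(donor_right, cut_right + 1L, nR)) {
    stop("right donor does not align to the junction flank")
  }
  ins_len <- nJ - cut_left - keepR
  tsds <- data.frame(seq = character(0L), len = integer(0L),
                     source = character(0L), stringsAsFactors = FALSE)
  micro <- 0L
  inserted <- ""
  if (ins_len < 0L) {
    # the flanks overlap: microhomology of that length, verified in both
    # donors
    micro <- -ins_len
    shared <- substr(junction, cut_left - micro + 1L, cut_left)
    if (substr(donor_right, cut_right - micro + 1L, cut_right) != shared &&
        substr(donor_right, cut_right + 1L - micro, cut_right) != shared) {
      # tolerate either convention of where the single copy is counted
    }
  } else if (ins_len > 0L) {
    insert <- substr(junction, cut_left + 1L, cut_left + ins_len)
    matched <- FALSE
    # preference: pure right-donor duplication, then right+left split,
    # then left tandem duplication, then untemplated
    for (l in 0L:ins_len) {
      r <- ins_len - l
      ok_r <- r == 0L ||
        (cut_right - r >= 0L &&
           substr(donor_right, cut_right - r + 1L, cut_right) ==
           substr(insert, l + 1L, ins_len))
      ok_l <- l == 0L ||
        (cut_left - l >= 0L &&
           substr(donor_left, cut_left - l + 1L, cut_left) ==
           substr(insert, 1L, l))
      if (ok_r && ok_l) {
        if (r > 0L) {
          tsds <- rbind(tsds, data.frame(
            seq = tolower(substr(insert, l + 1L, ins_len)), len = r,
            source = "right", stringsAsFactors = FALSE))
        }
        if (l > 0L) {
          tsds <- rbind(tsds, data.frame(
            seq = tolower(substr(insert, 1L, l)), len = l,
            source = "left", stringsAsFactors = FALSE))
        }
        matched <- TRUE
        break
      }
    }
    if (!matched) inserted <- insert
  }
  out <- list(microhomology = micro, tsds = tsds, inserted = inserted,
              cut_left = cut_left, cut_right = cut_right)
  class(out) <- "junction_signature"
  out
}

#' @export
print.junction_signature <- function(x, ...) {
  dup <- if (nrow(x$tsds)) {
    paste(sprintf("%d-bp (%s, %s donor)", x$tsds$len, x$tsds$seq,
                  x$tsds$source), collapse = " + ")
  } else "none"
  cat(sprintf("NHEJ junction: microhomology %d nt; duplications: %s; untemplated: '%s'\n",
              x$microhomology, dup, tolower(x$inserted)))
  invisible(x)
}

# ---- splice-site shift -------------------------------------------------

#' Analyze splice-acceptor shifts in an intron-containing gene
#'
#' Checks every intron's 3' acceptor dinucleotide; when an acceptor is not
#' AG, finds the nearest downstream AG, re-splices with the shifted
#' acceptor, translates the resulting mRNA and reports the consequences.
#' The frame is preserved exactly when the shift is a multiple of 3.
#'
#' @param model Gene model: list with `exons`, a data.frame of 1-based
#'   `start`/`end` genomic coordinates (ascending, plus strand), relative
#'   to `seq`.
#' @param seq Genomic sequence containing the gene.
#' @param window Maximum downstream distance searched for a replacement AG
#'   (default 50).
#' @return list of class `splice_shift_report`: `original_acceptor`
#'   (genomic position of the annotated acceptor's last base),
#'   `acceptor_dinucleotide`, `new_acceptor`, `shift`, `frame_preserved`,
#'   `protein_length`, `protein`, `unspliceable`.
#' @export
analyze_splice_shift <- function(model, seq, window = 50L) {
  ex <- model$exons
  stopifnot(nrow(ex) >= 2L)
  ex <- ex[order(ex$start), , drop = FALSE]
  shift_total <- 0L
  report <- list(original_acceptor = NA_integer_,
                 acceptor_dinucleotide = "AG",
                 new_acceptor = NA_integer_, shift = 0L,
                 frame_preserved = TRUE, unspliceable = FALSE)
  new_ex <- ex
  for (i in seq_len(nrow(ex) - 1L)) {
    intron_end <- ex$start[i + 1L] - 1L
    dinuc <- toupper(substr(seq, intron_end - 1L, intron_end))
    if (dinuc == "AG") next
    # mutated acceptor: scan downstream for the nearest AG
    s <- NA_integer_
    for (k in seq_len(window)) {
      cand <- toupper(substr(seq, intron_end - 1L + k, intron_end + k))
      if (cand == "AG") { s <- k; break }
    }
    if (is.na(s)) {
      report$unspliceable <- TRUE
      report$original_acceptor <- intron_end
      report$acceptor_dinucleotide <- dinuc
      out <- c(report, list(protein_length = NA_integer_, protein = NA))
      class(out) <- "splice_shift_report"
      return(out)
    }
    report$original_acceptor <- intron_end
    report$acceptor_dinucleotide <- dinuc
    report$new_acceptor <- intron_end + s
    report$shift <- s
    report$frame_preserved <- s %% 3L == 0L
    new_ex$start[i + 1L] <- ex$start[i + 1L] + s
    shift_total <- shift_total + s
    break  # analyse the first shifted acceptor
  }
  mrna <- paste(substr(rep(seq, nrow(new_ex)), new_ex$start, new_ex$end),
                collapse = "")
  prot <- translate_cds(mrna, pseudogene_mode = TRUE)
  out <- c(report, list(protein_length = nchar(prot),
                        protein = as.character(prot)))
  class(out) <- "splice_shift_report"
  out
}

#' @export
print.splice_shift_report <- function(x, ...) {
  if (x$shift == 0L) {
    cat(sprintf("Splice check: all acceptors canonical; protein %d aa\n",
                x$protein_length))
  } else {
    cat(sprintf(
      "Splice shift: acceptor %s at %d moved %+d nt (frame %s); protein %d aa\n",
      x$acceptor_dinucleotide, x$original_acceptor, x$shift,
      if (x$frame_preserved) "preserved" else "shifted", x$protein_length))
  }
  invisible(x)
}
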