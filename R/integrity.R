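# Gene-integrity screening: the homeolog length-ratio screen for
# disabling mutations, mechanism typing, cross-strain comparison of
# disablement calls, in-frame introns, and programmed +1 frameshift
# sites.

#' Screen homeolog pairs for disabling mutations
#'
#' Flags pairs in which one member's predicted protein is shorter than
#' `ratio_threshold` times the other's (the threshold is strict: a ratio
#' exactly at the threshold passes). When coding sequences are supplied
#' the mechanism is refined by [detect_mechanism()].
#'
#' @param pairs data.frame with `gene_a`, `gene_b`.
#' @param proteins Named character vector of predicted proteins
#'   (translate damaged CDS with `pseudogene_mode = TRUE`).
#' @param ratio_threshold Length-ratio threshold (default 0.9).
#' @param cds Optional named character vector of coding sequences used for
#'   mechanism refinement.
#' @return data.frame: `gene_id` (the damaged, shorter member), `partner`,
#'   `len_damaged`, `len_intact`, `length_ratio`, `mechanism`.
#' @export
screen_pairs <- function(pairs, proteins, ratio_threshold = 0.9,
                         cds = NULL) {
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    la <- nchar(proteins[[a]]); lb <- nchar(proteins[[b]])
    if (max(la, lb) == 0L) next
    ratio <- min(la, lb) / max(la, lb)
    if (ratio >= ratio_threshold) next
    damaged <- if (la < lb) a else b
    intact <- if (la < lb) b else a
    mech <- "length-only"
    if (!is.null(cds) && damaged %in% names(cds) && intact %in% names(cds)) {
      mech <- tryCatch(detect_mechanism(cds[[damaged]], cds[[intact]]),
                       error = function(e) "length-only")
      if (is.list(mech)) mech <- mech$mechanism
    }
    out[[length(out) + 1L]] <- data.frame(
      gene_id = damaged, partner = intact,
      len_damaged = min(la, lb), len_intact = max(la, lb),
      length_ratio = ratio, mechanism = mech, stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    return(data.frame(gene_id = character(0L), partner = character(0L),
                      len_damaged = integer(0L), len_intact = integer(0L),
                      length_ratio = numeric(0L), mechanism = character(0L)))
  }
  do.call(rbind, out)
}

#' Determine the disabling mechanism of a damaged coding sequence
#'
#' Compares a damaged CDS to its intact homeolog: a length difference
#' that is not a multiple of 3 is a frameshift indel (localised at the
#' first point of divergence); otherwise an in-frame premature stop codon
#' is searched for. Calling this on an undamaged (identical) pair is an
#' error.
#'
#' @param cds_broken,cds_intact Coding sequences.
#' @return list: `mechanism` ("frameshift-indel", "premature-stop" or
#'   "length-only"), `position` (1-based nucleotide of the first
#'   divergence, or codon index of the stop).
#' @export
detect_mechanism <- function(cds_broken, cds_intact) {
  cds_broken <- toupper(cds_broken); cds_intact <- toupper(cds_intact)
  if (cds_broken == cds_intact) {
    stop("sequences are identical: no disabling mechanism to call")
  }
  d <- nchar(cds_broken) - nchar(cds_intact)
  # first divergence point
  n <- min(nchar(cds_broken), nchar(cds_intact))
  av <- strsplit(substr(cds_broken, 1L, n), "")[[1L]]
  bv <- strsplit(substr(cds_intact, 1L, n), "")[[1L]]
  w <- which(av != bv)
  first_div <- if (length(w)) w[1L] else n + 1L
  if (d %% 3L != 0L) {
    return(list(mechanism = "frameshift-indel", position = first_div))
  }
  p <- translate_cds(cds_broken, pseudogene_mode = TRUE)
  if (isTRUE(attr(p, "premature_stop"))) {
    return(list(mechanism = "premature-stop",
                position = attr(p, "stop_codon_index")))
  }
  list(mechanism = "length-only", position = first_div)
}

#' Partition disablement calls into shared and strain-unique sets
#'
#' Calls from two strains are compared by gene id (use a shared
#' orthologous naming, e.g. the simulator's base ids) and mechanism
#' class: a call is shared when the same gene carries the same mechanism
#' in both strains.
#'
#' @param calls_1,calls_2 data.frames with `gene_id` and `mechanism`.
#' @return list: `shared` (data.frame of shared calls), `unique_1`,
#'   `unique_2`.
#' @export
compare_strains <- function(calls_1, calls_2) {
  key1 <- paste(calls_1$gene_id, calls_1$mechanism)
  key2 <- paste(calls_2$gene_id, calls_2$mechanism)
  shared <- calls_1[key1 %in% key2, , drop = FALSE]
  list(shared = shared,
       unique_1 = calls_1[!(key1 %in% key2), , drop = FALSE],
       unique_2 = calls_2[!(key2 %in% key1), , drop = FALSE])
}

#' Find in-frame introns
#'
#' An in-frame intron has a length that is a multiple of 3 and contains no
#' stop codon in its reading frame, so both the spliced and the unspliced
#' mRNA translate into protein. The check translates the unspliced
#' transcript with the candidate intron retained.
#'
#' @param models List of gene models: each a list with `gene_id` and
#'   `exons` (data.frame of ascending 1-based `start`/`end` within the
#'   gene's sequence).
#' @param seqs Named character vector of the genomic sequences the models
#'   refer to (names matched by each model's `chrom`, or a single
#'   unnamed sequence).
#' @return data.frame of qualifying introns: `gene_id`, `intron_index`,
#'   `start`, `end`, `length`.
#' @export
find_inframe_introns <- function(models, seqs) {
  out <- list()
  for (m in models) {
    seq <- if (is.null(m$chrom)) seqs[[1L]] else seqs[[m$chrom]]
    ex <- m$exons[order(m$exons$start), , drop = FALSE]
    if (nrow(ex) < 2L) next
    for (i in seq_len(nrow(ex) - 1L)) {
      istart <- ex$end[i] + 1L
      iend <- ex$start[i + 1L] - 1L
      ilen <- iend - istart + 1L
      if (ilen <= 0L || ilen %% 3L != 0L) next
      # unspliced transcript with this intron retained, others spliced out
      keep <- ex
      keep$end[i] <- ex$end[i + 1L]
      keep <- keep[-(i + 1L), , drop = FALSE]
      mrna <- paste(substr(rep(seq, nrow(keep)), keep$start, keep$end),
                    collapse = "")
      p <- translate_cds(mrna, pseudogene_mode = TRUE)
      if (!isTRUE(attr(p, "premature_stop"))) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = m$gene_id, intron_index = i, start = istart,
          end = iend, length = ilen, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(gene_id = character(0L), intron_index = integer(0L),
                      start = integer(0L), end = integer(0L),
                      length = integer(0L)))
  }
  do.call(rbind, out)
}

.PLUS1_MOTIFS <- c("CTT-A-GTT" = "CTTAGTT", "CTT-A-GGC" = "CTTAGGC")

#' Find programmed +1 frameshift candidate sites
#'
#' Scans coding sequences for the EST3-type (`CTT-A-GTT`) and ABP140-type
#' (`CTT-A-GGC`) motifs at in-frame positions (the CTT is a codon and the
#' A is the skipped nucleotide). A site qualifies when the zero frame
#' terminates within `near_stop` codons downstream of the motif while the
#' +1 frame stays open for at least `min_ext` codons.
#'
#' @param cds_set Named character vector of coding sequences.
#' @param min_ext Minimum +1 frame extension in codons (default 30).
#' @param near_stop Maximum zero-frame distance to a stop, in codons
#'   (default 30).
#' @return data.frame: `gene_id`, `pos` (1-based position of the motif),
#'   `motif`, `skipped_base`.
#' @export
find_plus1_sites <- function(cds_set, min_ext = 30L, near_stop = 30L) {
  ct <- codon_tables()
  out <- list()
  for (g in names(cds_set)) {
    cds <- toupper(cds_set[[g]])
    for (mi in seq_along(.PLUS1_MOTIFS)) {
      motif <- .PLUS1_MOTIFS[[mi]]
      for (p in str_find_all(motif, cds)) {
        if ((p - 1L) %% 3L != 0L) next  # CTT must be a codon
        # zero frame: first stop at/after the motif
        zf <- substring(cds, seq(p, nchar(cds) - 2L, by = 3L),
                        seq(p + 2L, nchar(cds), by = 3L))
        zf <- zf[nchar(zf) == 3L]
        zstop <- which(ct$aa[zf] == "*")
        if (length(zstop) == 0L || zstop[1L] > near_stop) next
        # +1 frame: codons after the skipped A
        q <- p + 4L
        if (q + 2L > nchar(cds)) next
        pf <- substring(cds, seq(q, nchar(cds) - 2L, by = 3L),
                        seq(q + 2L, nchar(cds), by = 3L))
        pf <- pf[nchar(pf) == 3L]
        pstop <- which(ct$aa[pf] == "*")
        open <- if (length(pstop) == 0L) length(pf) else pstop[1L] - 1L
        if (open < min_ext) next
        out[[length(out) + 1L]] <- data.frame(
          gene_id = g, pos = p, motif = names(.PLUS1_MOTIFS)[mi],
          skipped_base = "A", stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(gene_id = character(0L), pos = integer(0L),
                      motif = character(0L), skipped_base = character(0L)))
  }
  do.call(rbind, out)
}
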