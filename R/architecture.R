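# Gene-order archaeology: synteny blocks and breakpoints between two gene
# orders, rearrangement-event estimation, LOH tract segmentation,
# recombination junction detection, BIR end flagging and telomere repeat
# consensus.

# normalise a homolog map: data.frame(x, y), one-to-one
.norm_homolog_map <- function(order_x, order_y, homolog_map) {
  if (is.null(homolog_map)) {
    shared <- intersect(order_x$gene_id, order_y$gene_id)
    homolog_map <- data.frame(x = shared, y = shared,
                              stringsAsFactors = FALSE)
  }
  names(homolog_map)[1:2] <- c("x", "y")
  if (anyDuplicated(homolog_map$x) || anyDuplicated(homolog_map$y)) {
    stop("homolog map must be one-to-one")
  }
  homolog_map[homolog_map$x %in% order_x$gene_id &
                homolog_map$y %in% order_y$gene_id, , drop = FALSE]
}

# adjacency list between consecutive mapped genes in x, with the
# intact/broken verdict against y
.adjacency_table <- function(order_x, order_y, homolog_map, max_gap) {
  map <- .norm_homolog_map(order_x, order_y, homolog_map)
  ox <- order_x[order_x$gene_id %in% map$x, , drop = FALSE]
  yid <- stats::setNames(map$y, map$x)
  oy <- order_y
  ypos <- stats::setNames(oy$index, oy$gene_id)
  ychr <- stats::setNames(oy$chrom, oy$gene_id)
  ystr <- stats::setNames(oy$strand, oy$gene_id)
  xall_pos <- stats::setNames(order_x$index, order_x$gene_id)

  rows <- list()
  for (chr in unique(ox$chrom)) {
    sub <- ox[ox$chrom == chr, , drop = FALSE]
    sub <- sub[order(sub$index), , drop = FALSE]
    n <- nrow(sub)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      g <- sub$gene_id[i]; h <- sub$gene_id[i + 1L]
      # unmapped intervening genes beyond max_gap: no adjacency to test
      if (sub$index[i + 1L] - sub$index[i] - 1L > max_gap) next
      hg <- yid[[g]]; hh <- yid[[h]]
      fg <- if (ystr[[hg]] == sub$strand[i]) 1L else -1L
      fh <- if (ystr[[hh]] == sub$strand[i + 1L]) 1L else -1L
      intact <- FALSE
      if (ychr[[hg]] == ychr[[hh]] && fg == fh) {
        d <- ypos[[hh]] - ypos[[hg]]
        if (fg == 1L) intact <- d >= 1L && d <= max_gap + 1L
        else intact <- d <= -1L && d >= -(max_gap + 1L)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chr, left = g, right = h, intact = intact,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(0L), left = character(0L),
                      right = character(0L), intact = logical(0L)))
  }
  do.call(rbind, rows)
}

#' Count synteny breakpoints between two gene orders
#'
#' An adjacency is a pair of genes consecutive (up to `max_gap` unmapped
#' intervening genes) on a chromosome of the first order; it is broken
#' when the two homologs are on different chromosomes in the second order,
#' are not adjacent there (beyond `max_gap`), or disagree in relative
#' orientation. Chromosome ends are not adjacencies. Each inversion or
#' reciprocal translocation creates two breakpoints, which is what the
#' downstream event estimator divides by.
#'
#' @param order_x,order_y Gene-order tables: data.frames with `gene_id`,
#'   `chrom`, `index` (1..n along each chromosome) and `strand`.
#' @param homolog_map One-to-one data.frame mapping x genes (col 1) to y
#'   genes (col 2); `NULL` uses shared gene ids.
#' @param max_gap Tolerated unmapped intervening genes (default 0).
#' @return list of class `breakpoint_set`: `count`, `events`
#'   (`count %/% 2`), `odd` flag, and the `adjacencies` table with the
#'   per-adjacency verdict.
#' @export
count_breakpoints <- function(order_x, order_y, homolog_map = NULL,
                              max_gap = 0L) {
  adj <- .adjacency_table(order_x, order_y, homolog_map, max_gap)
  b <- sum(!adj$intact)
  out <- list(count = b, events = b %/% 2L, odd = b %% 2L == 1L,
              adjacencies = adj)
  class(out) <- "breakpoint_set"
  out
}

#' @export
print.breakpoint_set <- function(x, ...) {
  cat(sprintf("Synteny breakpoints: %d (~%d rearrangement events%s)\n",
              x$count, x$events,
              if (x$odd) "; odd breakpoint count" else ""))
  invisible(x)
}

#' Estimate rearrangement events from a breakpoint count
#'
#' Each reciprocal translocation or inversion creates two synteny
#' breakpoints, so the event estimate is the integer half of the
#' breakpoint count; an odd count (one breakpoint unaccounted for, e.g. a
#' non-reciprocal event) raises a warning.
#'
#' @param b Breakpoint count (non-negative integer).
#' @return Integer event estimate (`b %/% 2`).
#' @export
estimate_events <- function(b) {
  if (b < 0) stop("negative breakpoint count")
  if (b %% 2L == 1L) {
    warning("odd breakpoint count ", b,
            ": event estimate assumes reciprocal events")
  }
  as.integer(b) %/% 2L
}

#' Build synteny blocks between two gene orders
#'
#' Maximal runs of homologs that are collinear in both genomes (same or
#' reversed order with consistent strands), tolerating up to `max_gap`
#' unmapped intervening genes.
#'
#' @inheritParams count_breakpoints
#' @return data.frame: one block per row with `chrom_x`, `chrom_y`,
#'   `x_first`, `x_last`, `y_first`, `y_last` (index ranges),
#'   `orientation` ("+"/"-") and `n_genes`.
#' @export
build_synteny_blocks <- function(order_x, order_y, homolog_map = NULL,
                                 max_gap = 0L) {
  map <- .norm_homolog_map(order_x, order_y, homolog_map)
  adj <- .adjacency_table(order_x, order_y, homolog_map, max_gap)
  yid <- stats::setNames(map$y, map$x)
  ypos <- stats::setNames(order_y$index, order_y$gene_id)
  ychr <- stats::setNames(order_y$chrom, order_y$gene_id)
  ystr <- stats::setNames(order_y$strand, order_y$gene_id)
  xpos <- stats::setNames(order_x$index, order_x$gene_id)
  xstr <- stats::setNames(order_x$strand, order_x$gene_id)

  ok_next <- stats::setNames(adj$intact, paste(adj$left, adj$right))
  blocks <- list()
  ox <- order_x[order_x$gene_id %in% map$x, , drop = FALSE]
  for (chr in unique(ox$chrom)) {
    sub <- ox[ox$chrom == chr, , drop = FALSE]
    sub <- sub[order(sub$index), , drop = FALSE]
    ids <- sub$gene_id
    start <- 1L
    n <- length(ids)
    for (i in seq_len(n)) {
      chain_on <- FALSE
      if (i < n) {
        key <- paste(ids[i], ids[i + 1L])
        chain_on <- isTRUE(ok_next[[key]])
      }
      if (!chain_on) {
        members <- ids[start:i]
        hy <- yid[members]
        ori <- if (length(members) == 1L) {
          if (ystr[[hy[1L]]] == xstr[[members[1L]]]) "+" else "-"
        } else if (ypos[[hy[2L]]] > ypos[[hy[1L]]]) "+" else "-"
        blocks[[length(blocks) + 1L]] <- data.frame(
          chrom_x = chr, chrom_y = ychr[[hy[1L]]],
          x_first = xpos[[members[1L]]],
          x_last = xpos[[members[length(members)]]],
          y_first = ypos[[hy[1L]]],
          y_last = ypos[[hy[length(hy)]]],
          orientation = ori, n_genes = length(members),
          stringsAsFactors = FALSE
        )
        start <- i + 1L
      }
    }
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Segment loss-of-heterozygosity tracts from a categorized gene table
#'
#' LOH tracts are maximal runs of at least `min_run` consecutive genes in
#' same-label pair categories (A members of A:A pairs or B members of B:B
#' pairs). N genes are transparent (they do not interrupt a run). The
#' background class of a tract is the majority label of its flanking
#' non-tract A/B genes (up to `flank` genes per side), which stays correct
#' on chromosomes recombined into part-A/part-B mosaics.
#'
#' @param genes Categorized gene table (from [categorize()]; needs
#'   `gene_id`, `chrom`, `index`, `label`, `category`).
#' @param min_run Minimum tract length in genes (default 3).
#' @param flank Flanking genes per side used for the background vote
#'   (default 10).
#' @param exclude Optional character vector of gene ids to mask (e.g.
#'   BIR-homogenised chromosome ends, which are terminal same-label runs
#'   of a different origin).
#' @return data.frame: `chrom`, `tract_class`, `background`,
#'   `start_index`, `end_index`, `length`, `first_gene`, `last_gene`.
#' @export
segment_loh_tracts <- function(genes, min_run = 3L, flank = 10L,
                               exclude = character(0L)) {
  out <- list()
  for (chr in unique(genes$chrom)) {
    df <- genes[genes$chrom == chr, , drop = FALSE]
    df <- df[order(df$index), , drop = FALSE]
    if (!any(df$label %in% c("A", "B"))) {
      warning("chromosome ", chr, " has no A/B genes; skipped")
      next
    }
    vis <- df[df$label != "N", , drop = FALSE]  # N genes transparent
    state <- ifelse(vis$category %in% c("A-in-A:A", "B-in-B:B") &
                      !(vis$gene_id %in% exclude),
                    vis$category, "bg")
    r <- rle(state)
    r$values <- r$values != "bg"
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_run)) {
      rows <- starts[k]:ends[k]
      lab <- vis$label[rows[1L]]
      lf <- if (starts[k] > 1L) {
        vis$label[max(1L, starts[k] - flank):(starts[k] - 1L)]
      } else character(0L)
      rt <- if (ends[k] < nrow(vis)) {
        vis$label[(ends[k] + 1L):min(nrow(vis), ends[k] + flank)]
      } else character(0L)
      fl <- c(lf, rt)
      fl <- fl[fl %in% c("A", "B")]
      bg <- if (length(fl)) names(sort(table(fl), decreasing = TRUE))[1L]
      else {
        ab <- df$label[df$label %in% c("A", "B")]
        names(sort(table(ab), decreasing = TRUE))[1L]
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, tract_class = lab, background = bg,
        start_index = vis$index[rows[1L]],
        end_index = vis$index[rows[length(rows)]],
        length = length(rows),
        first_gene = vis$gene_id[rows[1L]],
        last_gene = vis$gene_id[rows[length(rows)]],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0L), tract_class = character(0L),
                      background = character(0L), start_index = integer(0L),
                      end_index = integer(0L), length = integer(0L),
                      first_gene = character(0L), last_gene = character(0L)))
  }
  do.call(rbind, out)
}

#' Detect interhomeolog recombination junctions
#'
#' Junctions are positions where the subgenome background switches
#' persistently along a chromosome: among genes that are members of A:B
#' pairs (LOH-pair, unpaired and N genes are transparent), a switch
#' between two runs each of at least `min_run` genes of their own class is
#' a crossover junction. LOH tracts do not qualify because their genes are
#' not in A:B pairs.
#'
#' @inheritParams segment_loh_tracts
#' @param min_run Minimum flank run length per side (default 3).
#' @return data.frame: `chrom`, `left_gene`, `right_gene`, `left_index`,
#'   `right_index`.
#' @export
detect_recombination_junctions <- function(genes, min_run = 3L) {
  out <- list()
  for (chr in unique(genes$chrom)) {
    df <- genes[genes$chrom == chr, , drop = FALSE]
    df <- df[order(df$index), , drop = FALSE]
    vis <- df[df$category %in% c("A-in-A:B", "B-in-A:B"), , drop = FALSE]
    if (nrow(vis) < 2L * min_run) next
    r <- rle(vis$label)
    if (length(r$lengths) < 2L) next
    ends <- cumsum(r$lengths)
    for (k in seq_len(length(r$lengths) - 1L)) {
      if (r$lengths[k] >= min_run && r$lengths[k + 1L] >= min_run) {
        li <- ends[k]; ri <- ends[k] + 1L
        out[[length(out) + 1L]] <- data.frame(
          chrom = chr,
          left_gene = vis$gene_id[li], right_gene = vis$gene_id[ri],
          left_index = vis$index[li], right_index = vis$index[ri],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0L), left_gene = character(0L),
                      right_gene = character(0L), left_index = integer(0L),
                      right_index = integer(0L)))
  }
  do.call(rbind, out)
}

#' Flag break-induced replication (BIR) chromosome ends
#'
#' A BIR event copies one chromosome end onto another, leaving the two
#' ends sequence-identical from an initiation point out to the telomere.
#' Candidate ends are terminal runs of at least `min_bir_genes` same-label
#' genes that are either unpaired or members of same-label pairs; a
#' candidate becomes a flag when another candidate end of the same label
#' shares at least `id_min` sequence identity over the shorter terminal
#' region. Each homogenised end pair is reported once. Candidate runs
#' without an identity-confirmed partner (e.g. homeologs widowed by the
#' event, or collapsed-assembly artefacts) are returned separately.
#'
#' @param genes Categorized gene table (needs `gene_id`, `chrom`,
#'   `index`, `start`, `end`, `label`, `category`).
#' @param genome The [annotated_genome()] the table was derived from.
#' @param min_bir_genes Minimum terminal run length (default 5).
#' @param id_min Minimum sequence identity between partner ends
#'   (default 0.95).
#' @return list with `flags` (one row per homogenised end pair: `chrom`,
#'   `side`, `run_genes`, `partner_chrom`, `partner_side`, `identity`) and
#'   `candidates` (unmatched candidate ends).
#' @export
flag_bir_ends <- function(genes, genome, min_bir_genes = 5L,
                          id_min = 0.95) {
  cands <- list()
  for (chr in unique(genes$chrom)) {
    df <- genes[genes$chrom == chr, , drop = FALSE]
    df <- df[order(df$index), , drop = FALSE]
    for (side in c("L", "R")) {
      v <- if (side == "L") seq_len(nrow(df)) else rev(seq_len(nrow(df)))
      lab0 <- NULL
      run <- integer(0L)
      for (i in v) {
        L <- df$label[i]
        ok <- L %in% c("A", "B") &&
          df$category[i] %in% paste0(L, c("-unpaired",
                                          sprintf("-in-%s:%s", L, L)))
        if (!ok) break
        if (is.null(lab0)) lab0 <- L
        if (L != lab0) break
        run <- c(run, i)
      }
      if (length(run) >= min_bir_genes) {
        # terminal sequence from the run's inner boundary to the telomere
        if (side == "L") {
          span <- substr(genome$seq[[chr]], 1L, max(df$end[run]))
        } else {
          span <- substr(genome$seq[[chr]], min(df$start[run]),
                         nchar(genome$seq[[chr]]))
        }
        cands[[length(cands) + 1L]] <- list(
          chrom = chr, side = side, label = lab0,
          run_genes = df$gene_id[run], seq = span
        )
      }
    }
  }
  term_identity <- function(a, b, side) {
    n <- min(nchar(a), nchar(b))
    if (n == 0L) return(0)
    sa <- if (side == "R") substr(a, nchar(a) - n + 1L, nchar(a)) else
      substr(a, 1L, n)
    sb <- if (side == "R") substr(b, nchar(b) - n + 1L, nchar(b)) else
      substr(b, 1L, n)
    mean(strsplit(sa, "")[[1L]] == strsplit(sb, "")[[1L]])
  }
  used <- rep(FALSE, length(cands))
  flags <- list()
  masked <- character(0L)
  if (length(cands) >= 2L) {
    for (i in seq_along(cands)) {
      if (used[i]) next
      best <- NULL
      for (j in seq_along(cands)) {
        if (j == i || used[j]) next
        if (cands[[i]]$label != cands[[j]]$label) next
        if (cands[[i]]$side != cands[[j]]$side) next
        idy <- term_identity(cands[[i]]$seq, cands[[j]]$seq,
                             cands[[i]]$side)
        if (idy >= id_min && (is.null(best) || idy > best$idy)) {
          best <- list(j = j, idy = idy)
        }
      }
      if (!is.null(best)) {
        used[i] <- used[best$j] <- TRUE
        masked <- c(masked, cands[[i]]$run_genes,
                    cands[[best$j]]$run_genes)
        flags[[length(flags) + 1L]] <- data.frame(
          chrom = cands[[i]]$chrom, side = cands[[i]]$side,
          n_genes = length(cands[[i]]$run_genes),
          partner_chrom = cands[[best$j]]$chrom,
          partner_side = cands[[best$j]]$side,
          identity = best$idy, stringsAsFactors = FALSE
        )
      }
    }
  }
  unmatched <- cands[!used]
  cand_df <- if (length(unmatched)) {
    do.call(rbind, lapply(unmatched, function(x) {
      data.frame(chrom = x$chrom, side = x$side, label = x$label,
                 n_genes = length(x$run_genes), stringsAsFactors = FALSE)
    }))
  } else data.frame()
  flag_df <- if (length(flags)) do.call(rbind, flags) else data.frame()
  list(flags = flag_df, candidates = cand_df, masked_genes = masked)
}

#' Telomeric repeat consensus from chromosome ends
#'
#' Examines a terminal window at every chromosome end (left ends are
#' reverse-complemented so both ends read in the same orientation),
#' detects the shortest tandem period at the terminus, and reports the
#' majority repeat unit normalised to its lexicographically minimal
#' rotation, together with the as-found orientation and any minority
#' units.
#'
#' @param genome An [annotated_genome()], or a character vector of
#'   end sequences already oriented telomere-rightward.
#' @param window Terminal window examined (default 300 bp).
#' @param max_unit Largest repeat unit considered (default 30 bp).
#' @param min_span Minimum tandem span (in bp) required to call a repeat
#'   (default 24).
#' @return list: `unit` (canonical minimal rotation, lower case),
#'   `unit_as_found`, `n_ends`, `n_detected`, `units` (per-end table).
#' @export
telomere_consensus <- function(genome, window = 300L, max_unit = 30L,
                               min_span = 24L) {
  ends <- if (is.character(genome)) {
    genome
  } else {
    unlist(lapply(genome$seq, function(s) {
      n <- nchar(s)
      c(revcomp(substr(s, 1L, min(window, n))),
        substr(s, max(1L, n - window + 1L), n))
    }), use.names = FALSE)
  }
  if (length(ends) < 2L) stop("need at least 2 chromosome ends")
  detect_unit <- function(s) {
    n <- nchar(s)
    ch <- strsplit(s, "")[[1L]]
    for (L in seq_len(min(max_unit, n %/% 2L))) {
      # longest suffix with period L
      span <- L
      i <- n - L
      while (i >= 1L && ch[i] == ch[i + L]) {
        span <- span + 1L
        i <- i - 1L
      }
      if (span >= max(min_span, 2L * L)) {
        return(primitive_unit(substr(s, n - L + 1L, n)))
      }
    }
    NA_character_
  }
  found <- vapply(ends, detect_unit, character(1L), USE.NAMES = FALSE)
  det <- found[!is.na(found)]
  if (length(det) == 0L) {
    warning("no terminal tandem repeat detected")
    return(list(unit = "", unit_as_found = "", n_ends = length(ends),
                n_detected = 0L, units = data.frame()))
  }
  canon <- vapply(det, min_rotation, character(1L), USE.NAMES = FALSE)
  tab <- sort(table(canon), decreasing = TRUE)
  major <- names(tab)[1L]
  as_found <- det[canon == major][1L]
  list(
    unit = tolower(major),
    unit_as_found = tolower(as_found),
    n_ends = length(ends), n_detected = length(det),
    units = data.frame(unit = tolower(names(tab)),
                       n_ends = as.integer(tab),
                       stringsAsFactors = FALSE)
  )
}
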