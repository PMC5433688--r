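# Pre-hybridization chromosomal rearrangements: inversions and reciprocal
# translocations with breakpoints restricted to intergenic midpoints, so
# gene integrity and reading frames are never disturbed. Every accepted
# event is verified to create exactly two new synteny breakpoints against
# the starting gene order (no breakpoint reuse); proposals that would
# reuse or restore an adjacency are redrawn.

.invert_segment <- function(ch, g1, g2) {
  n <- nrow(ch$genes)
  stopifnot(g1 >= 1L, g2 > g1, g2 <= n - 1L)
  seg <- (g1 + 1L):g2
  segg <- ch$genes[rev(seg), , drop = FALSE]
  segg$strand <- ifelse(segg$strand == "+", "-", "+")
  new_genes <- rbind(ch$genes[seq_len(g1), , drop = FALSE],
                     segg,
                     ch$genes[setdiff(seq_len(n), c(seq_len(g1), seg)), ,
                              drop = FALSE])
  rownames(new_genes) <- NULL
  s1 <- .split_spacer(ch$spacers[g1 + 1L],
                      nchar(ch$spacers[g1 + 1L]) %/% 2L)
  s2 <- .split_spacer(ch$spacers[g2 + 1L],
                      nchar(ch$spacers[g2 + 1L]) %/% 2L)
  inner <- if (g2 >= g1 + 2L) revcomp(ch$spacers[g2:(g1 + 2L)]) else
    character(0L)
  new_spacers <- c(
    ch$spacers[seq_len(g1)],
    paste0(s1$left, revcomp(s2$left)),
    inner,
    paste0(revcomp(s1$right), s2$right),
    if (g2 + 2L <= n + 1L) ch$spacers[(g2 + 2L):(n + 1L)] else character(0L)
  )
  .sim_chromosome(ch$name, new_genes, new_spacers, ch$tel_l, ch$tel_r)
}

.translocate <- function(ch1, ch2, a, b) {
  n1 <- nrow(ch1$genes); n2 <- nrow(ch2$genes)
  stopifnot(a >= 1L, a <= n1 - 1L, b >= 1L, b <= n2 - 1L)
  s1 <- .split_spacer(ch1$spacers[a + 1L], nchar(ch1$spacers[a + 1L]) %/% 2L)
  s2 <- .split_spacer(ch2$spacers[b + 1L], nchar(ch2$spacers[b + 1L]) %/% 2L)
  g1 <- rbind(ch1$genes[seq_len(a), , drop = FALSE],
              ch2$genes[(b + 1L):n2, , drop = FALSE])
  g2 <- rbind(ch2$genes[seq_len(b), , drop = FALSE],
              ch1$genes[(a + 1L):n1, , drop = FALSE])
  rownames(g1) <- rownames(g2) <- NULL
  sp1 <- c(ch1$spacers[seq_len(a)], paste0(s1$left, s2$right),
           ch2$spacers[(b + 2L):(n2 + 1L)])
  sp2 <- c(ch2$spacers[seq_len(b)], paste0(s2$left, s1$right),
           ch1$spacers[(a + 2L):(n1 + 1L)])
  list(.sim_chromosome(ch1$name, g1, sp1, ch1$tel_l, ch2$tel_r),
       .sim_chromosome(ch2$name, g2, sp2, ch2$tel_l, ch1$tel_r))
}

#' Apply pre-hybridization rearrangements to a parent genome
#'
#' Each event is an inversion (one chromosome, internal segment reversed,
#' strands flipped) or a reciprocal translocation (two chromosomes
#' exchange terminal segments). Breakpoints fall at intergenic midpoints
#' and are strictly internal, the chromosome count is preserved, and no
#' breakpoint is reused: after k accepted events the genome shows exactly
#' 2k synteny breakpoints against the starting order.
#'
#' @param genome A `sim_genome`.
#' @param n_events Number of events.
#' @param mix Fraction of events that are inversions (remainder:
#'   reciprocal translocations).
#' @param seed Integer seed.
#' @param max_retries Proposals per event before giving up (breakpoint
#'   collision error).
#' @return list with `genome` (rearranged `sim_genome`) and `events`
#'   (the event log; replayable with [replay_rearrangements()]).
#' @export
apply_rearrangements <- function(genome, n_events, mix = 0.5, seed = 1L,
                                 max_retries = 200L) {
  set.seed(as.integer(seed))
  orig_order <- .sim_order(genome)
  chroms <- genome$chroms
  log <- vector("list", n_events)
  if (n_events == 0L) return(list(genome = genome, events = list()))

  n_per <- vapply(chroms, function(ch) nrow(ch$genes), integer(1L))
  if (sum(pmax(n_per - 1L, 0L)) < 2L * n_events) {
    stop("not enough distinct intergenic positions for ", 2L * n_events,
         " breakpoints")
  }

  for (ev in seq_len(n_events)) {
    done <- FALSE
    for (try in seq_len(max_retries)) {
      type <- if (stats::runif(1L) < mix) "inversion" else "translocation"
      cand <- chroms
      if (type == "inversion") {
        ok_chr <- which(vapply(cand, function(ch) nrow(ch$genes) >= 3L,
                               logical(1L)))
        if (length(ok_chr) == 0L) next
        ci <- if (length(ok_chr) == 1L) ok_chr else sample(ok_chr, 1L)
        n <- nrow(cand[[ci]]$genes)
        gaps <- sort(sample.int(n - 1L, 2L))
        rec <- list(type = "inversion", chrom = cand[[ci]]$name,
                    after_gene_1 = cand[[ci]]$genes$gene_id[gaps[1L]],
                    after_gene_2 = cand[[ci]]$genes$gene_id[gaps[2L]])
        cand[[ci]] <- .invert_segment(cand[[ci]], gaps[1L], gaps[2L])
      } else {
        ok_chr <- which(vapply(cand, function(ch) nrow(ch$genes) >= 2L,
                               logical(1L)))
        if (length(ok_chr) < 2L) next
        cij <- sample(ok_chr, 2L)
        n1 <- nrow(cand[[cij[1L]]]$genes)
        n2 <- nrow(cand[[cij[2L]]]$genes)
        a <- sample.int(n1 - 1L, 1L)
        b <- sample.int(n2 - 1L, 1L)
        rec <- list(type = "translocation",
                    chrom_1 = cand[[cij[1L]]]$name,
                    after_gene_1 = cand[[cij[1L]]]$genes$gene_id[a],
                    chrom_2 = cand[[cij[2L]]]$name,
                    after_gene_2 = cand[[cij[2L]]]$genes$gene_id[b])
        tr <- .translocate(cand[[cij[1L]]], cand[[cij[2L]]], a, b)
        cand[[cij[1L]]] <- tr[[1L]]
        cand[[cij[2L]]] <- tr[[2L]]
      }
      tmp <- .sim_genome(cand, parent = genome$parent)
      bc <- count_breakpoints(.sim_order(tmp), orig_order, max_gap = 0L)
      if (bc$count == 2L * ev) {
        chroms <- cand
        log[[ev]] <- rec
        done <- TRUE
        break
      }
    }
    if (!done) {
      stop("breakpoint collision: could not place event ", ev,
           " without breakpoint reuse after ", max_retries, " proposals")
    }
  }
  out <- .sim_genome(chroms, parent = genome$parent)
  list(genome = out, events = log)
}

#' Replay a rearrangement event log on gene orders
#'
#' Pure gene-order transformation used to verify that the simulator's
#' event log reproduces the emitted order exactly.
#'
#' @param orders Named list (per chromosome) of data.frames with columns
#'   `gene_id`, `strand`.
#' @param events Event log from [apply_rearrangements()].
#' @return The transformed named list of orders.
#' @export
replay_rearrangements <- function(orders, events) {
  flip <- function(df) {
    df <- df[rev(seq_len(nrow(df))), , drop = FALSE]
    df$strand <- ifelse(df$strand == "+", "-", "+")
    df
  }
  for (ev in events) {
    if (ev$type == "inversion") {
      df <- orders[[ev$chrom]]
      g1 <- match(ev$after_gene_1, df$gene_id)
      g2 <- match(ev$after_gene_2, df$gene_id)
      seg <- (g1 + 1L):g2
      df <- rbind(df[seq_len(g1), , drop = FALSE],
                  flip(df[seg, , drop = FALSE]),
                  df[setdiff(seq_len(nrow(df)), c(seq_len(g1), seg)), ,
                     drop = FALSE])
      rownames(df) <- NULL
      orders[[ev$chrom]] <- df
    } else {
      d1 <- orders[[ev$chrom_1]]
      d2 <- orders[[ev$chrom_2]]
      a <- match(ev$after_gene_1, d1$gene_id)
      b <- match(ev$after_gene_2, d2$gene_id)
      n1 <- nrow(d1); n2 <- nrow(d2)
      new1 <- rbind(d1[seq_len(a), , drop = FALSE],
                    d2[(b + 1L):n2, , drop = FALSE])
      new2 <- rbind(d2[seq_len(b), , drop = FALSE],
                    d1[(a + 1L):n1, , drop = FALSE])
      rownames(new1) <- rownames(new2) <- NULL
      orders[[ev$chrom_1]] <- new1
      orders[[ev$chrom_2]] <- new2
    }
  }
  orders
}
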