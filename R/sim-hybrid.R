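# Hybridization and post-hybridization genome evolution: LOH tracts,
# interhomeolog crossovers, break-induced replication of chromosome ends,
# and sporadic gene disablements. Event order is fixed (LOH ->
# recombination -> BIR -> disablement) for reproducibility.

.sim_gene_cds <- function(sim, ids) {
  out <- stats::setNames(character(length(ids)), ids)
  for (ch in sim$chroms) {
    hit <- ch$genes$gene_id %in% ids
    if (any(hit)) out[ch$genes$gene_id[hit]] <- ch$genes$cds[hit]
  }
  if (any(out == "")) stop("gene id not found: ",
                           paste(ids[out == ""], collapse = ","))
  out
}

.chrom_idx <- function(sim, name) {
  which(vapply(sim$chroms, `[[`, character(1L), "name") == name)
}

#' Fuse two parent genomes into a hybrid
#'
#' The hybrid contains the union of both parents' chromosomes; gene ids
#' receive a `_A` / `_B` suffix recording their true parent of origin, and
#' a ground-truth table is initialised: every gene starts out as a member
#' of a simple A:B homeolog pair with its same-base-id gene from the other
#' parent (when present).
#'
#' @param parent_a,parent_b `sim_genome` objects.
#' @return list with `genome` (the hybrid `sim_genome`) and `truth`
#'   (a `sim_truth`).
#' @export
hybridize <- function(parent_a, parent_b) {
  names_a <- vapply(parent_a$chroms, `[[`, character(1L), "name")
  names_b <- vapply(parent_b$chroms, `[[`, character(1L), "name")
  if (anyDuplicated(c(names_a, names_b))) {
    stop("duplicate chromosome names between parents")
  }
  suffix <- function(chroms, suf) {
    lapply(chroms, function(ch) {
      if (nrow(ch$genes)) {
        ch$genes$gene_id <- paste0(ch$genes$gene_id, suf)
      }
      ch
    })
  }
  ca <- suffix(parent_a$chroms, "_A")
  cb <- suffix(parent_b$chroms, "_B")
  hybrid <- .sim_genome(c(ca, cb), parent = "hybrid")

  base_a <- unlist(lapply(parent_a$chroms, function(ch) ch$genes$gene_id))
  base_b <- unlist(lapply(parent_b$chroms, function(ch) ch$genes$gene_id))
  if (is.null(base_a)) base_a <- character(0L)
  if (is.null(base_b)) base_b <- character(0L)
  genes <- data.frame(
    gene_id = c(paste0(base_a, "_A"), paste0(base_b, "_B")),
    base_id = c(base_a, base_b),
    true_subgenome = rep(c("A", "B"), c(length(base_a), length(base_b))),
    orig_subgenome = rep(c("A", "B"), c(length(base_a), length(base_b))),
    partner = c(ifelse(base_a %in% base_b, paste0(base_a, "_B"), NA),
                ifelse(base_b %in% base_a, paste0(base_b, "_A"), NA)),
    stringsAsFactors = FALSE
  )
  genes$true_category <- ifelse(
    is.na(genes$partner),
    paste0(genes$true_subgenome, "-unpaired"),
    paste0(genes$true_subgenome, "-in-A:B")
  )
  truth <- structure(list(
    genes = genes, rearrangements = list(),
    loh = list(), recombination = list(), bir = list(),
    disabled = list(), mat = NULL
  ), class = "sim_truth")
  list(genome = hybrid, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "Simulation ground truth: %d genes (%d LOH tracts, %d crossovers, %d BIR ends, %d disablements)\n",
    nrow(x$genes), length(x$loh), length(x$recombination), length(x$bir),
    length(x$disabled)))
  invisible(x)
}

# windows of >= L consecutive TRUE in a logical vector: start positions
.runs_of <- function(ok, L) {
  if (L <= 0L || length(ok) < L) return(integer(0L))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0L)
  for (i in which(r$values & r$lengths >= L)) {
    out <- c(out, starts[i]:(ends[i] - L + 1L))
  }
  out
}

#' Apply post-hybridization events to a hybrid genome
#'
#' In order: (1) LOH tracts -- a run of genes on one homeolog is
#' overwritten in place by the other homeolog's coding sequence, turning
#' A:B pairs into A:A or B:B pairs; (2) interhomeolog recombination --
#' reciprocal crossovers at homeologous intergenic sites, producing
#' part-A/part-B chromosomes; (3) BIR -- a terminal segment of one
#' chromosome is replaced by a copy of another chromosome's end, leaving
#' the two ends sequence-identical from the initiation point out to the
#' telomere (donor end unchanged); (4) disablements -- a 1-bp indel or
#' premature stop planted in one member of an A:B pair. The truth table is
#' updated after every event; proposals that would overlap a previous
#' event are redrawn.
#'
#' @param hybrid Hybrid `sim_genome` from [hybridize()].
#' @param truth Matching `sim_truth`.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return list with updated `genome` and `truth`.
#' @export
apply_posthyb_events <- function(hybrid, truth, config, seed = 1L) {
  set.seed(as.integer(seed))
  sim <- hybrid
  used <- character(0L)
  tg <- truth$genes
  rownames(tg) <- tg$gene_id

  draw_or_stop <- function(cands, what) {
    if (length(cands) == 0L) stop("event placement exhausted: ", what)
    if (length(cands) == 1L) cands else sample(cands, 1L)
  }

  ## --- (1) LOH tracts ------------------------------------------------
  # cassette chromosomes are excluded so that the MAT breakage
  # translocation (applied later, mid-chromosome) can never bisect a tract
  cassette_chroms <- sprintf("chr%s_%02d", c("A", "B"),
                             config$mat_spec$mat_chrom)
  for (L in config$loh_lengths) {
    donor <- if (stats::runif(1L) < config$p_loh_donor_a) "A" else "B"
    target <- setdiff(c("A", "B"), donor)
    windows <- list()
    for (ci in seq_along(sim$chroms)) {
      if (sim$chroms[[ci]]$name %in% cassette_chroms) next
      ids <- sim$chroms[[ci]]$genes$gene_id
      if (length(ids) < L) next
      ok <- tg[ids, "true_subgenome"] == target &
        !is.na(tg[ids, "partner"]) &
        !(ids %in% used) & !(tg[ids, "partner"] %in% used) &
        tg[ids, "true_category"] == paste0(target, "-in-A:B")
      ok[is.na(ok)] <- FALSE
      for (s in .runs_of(ok, L)) {
        windows[[length(windows) + 1L]] <- c(ci, s)
      }
    }
    wi <- draw_or_stop(seq_along(windows), "LOH tract")
    ci <- windows[[wi]][1L]; s <- windows[[wi]][2L]
    ids_w <- sim$chroms[[ci]]$genes$gene_id[s:(s + L - 1L)]
    partners <- tg[ids_w, "partner"]
    donor_cds <- .sim_gene_cds(sim, partners)
    rows <- match(ids_w, sim$chroms[[ci]]$genes$gene_id)
    sim$chroms[[ci]]$genes$cds[rows] <- unname(donor_cds)
    cat_new <- paste0(donor, "-in-", donor, ":", donor)
    tg[ids_w, "true_subgenome"] <- donor
    tg[c(ids_w, partners), "true_category"] <- cat_new
    # buffer the tract with one flanking gene per side so that two tracts
    # can never be placed immediately adjacent (they would merge)
    all_ids <- sim$chroms[[ci]]$genes$gene_id
    buffer <- all_ids[c(s - 1L, s + L)]
    buffer <- buffer[!is.na(buffer)]
    used <- c(used, ids_w, partners, buffer)
    truth$loh[[length(truth$loh) + 1L]] <- list(
      donor = donor, background = target, length = L,
      gene_ids = ids_w, partner_ids = partners
    )
  }

  ## --- (2) interhomeolog reciprocal crossovers -----------------------
  # crossover sites require 3 clean A:B genes on each flank of both cut
  # points (so every simulated junction is a detectable A|B boundary) and
  # avoid the cassette chromosomes, whose label integrity the MAT
  # breakage depends on
  flank_ok <- function(ordt, chrom, p, lo, hi, want_cat, ids_by_chrom) {
    idxs <- (p - lo):(p + hi)
    ids <- ids_by_chrom[[chrom]]
    if (any(idxs < 1L) || any(idxs > length(ids))) return(FALSE)
    w <- ids[idxs]
    all(tg[w, "true_category"] == want_cat) && !any(w %in% used)
  }
  for (ev in seq_len(config$n_recombinations)) {
    ordt <- .sim_order(sim)
    rownames(ordt) <- ordt$gene_id
    ids_by_chrom <- split(ordt$gene_id, ordt$chrom)
    ids_by_chrom <- lapply(ids_by_chrom, function(x)
      x[order(ordt[x, "index"])])
    cand <- tg$gene_id[tg$true_subgenome == "A" &
                         tg$true_category == "A-in-A:B" &
                         !(tg$gene_id %in% used) &
                         !is.na(tg$partner) & !(tg$partner %in% used)]
    cand <- cand[cand %in% ordt$gene_id & tg[cand, "partner"] %in% ordt$gene_id]
    cand <- cand[!(ordt[cand, "chrom"] %in% cassette_chroms) &
                   !(ordt[tg[cand, "partner"], "chrom"] %in% cassette_chroms)]
    ok <- vapply(cand, function(g) {
      p <- tg[g, "partner"]
      cg <- ordt[g, "chrom"]; cp <- ordt[p, "chrom"]
      if (cg == cp) return(FALSE)
      flank_ok(ordt, cg, ordt[g, "index"], 2L, 3L, "A-in-A:B",
               ids_by_chrom) &&
        flank_ok(ordt, cp, ordt[p, "index"], 2L, 3L, "B-in-A:B",
                 ids_by_chrom)
    }, logical(1L))
    cand <- cand[ok]
    g <- draw_or_stop(cand, "crossover site")
    p <- tg[g, "partner"]
    ci <- .chrom_idx(sim, ordt[g, "chrom"])
    cj <- .chrom_idx(sim, ordt[p, "chrom"])
    a <- ordt[g, "index"]; b <- ordt[p, "index"]
    right_a <- sim$chroms[[ci]]$genes$gene_id[a + 1L]
    right_b <- sim$chroms[[cj]]$genes$gene_id[b + 1L]
    tr <- .translocate(sim$chroms[[ci]], sim$chroms[[cj]], a, b)
    sim$chroms[[ci]] <- tr[[1L]]
    sim$chroms[[cj]] <- tr[[2L]]
    used <- c(used, g, p, right_a, right_b)
    truth$recombination[[length(truth$recombination) + 1L]] <- list(
      chrom_1 = tr[[1L]]$name, left_gene_1 = g, right_gene_1 = right_b,
      chrom_2 = tr[[2L]]$name, left_gene_2 = p, right_gene_2 = right_a
    )
  }

  ## --- (3) break-induced replication of chromosome ends --------------
  k <- config$bir_len_genes
  used_ends <- character(0L)
  mat_chroms <- sprintf("chr%s_%02d", c("A", "B"),
                        config$mat_spec$mat_chrom)
  end_label <- function(ci, side) {
    ids <- sim$chroms[[ci]]$genes$gene_id
    n <- length(ids)
    if (n < k + 2L) return(NULL)  # keep at least 2 genes
    term <- if (side == "R") ids[(n - k + 1L):n] else ids[1L:k]
    labs <- tg[term, "true_subgenome"]
    if (length(unique(labs)) != 1L) return(NULL)
    list(ids = term, label = labs[1L])
  }
  for (ev in seq_len(config$bir_ends)) {
    ends <- list()
    for (ci in seq_along(sim$chroms)) {
      nm <- sim$chroms[[ci]]$name
      if (nm %in% mat_chroms) next
      for (side in c("L", "R")) {
        key <- paste0(nm, ":", side)
        if (key %in% used_ends) next
        e <- end_label(ci, side)
        if (is.null(e)) next
        if (any(e$ids %in% used)) next
        ends[[length(ends) + 1L]] <- list(ci = ci, side = side,
                                          key = key, ids = e$ids,
                                          label = e$label)
      }
    }
    pairs <- list()
    for (i in seq_along(ends)) for (j in seq_along(ends)) {
      if (i == j) next
      d <- ends[[i]]; r <- ends[[j]]
      if (d$side != r$side) next      # same-side copy keeps orientation
      if (d$ci == r$ci) next
      if (d$label == r$label) next    # homogenisation across subgenomes
      # recipient partners must still be around (they become unpaired)
      rp <- tg[r$ids, "partner"]
      if (any(is.na(rp)) || any(rp %in% used)) next
      dp <- tg[d$ids, "partner"]
      if (any(dp %in% used, na.rm = TRUE)) next
      pairs[[length(pairs) + 1L]] <- list(d = d, r = r)
    }
    pr <- pairs[[draw_or_stop(seq_along(pairs), "BIR end pair")]]
    d <- pr$d; r <- pr$r
    dch <- sim$chroms[[d$ci]]; rch <- sim$chroms[[r$ci]]
    nd <- nrow(dch$genes); nr <- nrow(rch$genes)
    copy_genes <- if (d$side == "R") {
      dch$genes[(nd - k + 1L):nd, , drop = FALSE]
    } else dch$genes[1L:k, , drop = FALSE]
    new_ids <- paste0(copy_genes$gene_id, "bir")
    orig_ids <- copy_genes$gene_id
    copy_genes$gene_id <- new_ids
    if (d$side == "R") {
      dsp <- .split_spacer(dch$spacers[nd - k + 1L],
                           nchar(dch$spacers[nd - k + 1L]) %/% 2L)
      rsp <- .split_spacer(rch$spacers[nr - k + 1L],
                           nchar(rch$spacers[nr - k + 1L]) %/% 2L)
      new_genes <- rbind(rch$genes[seq_len(nr - k), , drop = FALSE],
                         copy_genes)
      new_spacers <- c(rch$spacers[seq_len(nr - k)],
                       paste0(rsp$left, dsp$right),
                       dch$spacers[(nd - k + 2L):(nd + 1L)])
      sim$chroms[[r$ci]] <- .sim_chromosome(rch$name, new_genes,
                                            new_spacers, rch$tel_l,
                                            dch$tel_r)
      deleted <- rch$genes$gene_id[(nr - k + 1L):nr]
    } else {
      dsp <- .split_spacer(dch$spacers[k + 1L],
                           nchar(dch$spacers[k + 1L]) %/% 2L)
      rsp <- .split_spacer(rch$spacers[k + 1L],
                           nchar(rch$spacers[k + 1L]) %/% 2L)
      new_genes <- rbind(copy_genes,
                         rch$genes[(k + 1L):nr, , drop = FALSE])
      new_spacers <- c(dch$spacers[seq_len(k)],
                       paste0(dsp$left, rsp$right),
                       rch$spacers[(k + 2L):(nr + 1L)])
      sim$chroms[[r$ci]] <- .sim_chromosome(rch$name, new_genes,
                                            new_spacers, dch$tel_l,
                                            rch$tel_r)
      deleted <- rch$genes$gene_id[1L:k]
    }
    rownames(sim$chroms[[r$ci]]$genes) <- NULL

    # truth updates: copies pair with their donors (identical sequences);
    # the recipient genes are gone and their homeologs become unpaired
    lab <- d$label
    add <- data.frame(
      gene_id = new_ids, base_id = tg[orig_ids, "base_id"],
      true_subgenome = lab, orig_subgenome = lab,
      partner = orig_ids,
      true_category = paste0(lab, "-in-", lab, ":", lab),
      stringsAsFactors = FALSE
    )
    rownames(add) <- add$gene_id
    dp_old <- tg[orig_ids, "partner"]
    tg[orig_ids, "partner"] <- new_ids
    tg[orig_ids, "true_category"] <- paste0(lab, "-in-", lab, ":", lab)
    # both the recipient genes' homeologs and the donors' former homeologs
    # lose their reciprocal best hit
    widowed <- unique(c(tg[deleted, "partner"], dp_old))
    widowed <- widowed[!is.na(widowed) & !(widowed %in% orig_ids) &
                         !(widowed %in% deleted)]
    tg[widowed, "partner"] <- NA
    tg[widowed, "true_category"] <-
      paste0(tg[widowed, "true_subgenome"], "-unpaired")
    tg <- tg[!(tg$gene_id %in% deleted), , drop = FALSE]
    tg <- rbind(tg, add)
    used <- c(used, orig_ids, new_ids, widowed)
    used_ends <- c(used_ends, d$key, r$key,
                   paste0(sim$chroms[[r$ci]]$name, ":", r$side))
    truth$bir[[length(truth$bir) + 1L]] <- list(
      donor_chrom = dch$name, donor_side = d$side,
      recipient_chrom = rch$name, recipient_side = r$side,
      donor_ids = orig_ids, copy_ids = new_ids, deleted_ids = deleted,
      widowed_ids = widowed
    )
  }

  ## --- (4) disablements ----------------------------------------------
  for (sub in c("A", "B")) {
    nd <- config$n_disablements_per_subgenome
    for (ev in seq_len(nd)) {
      mech <- if (ev %% 2L == 1L) "frameshift-indel" else "premature-stop"
      cand <- tg$gene_id[tg$true_subgenome == sub &
                           tg$true_category == paste0(sub, "-in-A:B") &
                           !(tg$gene_id %in% used) &
                           !is.na(tg$partner) & !(tg$partner %in% used)]
      g <- draw_or_stop(cand, "disablement target")
    loc <- .sim_locate(sim, g)
      ci <- .chrom_idx(sim, loc$chrom)
      row <- match(g, sim$chroms[[ci]]$genes$gene_id)
      cds <- sim$chroms[[ci]]$genes$cds[row]
      L_cod <- nchar(cds) %/% 3L
      placed <- FALSE
      for (try in seq_len(50L)) {
        cpos <- sample(seq.int(max(2L, round(0.1 * L_cod)),
                               max(3L, round(0.6 * L_cod))), 1L)
        if (mech == "premature-stop") {
          new_cds <- str_replace_at(cds, 3L * (cpos - 1L) + 1L, "TAA")
        } else if (stats::runif(1L) < 0.5) {
          at <- 3L * (cpos - 1L) + sample.int(3L, 1L)
          new_cds <- str_insert_at(cds, at, sample(.BASES, 1L))
        } else {
          at <- 3L * (cpos - 1L) + sample.int(3L, 1L)
          new_cds <- str_delete_at(cds, at, 1L)
        }
        ratio <- predicted_protein_length(new_cds) / (L_cod - 1L)
        if (ratio < 0.9 && ratio > 0.02) { placed <- TRUE; break }
      }
      if (!placed) stop("could not plant a disabling mutation")
      sim$chroms[[ci]]$genes$cds[row] <- new_cds
      used <- c(used, g, tg[g, "partner"])
      truth$disabled[[length(truth$disabled) + 1L]] <- list(
        gene_id = g, partner = tg[g, "partner"], mechanism = mech,
        codon = cpos
      )
    }
  }

  rownames(tg) <- NULL
  truth$genes <- tg
  list(genome = sim, truth = truth)
}
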