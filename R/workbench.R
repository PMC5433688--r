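# Orchestration: the full analysis pipeline (simulate -> homology/Ks ->
# classify -> genome architecture -> MAT forensics -> integrity), recovery
# evaluation against simulator ground truth, and a machine-readable
# summary.

#' Pipeline configuration
#'
#' Collects every analysis tunable in one place.
#'
#' @param ks_a,ks_b Subgenome classification thresholds (0.05 / 0.25).
#' @param length_ratio Integrity screen threshold (0.9).
#' @param min_run Minimum LOH tract / junction flank length in genes (3).
#' @param max_gap Synteny gap tolerance in unmapped genes (2).
#' @param min_bir_genes Minimum BIR terminal run (5).
#' @param bir_id_min BIR partner end identity (0.95).
#' @param seed Seed for the simulation stage.
#' @param sim A [sim_config()] for the simulation stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(ks_a = 0.05, ks_b = 0.25, length_ratio = 0.9,
                            min_run = 3L, max_gap = 2L,
                            min_bir_genes = 5L, bir_id_min = 0.95,
                            seed = 1L, sim = sim_config(seed = seed)) {
  stopifnot(ks_a > 0, ks_b < 1, ks_a < ks_b,
            length_ratio > 0, length_ratio < 1)
  structure(list(ks_a = ks_a, ks_b = ks_b, length_ratio = length_ratio,
                 min_run = as.integer(min_run),
                 max_gap = as.integer(max_gap),
                 min_bir_genes = as.integer(min_bir_genes),
                 bir_id_min = bir_id_min, seed = as.integer(seed),
                 sim = sim),
            class = "pipeline_config")
}

# Ks-ready CDS: damaged sequences trimmed to their translatable prefix
.effective_cds <- function(cds) {
  p <- translate_cds(cds, pseudogene_mode = TRUE)
  substr(cds, 1L, 3L * nchar(p))
}

#' Classify a hybrid genome against a reference parental genome
#'
#' Runs the homology/Ks stage (best hits of hybrid proteins against the
#' reference proteome, protein-guided codon alignment, NG86 + Jukes-Cantor
#' Ks), assigns subgenome labels by thresholding Ks, pairs homeologs
#' within the hybrid by reciprocal best hit, and assembles the 7-category
#' genome map.
#'
#' @param hybrid An [annotated_genome()] (the hybrid).
#' @param reference An [annotated_genome()] (the reference parental
#'   species).
#' @param ks_a,ks_b Classification thresholds.
#' @param min_codons Minimum aligned codons for a confident Ks.
#' @return list: `genes` (gene table with `ks`, `ref_hit`, `label`,
#'   `pair_id`, `pair_type`, `category`), `tracks`, `counts`, `pairs`,
#'   `hits`.
#' @export
classify_hybrid <- function(hybrid, reference, ks_a = 0.05, ks_b = 0.25,
                            min_codons = 30L) {
  hy_cds <- extract_cds(hybrid)
  ref_cds <- extract_cds(reference)
  hy_prot <- vapply(hy_cds, function(s)
    as.character(translate_cds(s, pseudogene_mode = TRUE)), character(1L))
  ref_prot <- vapply(ref_cds, function(s)
    as.character(translate_cds(s, pseudogene_mode = TRUE)), character(1L))

  hits <- find_best_hits(hy_prot, ref_prot)
  ks <- rep(NA_real_, nrow(hybrid$genes))
  names(ks) <- hybrid$genes$gene_id
  for (i in seq_len(nrow(hits))) {
    q <- hits$query_id[i]; s <- hits$subject_id[i]
    est <- tryCatch(
      estimate_ks(align_codons(.effective_cds(hy_cds[[q]]),
                               .effective_cds(ref_cds[[s]]),
                               id_a = q, id_b = s),
                  min_codons = min_codons),
      error = function(e) NULL
    )
    if (!is.null(est) && !est$low_confidence) ks[q] <- est$Ks
  }
  labels <- assign_subgenome(ks, ks_a = ks_a, ks_b = ks_b)
  names(labels) <- names(ks)

  pairs <- pair_within(hy_prot)
  cz <- categorize(hybrid$genes, labels, pairs)
  cz$genes$ks <- unname(ks[cz$genes$gene_id])
  cz$genes$ref_hit <- hits$subject_id[match(cz$genes$gene_id,
                                            hits$query_id)]
  c(cz, list(pairs = pairs, hits = hits))
}

#' Run the full archaeology pipeline on a simulated hybrid
#'
#' Simulates a hybrid genome under `config$sim`, classifies it against
#' the simulated parent-A genome (standing in for the reference parental
#' species), maps the genome architecture (breakpoints between the
#' pre-hybridization parents, LOH tracts, recombination junctions, BIR
#' ends, telomere consensus), catalogues the MAT loci and HO sites,
#' screens gene integrity, and evaluates recovery against the simulator's
#' ground truth.
#'
#' @param config A [pipeline_config()].
#' @return list of class `pipeline_result` with stage outputs, a
#'   `summary` list (JSON-ready) and `recovery` statistics.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  sim <- simulate_hybrid_genome(config$sim)
  cls <- classify_hybrid(sim$genome, sim$parent_a,
                         ks_a = config$ks_a, ks_b = config$ks_b)

  # pre-hybridization rearrangements: parent B order vs parent A order
  bp <- count_breakpoints(sim$parent_b$genes,
                          sim$parent_a$genes,
                          max_gap = 0L)
  blocks <- build_synteny_blocks(sim$parent_b$genes, sim$parent_a$genes,
                                 max_gap = 0L)

  bir <- flag_bir_ends(cls$genes, sim$genome,
                       min_bir_genes = config$min_bir_genes,
                       id_min = config$bir_id_min)
  loh <- segment_loh_tracts(cls$genes, min_run = config$min_run,
                            exclude = bir$masked_genes)
  junctions <- detect_recombination_junctions(cls$genes,
                                              min_run = config$min_run)
  tel <- telomere_consensus(sim$genome)

  cat <- catalog_mat_loci(sim$genome,
                          gene_labels = stats::setNames(cls$genes$label,
                                                        cls$genes$gene_id))
  ho <- locate_ho_sites(sim$genome, catalog = cat)

  hy_cds <- extract_cds(sim$genome)
  hy_prot <- vapply(hy_cds, function(s)
    as.character(translate_cds(s, pseudogene_mode = TRUE)), character(1L))
  ab_pairs <- cls$pairs
  screen <- screen_pairs(ab_pairs, hy_prot,
                         ratio_threshold = config$length_ratio,
                         cds = hy_cds)
  plus1 <- find_plus1_sites(hy_cds)

  recovery <- evaluate_recovery(
    list(genes = cls$genes, loh = loh, junctions = junctions, bir = bir,
         screen = screen),
    sim$truth, min_run = config$min_run
  )

  summary <- list(
    package_version = as.character(utils::packageVersion("hybridarch")),
    seed = config$seed,
    config_hash = .config_hash(config),
    genome = list(
      n_chromosomes = length(sim$genome$seq),
      n_genes = nrow(sim$genome$genes),
      total_bp = sum(nchar(sim$genome$seq))
    ),
    categories = as.list(cls$counts),
    pair_types = as.list(table(cls$genes$pair_type[
      !duplicated(cls$genes$pair_id) & !is.na(cls$genes$pair_id)])),
    breakpoints = list(count = bp$count, events = bp$events,
                       odd = bp$odd),
    loh = list(n_tracts = nrow(loh)),
    junctions = list(n = nrow(junctions)),
    bir = list(n_flags = nrow(bir$flags),
               n_candidates = nrow(bir$candidates)),
    telomere = list(unit = tel$unit, n_detected = tel$n_detected),
    mat = list(n_regions = nrow(cat$loci),
               n_intact = sum(cat$loci$intact %in% TRUE),
               n_fragments = nrow(cat$fragments),
               x_identity = cat$x_identity,
               z_identity = cat$z_identity,
               n_ho_sites = nrow(ho)),
    integrity = list(n_flagged = nrow(screen),
                     n_plus1_sites = nrow(plus1)),
    recovery = recovery
  )

  structure(list(
    sim = sim, classification = cls, breakpoints = bp, blocks = blocks,
    loh = loh, junctions = junctions, bir = bir, telomere = tel,
    mat_catalog = cat, ho_sites = ho, screen = screen, plus1 = plus1,
    recovery = recovery, summary = summary, config = config
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("Hybrid genome archaeology pipeline\n")
  cat(sprintf("  genome: %d chromosomes, %d genes\n",
              s$genome$n_chromosomes, s$genome$n_genes))
  cat(sprintf("  breakpoints: %d (~%d events)\n",
              s$breakpoints$count, s$breakpoints$events))
  cat(sprintf("  LOH tracts: %d; junctions: %d; BIR flags: %d\n",
              s$loh$n_tracts, s$junctions$n, s$bir$n_flags))
  cat(sprintf("  MAT regions: %d (%d intact); HO sites: %d\n",
              s$mat$n_regions, s$mat$n_intact, s$mat$n_ho_sites))
  cat(sprintf("  integrity: %d flagged pairs\n", s$integrity$n_flagged))
  invisible(x)
}

.config_hash <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

#' Evaluate pipeline recovery against simulator ground truth
#'
#' Computes per-stage accuracy and precision/recall: subgenome label and
#' category accuracy per gene; LOH tract precision/recall (a called tract
#' matches a true tract when chromosome and gene-index ranges coincide;
#' only events of at least `min_run` genes are scored) plus an
#' exact-boundary indicator for the longest planted tract; junction
#' precision/recall (matched by flanking genes, the MAT translocation
#' junctions included); BIR event precision/recall (matched by the
#' unordered pair of chromosome ends).
#'
#' @param result list with `genes` (categorized gene table), `loh`,
#'   `junctions`, `bir`, `screen`.
#' @param truth A resolved `sim_truth`.
#' @param min_run Minimum event size scored (default 3).
#' @return list of recovery statistics.
#' @export
evaluate_recovery <- function(result, truth, min_run = 3L) {
  g <- result$genes
  tg <- truth$genes
  m <- match(g$gene_id, tg$gene_id)
  label_acc <- mean(g$label == tg$true_subgenome[m])
  cat_acc <- mean(g$category == tg$true_category[m])

  # LOH tracts. Both members of an overwritten pair are in same-label
  # pair categories, so each event shows up as a run at the overwritten
  # site and (possibly fragmented by pre-hybridization rearrangements) at
  # the donor site: a called tract is correct if all of its genes belong
  # to one event; an event is recovered when its overwritten-side window
  # is called at exact boundaries.
  tt <- truth$loh_table
  tt_big <- if (nrow(tt)) tt[tt$length >= min_run & tt$contiguous, ,
                             drop = FALSE] else tt
  called <- result$loh
  event_sets <- lapply(truth$loh, function(x)
    c(x$gene_ids, x$partner_ids))
  called_genes <- function(i) {
    g$gene_id[g$chrom == called$chrom[i] &
                g$index >= called$start_index[i] &
                g$index <= called$end_index[i]]
  }
  loh_tp <- 0L
  if (nrow(called)) {
    for (i in seq_len(nrow(called))) {
      cg <- called_genes(i)
      if (any(vapply(event_sets, function(s) all(cg %in% s),
                     logical(1L)))) {
        loh_tp <- loh_tp + 1L
      }
    }
  }
  loh_recall <- if (nrow(tt_big)) {
    found <- vapply(seq_len(nrow(tt_big)), function(i) {
      nrow(called) > 0L && any(called$chrom == tt_big$chrom[i] &
                                 called$start_index == tt_big$start_index[i] &
                                 called$end_index == tt_big$end_index[i])
    }, logical(1L))
    mean(found)
  } else NA_real_
  loh_precision <- if (nrow(called)) loh_tp / nrow(called) else NA_real_
  longest_exact <- if (nrow(tt_big)) {
    i <- which.max(tt_big$length)
    nrow(called) > 0L && any(called$chrom == tt_big$chrom[i] &
                               called$start_index == tt_big$start_index[i] &
                               called$end_index == tt_big$end_index[i])
  } else NA

  # junctions (crossovers + the MAT translocation junctions); a called
  # junction spans (left_index, right_index) across any transparent
  # genes: it matches a true boundary lying inside that span
  jt <- truth$junction_table
  called_j <- result$junctions
  j_match <- function(ci) {
    nrow(jt) > 0L && any(
      jt$chrom == called_j$chrom[ci] &
        jt$left_index >= called_j$left_index[ci] &
        jt$left_index < called_j$right_index[ci]
    )
  }
  t_match <- function(ti) {
    nrow(called_j) > 0L && any(
      called_j$chrom == jt$chrom[ti] &
        called_j$left_index <= jt$left_index[ti] &
        called_j$right_index > jt$left_index[ti]
    )
  }
  j_precision <- if (nrow(called_j))
    mean(vapply(seq_len(nrow(called_j)), j_match, logical(1L))) else
      NA_real_
  j_recall <- if (nrow(jt))
    mean(vapply(seq_len(nrow(jt)), t_match, logical(1L))) else NA_real_

  # BIR events: unordered end pairs
  bt <- truth$bir_table
  end_pair <- function(c1, s1, c2, s2) {
    apply(cbind(paste0(c1, s1), paste0(c2, s2)), 1L,
          function(x) paste(sort(x), collapse = "|"))
  }
  truth_bir <- if (nrow(bt)) end_pair(bt$donor_chrom, bt$donor_side,
                                      bt$recipient_chrom,
                                      bt$recipient_side) else character(0L)
  fl <- result$bir$flags
  called_bir <- if (nrow(fl)) end_pair(fl$chrom, fl$side,
                                       fl$partner_chrom, fl$partner_side)
  else character(0L)
  bir_precision <- if (length(called_bir))
    mean(called_bir %in% truth_bir) else NA_real_
  bir_recall <- if (length(truth_bir))
    mean(truth_bir %in% called_bir) else NA_real_

  # disablement screen
  dt <- truth$disabled_table
  sc <- result$screen
  screen_recall <- if (nrow(dt)) {
    mean(dt$gene_id %in% sc$gene_id)
  } else NA_real_
  mech_acc <- if (nrow(dt)) {
    m2 <- match(dt$gene_id, sc$gene_id)
    mean(!is.na(m2) & sc$mechanism[m2] == dt$mechanism)
  } else NA_real_

  list(
    label_accuracy = label_acc,
    category_accuracy = cat_acc,
    loh = list(precision = loh_precision, recall = loh_recall,
               longest_tract_exact = longest_exact,
               n_called = nrow(called), n_true = nrow(tt_big)),
    junctions = list(precision = j_precision, recall = j_recall,
                     n_called = nrow(called_j), n_true = nrow(jt)),
    bir = list(precision = bir_precision, recall = bir_recall,
               n_called = length(called_bir), n_true = length(truth_bir)),
    screen = list(recall = screen_recall, mechanism_accuracy = mech_acc,
                  n_called = nrow(sc), n_true = nrow(dt))
  )
}

#' Write the pipeline summary as JSON
#'
#' @param result A `pipeline_result`.
#' @param path Output path.
#' @export
write_summary <- function(result, path) {
  jsonlite::write_json(result$summary, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
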