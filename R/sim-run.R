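# End-to-end hybrid genome simulation: parent A -> sequence divergence ->
# pre-hybridization rearrangements -> hybridization -> LOH/recombination/
# BIR/disablements -> MAT architecture and HO breakage -> emission with a
# fully resolved ground-truth table.

#' Simulate a hybrid genome with complete ground truth
#'
#' Runs the whole evolutionary scenario encoded in a [sim_config()]:
#' a parent-A genome is generated, parent B is derived from it by
#' codon-wise divergence to the target synonymous divergence and by
#' chromosomal rearrangements, the two are fused into a hybrid, and the
#' post-hybridization events (LOH, interhomeolog crossovers, BIR,
#' disablements, MAT cassette installation and HO-catalysed breakage) are
#' applied. All randomness derives from `config$seed`: the same
#' configuration always yields byte-identical output.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genome` (the hybrid
#'   [annotated_genome()]), `truth` (resolved `sim_truth`), `parent_a`,
#'   `parent_b` (annotated parent genomes; `parent_b` is
#'   post-rearrangement), `parent_b_unrearranged`, `events` (the
#'   rearrangement log) and `config`.
#' @export
simulate_hybrid_genome <- function(config = sim_config()) {
  validate_sim_config(config)
  pa <- simulate_parent(config)
  pb0 <- evolve_divergence(pa, config$target_ks, config$omega,
                           seed = config$seed + 1L)
  re <- apply_rearrangements(pb0, config$n_rearrangements,
                             config$rearrangement_mix,
                             seed = config$seed + 2L)
  hy <- hybridize(pa, re$genome)
  hy$truth$rearrangements <- re$events
  ph <- apply_posthyb_events(hy$genome, hy$truth, config,
                             seed = config$seed + 3L)
  mb <- build_mat_architecture_and_breakage(ph$genome, ph$truth,
                                            config$mat_spec,
                                            seed = config$seed + 4L)
  genome <- as_annotated_genome(mb$genome)
  truth <- finalize_truth(mb$truth, genome)
  list(genome = genome, truth = truth,
       parent_a = as_annotated_genome(pa),
       parent_b = as_annotated_genome(re$genome),
       parent_b_unrearranged = as_annotated_genome(pb0),
       events = re$events, config = config)
}

#' Resolve a simulation truth table against the emitted genome
#'
#' Attaches final chromosome/index coordinates to the per-gene table and
#' converts the event records (LOH tracts, crossover junctions, BIR ends,
#' disablements, MAT loci) into coordinate-resolved data.frames.
#'
#' @param truth A `sim_truth` as built during simulation.
#' @param genome The emitted [annotated_genome()].
#' @return The resolved `sim_truth`.
#' @export
finalize_truth <- function(truth, genome) {
  g <- genome$genes
  m <- match(truth$genes$gene_id, g$gene_id)
  if (anyNA(m)) stop("truth table and emitted genome disagree")
  if (nrow(g) != nrow(truth$genes)) stop("emitted gene not in truth table")
  truth$genes$chrom <- g$chrom[m]
  truth$genes$index <- g$index[m]
  truth$genes$start <- g$start[m]
  truth$genes$end <- g$end[m]
  truth$genes$strand <- g$strand[m]

  idx_of <- stats::setNames(g$index, g$gene_id)
  chr_of <- stats::setNames(g$chrom, g$gene_id)

  if (length(truth$loh)) {
    truth$loh_table <- do.call(rbind, lapply(seq_along(truth$loh),
                                             function(i) {
      x <- truth$loh[[i]]
      chs <- unique(chr_of[x$gene_ids])
      data.frame(
        tract_id = i, donor = x$donor, background = x$background,
        chrom = chs[1L], start_index = min(idx_of[x$gene_ids]),
        end_index = max(idx_of[x$gene_ids]), length = x$length,
        contiguous = length(chs) == 1L &&
          diff(range(idx_of[x$gene_ids])) == x$length - 1L,
        stringsAsFactors = FALSE
      )
    }))
  } else {
    truth$loh_table <- data.frame()
  }

  jrec <- truth$recombination
  if (!is.null(truth$mat$breakage)) {
    jg <- truth$mat$breakage$junction_genes
    jrec[[length(jrec) + 1L]] <- list(
      chrom_1 = truth$mat$breakage$a_chrom,
      left_gene_1 = jg$j1[["left"]], right_gene_1 = jg$j1[["right"]],
      chrom_2 = truth$mat$breakage$b_chrom,
      left_gene_2 = jg$j2[["left"]], right_gene_2 = jg$j2[["right"]]
    )
  }
  if (length(jrec)) {
    # chromosomes are re-resolved from the final gene positions (a later
    # crossover can move an earlier junction onto another chromosome)
    rows <- lapply(jrec, function(x) {
      data.frame(
        chrom = unname(chr_of[c(x$left_gene_1, x$left_gene_2)]),
        left_gene = c(x$left_gene_1, x$left_gene_2),
        right_gene = c(x$right_gene_1, x$right_gene_2),
        left_index = unname(idx_of[c(x$left_gene_1, x$left_gene_2)]),
        right_index = unname(idx_of[c(x$right_gene_1, x$right_gene_2)]),
        stringsAsFactors = FALSE
      )
    })
    truth$junction_table <- do.call(rbind, rows)
    rownames(truth$junction_table) <- NULL
  } else {
    truth$junction_table <- data.frame()
  }

  if (length(truth$bir)) {
    # end coordinates re-resolved from final gene positions: a later
    # translocation can carry a homogenised end onto another chromosome
    nper <- table(g$chrom)
    end_of <- function(ids) {
      ch <- unname(chr_of[ids[1L]])
      idx <- idx_of[ids]
      side <- if (min(idx) == 1L) "L"
      else if (max(idx) == as.integer(nper[[ch]])) "R" else "?"
      list(chrom = ch, side = side)
    }
    truth$bir_table <- do.call(rbind, lapply(seq_along(truth$bir),
                                             function(i) {
      x <- truth$bir[[i]]
      d <- end_of(x$donor_ids)
      r <- end_of(x$copy_ids)
      data.frame(event_id = i, donor_chrom = d$chrom,
                 donor_side = d$side,
                 recipient_chrom = r$chrom,
                 recipient_side = r$side,
                 n_genes = length(x$donor_ids), stringsAsFactors = FALSE)
    }))
  } else {
    truth$bir_table <- data.frame()
  }

  if (length(truth$disabled)) {
    truth$disabled_table <- do.call(rbind, lapply(truth$disabled,
                                                  function(x) {
      data.frame(gene_id = x$gene_id, partner = x$partner,
                 mechanism = x$mechanism, codon = x$codon,
                 stringsAsFactors = FALSE)
    }))
  } else {
    truth$disabled_table <- data.frame()
  }

  if (!is.null(truth$mat) && !is.null(genome$features)) {
    fl <- genome$features
    truth$mat$loci_table <- do.call(rbind, lapply(truth$mat$loci,
                                                  function(l) {
      row <- fl[fl$name == l$name, , drop = FALSE]
      broken <- nrow(row) == 0L
      if (broken) {
        row <- fl[fl$name == paste0(l$name, ":fragment_XY"), , drop = FALSE]
      }
      data.frame(name = l$name, kind = l$kind, idiomorph = l$idiomorph,
                 subgenome = l$subgenome, chrom = row$chrom,
                 start = row$start, end = row$end, intact = l$intact,
                 stringsAsFactors = FALSE)
    }))
  }
  truth
}

#' Write simulator output to disk
#'
#' Emits FASTA chromosomes, a GFF3 gene annotation, a tab-separated
#' ground-truth gene table and a JSON event log.
#'
#' @param sim_result Result of [simulate_hybrid_genome()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim_result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "hybrid.fa"),
    gff = file.path(dir, "hybrid.gff3"),
    truth = file.path(dir, "truth_genes.tsv"),
    events = file.path(dir, "events.json")
  )
  write_genome(sim_result$genome, paths[["fasta"]], paths[["gff"]])
  tg <- sim_result$truth$genes
  utils::write.table(
    tg[, c("gene_id", "chrom", "index", "true_subgenome", "true_category")],
    paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE
  )
  ev <- list(
    rearrangements = sim_result$truth$rearrangements,
    loh = sim_result$truth$loh,
    recombination = sim_result$truth$recombination,
    bir = sim_result$truth$bir,
    disabled = sim_result$truth$disabled
  )
  jsonlite::write_json(ev, paths[["events"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
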