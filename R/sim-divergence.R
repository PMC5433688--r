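# Sequence divergence between the two parents, simulated codon-wise.
#
# Model: each internal codon receives a Poisson(3 * target_ks) number of
# proposed single-nucleotide changes, drawn uniformly over the nine
# single-base neighbours. Synonymous proposals are accepted with
# probability 1, nonsynonymous with probability omega, proposals creating
# a stop codon are rejected. A uniform proposal is synonymous with
# probability s_c/3 (s_c = the codon's synonymous site count), so the
# expected number of accepted synonymous events per synonymous site is
# exactly target_ks for every codon -- the quantity the NG86 + Jukes-Cantor
# estimator downstream is designed to recover. Multiple hits arise
# naturally and are what the correction absorbs. Start and stop codons are
# never touched; intergenic spacers accumulate substitutions at the same
# per-site event rate; telomere arrays are left untouched.

#' Evolve a diverged second parent from parent A
#'
#' @param parent A `sim_genome` (typically parent A).
#' @param target_ks Expected synonymous substitutions per synonymous site;
#'   must lie in `[0, 0.75)` (Jukes-Cantor saturation bound). 0 returns an
#'   identical genome.
#' @param omega Acceptance probability of nonsynonymous changes.
#' @param seed Integer seed.
#' @param rename_to Chromosome name prefix of the new parent
#'   (default "chrB"); gene ids are unchanged, so a gene and its future
#'   homeolog share a base id until hybridization suffixes them.
#' @return A `sim_genome` (parent B, pre-rearrangement; gene order equals
#'   parent A's).
#' @export
evolve_divergence <- function(parent, target_ks, omega = 0.05, seed = 1L,
                              rename_to = "chrB") {
  if (target_ks < 0 || target_ks >= 0.75) {
    stop("target_ks must lie in [0, 0.75): synonymous divergence beyond ",
         "0.75 is saturated under Jukes-Cantor")
  }
  set.seed(as.integer(seed))
  ct <- codon_tables()
  chroms <- parent$chroms

  # flatten all internal codons genome-wide for one vectorised pass
  gene_chr <- integer(0L); gene_row <- integer(0L)
  codon_list <- list()
  meta <- list()
  k <- 0L
  for (ci in seq_along(chroms)) {
    g <- chroms[[ci]]$genes
    for (ri in seq_len(nrow(g))) {
      k <- k + 1L
      cods <- split_codons(g$cds[ri])
      codon_list[[k]] <- cods[-c(1L, length(cods))]
      meta[[k]] <- c(ci, ri)
    }
  }
  lens <- lengths(codon_list)
  flat <- unlist(codon_list, use.names = FALSE)

  if (length(flat) > 0L && target_ks > 0) {
    nprop <- stats::rpois(length(flat), 3 * target_ks)
    maxr <- if (length(nprop)) max(nprop) else 0L
    for (r in seq_len(maxr)) {
      idx <- which(nprop >= r)
      if (length(idx) == 0L) break
      cur <- ct$idx[flat[idx]]
      pick <- sample.int(9L, length(idx), replace = TRUE)
      sel <- cbind(cur, pick)
      neigh <- ct$neighbour[sel]
      syn <- ct$neighbour_syn[sel]
      stp <- ct$neighbour_stop[sel]
      accept <- !stp & (syn | stats::runif(length(idx)) < omega)
      flat[idx[accept]] <- neigh[accept]
    }
  }

  # write mutated codons back into gene bodies
  if (k > 0L) {
    off <- cumsum(c(0L, lens[-k]))
    for (i in seq_len(k)) {
      ci <- meta[[i]][1L]; ri <- meta[[i]][2L]
      cods <- split_codons(chroms[[ci]]$genes$cds[ri])
      if (lens[i] > 0L) {
        cods[-c(1L, length(cods))] <- flat[off[i] + seq_len(lens[i])]
      }
      chroms[[ci]]$genes$cds[ri] <- paste(cods, collapse = "")
    }
  }

  # intergenic spacers: uniform substitutions at the same event rate
  if (target_ks > 0) {
    for (ci in seq_along(chroms)) {
      sp <- chroms[[ci]]$spacers
      for (si in seq_along(sp)) {
        len <- nchar(sp[si])
        if (len == 0L) next
        m <- stats::rpois(1L, len * target_ks)
        if (m == 0L) next
        chars <- strsplit(sp[si], "", fixed = TRUE)[[1L]]
        pos <- sample.int(len, m, replace = TRUE)
        for (p in pos) {
          chars[p] <- sample(setdiff(.BASES, chars[p]), 1L)
        }
        chroms[[ci]]$spacers[si] <- paste(chars, collapse = "")
      }
    }
  }

  for (ci in seq_along(chroms)) {
    chroms[[ci]]$name <- sub("^chr[A-Za-z]+", rename_to, chroms[[ci]]$name)
  }
  .sim_genome(chroms, parent = "B")
}
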