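# Codon-level lookup tables shared by the divergence simulator and the
# Nei-Gojobori (NG86) estimator. Built once per session and cached.
#
# Conventions (stated once, used everywhere):
#  * Standard genetic code.
#  * Synonymous site count of a codon: for each of the 3 positions, the
#    fraction of the 3 possible single-nucleotide changes that are
#    synonymous; changes creating a stop codon count as nonsynonymous.
#  * Differences between two codons are resolved by averaging the
#    synonymous/nonsynonymous step counts over all minimal mutational
#    pathways; pathways passing through a stop codon are excluded unless
#    every pathway is blocked, in which case all pathways are used.

.ha_cache <- new.env(parent = emptyenv())

.genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

.all_codons <- function() {
  g <- expand.grid(b3 = .BASES, b2 = .BASES, b1 = .BASES,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

#' @keywords internal
codon_tables <- function() {
  if (!is.null(.ha_cache$codon_tables)) return(.ha_cache$codon_tables)
  code <- .genetic_code()
  codons <- .all_codons()
  aa <- unname(code[codons])
  is_stop <- aa == "*"
  names(aa) <- codons

  # neighbour table: 9 single-nucleotide variants per codon
  nb_codon <- matrix("", nrow = 64L, ncol = 9L, dimnames = list(codons, NULL))
  nb_syn <- matrix(FALSE, nrow = 64L, ncol = 9L, dimnames = list(codons, NULL))
  nb_stop <- matrix(FALSE, nrow = 64L, ncol = 9L, dimnames = list(codons, NULL))
  syn_sites <- stats::setNames(numeric(64L), codons)

  for (cd in codons) {
    chars <- strsplit(cd, "", fixed = TRUE)[[1L]]
    k <- 0L
    s <- 0
    for (pos in 1:3) {
      nsyn_pos <- 0L
      for (alt in setdiff(.BASES, chars[pos])) {
        k <- k + 1L
        mut <- chars
        mut[pos] <- alt
        mcd <- paste(mut, collapse = "")
        nb_codon[cd, k] <- mcd
        nb_stop[cd, k] <- code[mcd] == "*"
        syn <- (code[mcd] == code[cd]) && code[mcd] != "*"
        nb_syn[cd, k] <- syn
        if (syn) nsyn_pos <- nsyn_pos + 1L
      }
      s <- s + nsyn_pos / 3
    }
    syn_sites[cd] <- s
  }

  # pathway-averaged difference counts for all codon pairs
  sd_mat <- matrix(0, 64L, 64L, dimnames = list(codons, codons))
  nd_mat <- matrix(0, 64L, 64L, dimnames = list(codons, codons))
  perms <- list(
    `1` = list(1L),
    `2` = list(c(1L, 2L), c(2L, 1L)),
    `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
               c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )
  for (a in codons) {
    ca <- strsplit(a, "", fixed = TRUE)[[1L]]
    for (b in codons) {
      if (a == b) next
      cb <- strsplit(b, "", fixed = TRUE)[[1L]]
      diffpos <- which(ca != cb)
      nd <- length(diffpos)
      paths <- perms[[nd]]
      res <- matrix(NA_real_, nrow = length(paths), ncol = 3L) # syn, nonsyn, blocked
      for (pi in seq_along(paths)) {
        ord <- diffpos[paths[[pi]]]
        cur <- ca
        syn <- 0
        non <- 0
        blocked <- FALSE
        for (pos in ord) {
          nxt <- cur
          nxt[pos] <- cb[pos]
          cur_cd <- paste(cur, collapse = "")
          nxt_cd <- paste(nxt, collapse = "")
          if (code[nxt_cd] == "*" && nxt_cd != b) blocked <- TRUE
          if (code[nxt_cd] != "*" && code[nxt_cd] == code[cur_cd]) {
            syn <- syn + 1
          } else {
            non <- non + 1
          }
          cur <- nxt
        }
        res[pi, ] <- c(syn, non, as.numeric(blocked))
      }
      ok <- res[, 3L] == 0
      if (!any(ok)) ok <- rep(TRUE, nrow(res))
      sd_mat[a, b] <- mean(res[ok, 1L])
      nd_mat[a, b] <- mean(res[ok, 2L])
    }
  }

  idx <- stats::setNames(seq_len(64L), codons)
  .ha_cache$codon_tables <- list(
    codons = codons, aa = aa, is_stop = is_stop, idx = idx,
    neighbour = nb_codon, neighbour_syn = nb_syn, neighbour_stop = nb_stop,
    syn_sites = syn_sites, sd = sd_mat, nd = nd_mat
  )
  .ha_cache$codon_tables
}

# sense codons only (no stops)
sense_codons <- function() {
  ct <- codon_tables()
  ct$codons[!ct$is_stop]
}
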