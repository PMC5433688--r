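# Independent oracles, implemented from first principles and kept free of
# the package's internal lookup tables.

# genetic code for the oracle, written out independently
.oracle_code <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- as.vector(outer(bases, outer(bases, bases, paste0),
                            function(a, b) paste0(a, b)))
  # order: first base slowest
  codons <- character(64)
  k <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1
    codons[k] <- paste0(b1, b2, b3)
  }
  stats::setNames(aas, codons)
})

oracle_translate <- function(codon) unname(.oracle_code[codon])

# NG86 synonymous site count of one codon: per position, the fraction of
# the three single-nucleotide changes that preserve the amino acid
# (changes to stop codons count as nonsynonymous)
oracle_syn_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  aa <- oracle_translate(codon)
  s <- 0
  for (pos in 1:3) {
    for (alt in setdiff(c("A", "C", "G", "T"), ch[pos])) {
      mut <- ch
      mut[pos] <- alt
      maa <- oracle_translate(paste(mut, collapse = ""))
      if (maa != "*" && maa == aa) s <- s + 1 / 3
    }
  }
  s
}

# pathway-enumeration oracle for the (Sd, Nd) contribution of one codon
# pair: average over all orderings of the differing positions, excluding
# orderings that pass through a stop codon unless all do
oracle_pair_diffs <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  dpos <- which(ca != cb)
  if (length(dpos) == 0) return(c(sd = 0, nd = 0))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  res <- list()
  for (ord in perms(dpos)) {
    cur <- ca
    sd <- 0; nd <- 0; blocked <- FALSE
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- cb[pos]
      aa1 <- oracle_translate(paste(cur, collapse = ""))
      aa2 <- oracle_translate(paste(nxt, collapse = ""))
      if (aa2 == "*" && paste(nxt, collapse = "") != b) blocked <- TRUE
      if (aa2 != "*" && aa2 == aa1) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    res[[length(res) + 1]] <- c(sd, nd, blocked)
  }
  m <- do.call(rbind, res)
  ok <- m[, 3] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(m))
  c(sd = mean(m[ok, 1]), nd = mean(m[ok, 2]))
}

# brute-force adjacency comparison: breakpoints between two gene orders
# given as named lists of data.frames(gene_id, strand)
oracle_breakpoints <- function(orders_x, orders_y) {
  pos_y <- list(); chr_y <- list(); str_y <- list()
  for (nm in names(orders_y)) {
    df <- orders_y[[nm]]
    for (i in seq_len(nrow(df))) {
      g <- df$gene_id[i]
      pos_y[[g]] <- i; chr_y[[g]] <- nm; str_y[[g]] <- df$strand[i]
    }
  }
  b <- 0
  for (nm in names(orders_x)) {
    df <- orders_x[[nm]]
    if (nrow(df) < 2) next
    for (i in seq_len(nrow(df) - 1)) {
      g <- df$gene_id[i]; h <- df$gene_id[i + 1]
      if (is.null(pos_y[[g]]) || is.null(pos_y[[h]])) next
      fg <- if (str_y[[g]] == df$strand[i]) 1 else -1
      fh <- if (str_y[[h]] == df$strand[i + 1]) 1 else -1
      intact <- chr_y[[g]] == chr_y[[h]] && fg == fh &&
        (pos_y[[h]] - pos_y[[g]]) == fg
      if (!intact) b <- b + 1
    }
  }
  b
}

# exhaustive Needleman-Wunsch / Smith-Waterman scorer for tiny proteins,
# linear gap costs intentionally replaced by affine via 3-state DP
oracle_local_align_score <- function(a, b, mat, gap_open, gap_ext) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                             X[i, j + 1] - gap_ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                             Y[i + 1, j] - gap_ext)
      sc <- mat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(0,
                             max(M[i, j], X[i, j], Y[i, j]) + sc)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}
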