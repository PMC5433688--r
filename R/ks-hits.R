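# Homolog search between proteomes: shared-k-mer prefilter followed by
# Smith-Waterman scoring (BLOSUM62, affine gaps) of the candidate pairs.
# Replaces an external BLASTP dependency with the same decision rule: the
# highest-scoring subject is the homolog.

# k-mer table of a proteome: data.frame(idx, kmer), unique per protein
.protein_kmers <- function(prots, k) {
  lens <- nchar(prots)
  keep <- which(lens >= k)
  if (length(keep) == 0L) {
    return(data.frame(idx = integer(0L), kmer = character(0L)))
  }
  lst <- lapply(keep, function(i) {
    n <- lens[i]
    unique(substring(prots[i], 1:(n - k + 1L), k:n))
  })
  data.frame(
    idx = rep(keep, lengths(lst)),
    kmer = unlist(lst, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Best-hit homolog search between two proteomes
#'
#' For each query protein, candidate subjects are proteins sharing at least
#' `min_shared` k-mers with the query; candidates are scored by local
#' alignment (BLOSUM62, gap open 11 / extend 1) and the top scorer is the
#' best hit. Ties are broken by higher percent identity, then by
#' lexicographic subject id. Hits whose alignment covers less than
#' `min_coverage` of the shorter protein are discarded (such query genes
#' end up in the "no homolog" class downstream).
#'
#' @param query,subject Named character vectors of protein sequences.
#' @param k k-mer length of the prefilter (default 5).
#' @param min_shared Minimum shared k-mers for a candidate (default 3).
#' @param max_candidates Align at most this many candidates per query,
#'   keeping those sharing the most k-mers (default 8).
#' @param min_coverage Minimum fraction of the shorter protein covered by
#'   the local alignment (default 0.5).
#' @param exclude_self Drop hits of a protein to itself (same name); used
#'   for within-proteome searches.
#' @return data.frame with columns `query_id`, `subject_id`, `score`,
#'   `identity` (fraction), `coverage` (fraction of the shorter protein).
#'   Queries with no acceptable hit are absent.
#' @export
find_best_hits <- function(query, subject, k = 5L, min_shared = 3L,
                           max_candidates = 8L, min_coverage = 0.5,
                           exclude_self = FALSE) {
  if (length(query) == 0L || length(subject) == 0L) {
    warning("empty proteome: no hits")
    return(data.frame(query_id = character(0L), subject_id = character(0L),
                      score = numeric(0L), identity = numeric(0L),
                      coverage = numeric(0L), stringsAsFactors = FALSE))
  }
  stopifnot(!is.null(names(query)), !is.null(names(subject)))
  qk <- .protein_kmers(query, k)
  sk <- .protein_kmers(subject, k)
  # shared-k-mer counts per (query, subject) pair via an integer join
  lv <- unique(sk$kmer)
  qk <- qk[qk$kmer %in% lv, , drop = FALSE]
  qk$kid <- match(qk$kmer, lv)
  sk$kid <- match(sk$kmer, lv)
  s_by_k <- split(sk$idx, sk$kid)
  hit_s <- s_by_k[as.character(qk$kid)]
  nrep <- lengths(hit_s)
  pair_q <- rep(qk$idx, nrep)
  pair_s <- unlist(hit_s, use.names = FALSE)
  if (length(pair_q) == 0L) {
    return(data.frame(query_id = character(0L), subject_id = character(0L),
                      score = numeric(0L), identity = numeric(0L),
                      coverage = numeric(0L), stringsAsFactors = FALSE))
  }
  key <- (pair_q - 1) * length(subject) + pair_s
  cnt <- table(key)
  keyv <- as.numeric(names(cnt))
  shared <- as.integer(cnt)
  cq <- as.integer((keyv - 1) %/% length(subject)) + 1L
  cs <- as.integer((keyv - 1) %% length(subject)) + 1L
  ok <- shared >= min_shared
  if (exclude_self) ok <- ok & names(query)[cq] != names(subject)[cs]
  cq <- cq[ok]; cs <- cs[ok]; shared <- shared[ok]

  # cap candidates per query by shared-k-mer count, then score every
  # retained (query, candidate) pair in one vectorised alignment call
  keep_idx <- integer(0L)
  for (q in unique(cq)) {
    sel <- which(cq == q)
    sel <- sel[order(-shared[sel])]
    if (length(sel) > max_candidates) sel <- sel[seq_len(max_candidates)]
    keep_idx <- c(keep_idx, sel)
  }
  cq <- cq[keep_idx]; cs <- cs[keep_idx]
  if (length(cq) == 0L) {
    return(data.frame(query_id = character(0L), subject_id = character(0L),
                      score = numeric(0L), identity = numeric(0L),
                      coverage = numeric(0L), stringsAsFactors = FALSE))
  }
  prm <- .aln_params()
  mat <- .blosum62()
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(unname(query[cq])),
    Biostrings::AAStringSet(unname(subject[cs])),
    substitutionMatrix = mat, gapOpening = prm$gap_open,
    gapExtension = prm$gap_ext, type = "local"
  )
  sc <- Biostrings::score(al)
  idf <- Biostrings::pid(al) / 100
  cov <- Biostrings::nchar(al) /
    pmin(nchar(query)[cq], nchar(subject)[cs])

  res <- vector("list", length(unique(cq)))
  ri <- 0L
  for (q in unique(cq)) {
    sel <- which(cq == q)
    ord <- sel[order(-sc[sel], -idf[sel], names(subject)[cs[sel]])]
    b <- ord[1L]
    if (cov[b] >= min_coverage) {
      ri <- ri + 1L
      res[[ri]] <- data.frame(
        query_id = names(query)[q], subject_id = names(subject)[cs[b]],
        score = sc[b], identity = idf[b],
        coverage = min(cov[b], 1),
        stringsAsFactors = FALSE
      )
    }
  }
  if (ri == 0L) {
    return(data.frame(query_id = character(0L), subject_id = character(0L),
                      score = numeric(0L), identity = numeric(0L),
                      coverage = numeric(0L), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res[seq_len(ri)])
  out[order(out$query_id), , drop = FALSE]
}

#' Reciprocal-best-hit pairs from two best-hit tables
#'
#' Pairs (a, b) where b is a's best hit and a is b's best hit. Because each
#' query has at most one best hit, every gene occurs in at most one pair.
#'
#' @param hits_ab Best hits of proteome A queried against proteome B.
#' @param hits_ba Best hits of proteome B queried against proteome A.
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
reciprocal_best_pairs <- function(hits_ab, hits_ba) {
  if (nrow(hits_ab) == 0L || nrow(hits_ba) == 0L) {
    return(data.frame(gene_a = character(0L), gene_b = character(0L),
                      stringsAsFactors = FALSE))
  }
  back <- stats::setNames(hits_ba$subject_id, hits_ba$query_id)
  mutual <- !is.na(back[hits_ab$subject_id]) &
    back[hits_ab$subject_id] == hits_ab$query_id
  mutual[is.na(mutual)] <- FALSE
  out <- data.frame(gene_a = hits_ab$query_id[mutual],
                    gene_b = hits_ab$subject_id[mutual],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Homeolog pairs within one proteome
#'
#' Within-proteome reciprocal-best-hit pairing (self-hits excluded); each
#' unordered pair is reported once.
#' @param prots Named character vector of proteins.
#' @param ... Passed to [find_best_hits()].
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
pair_within <- function(prots, ...) {
  hits <- find_best_hits(prots, prots, exclude_self = TRUE, ...)
  pairs <- reciprocal_best_pairs(hits, hits)
  if (nrow(pairs) == 0L) return(pairs)
  keep <- pairs$gene_a < pairs$gene_b
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
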