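# Internal simulator representation: a chromosome is an ordered list of
# gene bodies (CDS stored in coding orientation plus a strand) separated
# by intergenic spacers and capped by telomere arrays:
#
#   tel_l  spacer[1]  gene[1]  spacer[2] ... gene[n]  spacer[n+1]  tel_r
#
# Rearrangements, LOH, crossovers and BIR are permutations/edits of this
# element list; the flat sequence and gene coordinates are materialised
# only at emission. Non-gene features (MAT cassettes) are anchored to a
# (chromosome, spacer index, offset) triple and resolved at emission.

.sim_chromosome <- function(name, genes, spacers, tel_l, tel_r) {
  stopifnot(length(spacers) == nrow(genes) + 1L)
  list(name = name, genes = genes, spacers = spacers,
       tel_l = tel_l, tel_r = tel_r)
}

.sim_genome <- function(chroms, parent = "A") {
  structure(list(chroms = chroms, parent = parent,
                 features = NULL), class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  ng <- sum(vapply(x$chroms, function(ch) nrow(ch$genes), integer(1L)))
  cat(sprintf("Simulated parent-%s genome: %d chromosomes, %d genes\n",
              x$parent, length(x$chroms), ng))
  invisible(x)
}

# Ordered gene table (gene_id, chrom, index, strand) of a sim genome.
.sim_order <- function(sim) {
  rows <- lapply(sim$chroms, function(ch) {
    n <- nrow(ch$genes)
    if (n == 0L) return(NULL)
    data.frame(gene_id = ch$genes$gene_id, chrom = ch$name,
               index = seq_len(n), strand = ch$genes$strand,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0L), chrom = character(0L),
                      index = integer(0L), strand = character(0L))
  }
  rownames(out) <- NULL
  out
}

# locate genes: named list chrom/pos for a set of gene ids
.sim_locate <- function(sim, ids) {
  ord <- .sim_order(sim)
  m <- match(ids, ord$gene_id)
  if (anyNA(m)) stop("gene id not in simulated genome")
  ord[m, , drop = FALSE]
}

# Materialise one chromosome: returns list(seq, gene_coords, spacer_starts)
.sim_build_chrom <- function(ch) {
  n <- nrow(ch$genes)
  parts <- character(2L * n + 3L)
  kinds <- character(2L * n + 3L)
  parts[1L] <- ch$tel_l; kinds[1L] <- "tel"
  pi <- 1L
  for (i in seq_len(n)) {
    pi <- pi + 1L; parts[pi] <- ch$spacers[i]; kinds[pi] <- paste0("sp", i)
    body <- if (ch$genes$strand[i] == "+") ch$genes$cds[i] else
      revcomp(ch$genes$cds[i])
    pi <- pi + 1L; parts[pi] <- body; kinds[pi] <- paste0("g", i)
  }
  pi <- pi + 1L; parts[pi] <- ch$spacers[n + 1L]
  kinds[pi] <- paste0("sp", n + 1L)
  pi <- pi + 1L; parts[pi] <- ch$tel_r; kinds[pi] <- "tel"
  parts <- parts[seq_len(pi)]; kinds <- kinds[seq_len(pi)]
  lens <- nchar(parts)
  starts <- cumsum(c(1L, lens[-length(lens)]))
  seq <- paste(parts, collapse = "")
  gsel <- grep("^g", kinds)
  gene_coords <- data.frame(
    gene_id = ch$genes$gene_id,
    start = starts[gsel],
    end = starts[gsel] + lens[gsel] - 1L,
    strand = ch$genes$strand,
    stringsAsFactors = FALSE
  )
  spsel <- grep("^sp", kinds)
  spacer_starts <- stats::setNames(starts[spsel],
                                   sub("^sp", "", kinds[spsel]))
  list(seq = seq, gene_coords = gene_coords, spacer_starts = spacer_starts)
}

#' Materialise a simulated genome as an annotated genome
#'
#' Flattens the element-list representation into chromosome sequences and
#' 1-based gene coordinates. Feature anchors (MAT cassettes) are resolved
#' to absolute coordinates.
#'
#' @param sim A `sim_genome`.
#' @return An [annotated_genome()]; `$features` holds resolved non-gene
#'   features when present.
#' @export
as_annotated_genome <- function(sim) {
  built <- lapply(sim$chroms, .sim_build_chrom)
  names(built) <- vapply(sim$chroms, `[[`, character(1L), "name")
  seqs <- vapply(built, `[[`, character(1L), "seq")
  gene_rows <- lapply(names(built), function(nm) {
    gc <- built[[nm]]$gene_coords
    if (nrow(gc) == 0L) return(NULL)
    cbind(gc[, "gene_id", drop = FALSE],
          data.frame(chrom = nm, stringsAsFactors = FALSE),
          gc[, c("start", "end", "strand")])
  })
  genes <- do.call(rbind, gene_rows)
  if (is.null(genes)) {
    genes <- data.frame(gene_id = character(0L), chrom = character(0L),
                        start = integer(0L), end = integer(0L),
                        strand = character(0L))
  }
  features <- NULL
  if (!is.null(sim$features) && nrow(sim$features) > 0L) {
    fs <- sim$features
    abs_start <- integer(nrow(fs))
    for (i in seq_len(nrow(fs))) {
      sp0 <- built[[fs$chrom[i]]]$spacer_starts[[as.character(fs$spacer_index[i])]]
      abs_start[i] <- sp0 + fs$offset[i] - 1L
    }
    features <- data.frame(
      name = fs$name, type = fs$type, chrom = fs$chrom,
      start = abs_start, end = abs_start + fs$len - 1L,
      stringsAsFactors = FALSE
    )
  }
  annotated_genome(seqs, genes, features = features)
}

# split a spacer string at an offset (characters 1..off stay left)
.split_spacer <- function(s, off) {
  list(left = substr(s, 1L, off), right = substr(s, off + 1L, nchar(s)))
}
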