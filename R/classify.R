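# Subgenome classification: thresholding synonymous divergence into
# parental labels, typing homeolog pairs, and assembling the 7-category
# genome map that post-hybridization events are read from.

.CATEGORIES <- c("A-in-A:B", "B-in-A:B", "A-in-A:A", "B-in-B:B",
                 "A-unpaired", "B-unpaired", "N")

#' Assign a subgenome label from synonymous divergence
#'
#' A gene is assigned to the A-subgenome (the reference-like parent) if
#' its synonymous divergence from its reference homolog is at most
#' `ks_a`, to the B-subgenome if it lies in (`ks_a`, `ks_b`], and to the
#' "N" class if it exceeds `ks_b` or could not be computed. Boundary
#' values go to the lower class.
#'
#' @param ks Numeric vector of Ks values; `NA` means no homolog /
#'   incalculable.
#' @param ks_a Upper bound of the A class (default 0.05).
#' @param ks_b Upper bound of the B class (default 0.25).
#' @return Character vector of labels in `{A, B, N}`.
#' @export
assign_subgenome <- function(ks, ks_a = 0.05, ks_b = 0.25) {
  stopifnot(ks_a < ks_b)
  if (any(!is.na(ks) & ks < 0)) stop("negative Ks")
  out <- rep("N", length(ks))
  out[!is.na(ks) & ks <= ks_b] <- "B"
  out[!is.na(ks) & ks <= ks_a] <- "A"
  out
}

#' Type homeolog pairs from member labels
#'
#' @param label_a,label_b Character vectors of subgenome labels of the two
#'   pair members.
#' @return Character vector: "A:B", "A:A", "B:B", or "other" (any pair
#'   containing an N label).
#' @export
type_pairs <- function(label_a, label_b) {
  stopifnot(length(label_a) == length(label_b))
  out <- rep("other", length(label_a))
  ab <- (label_a == "A" & label_b == "B") | (label_a == "B" & label_b == "A")
  out[ab] <- "A:B"
  out[label_a == "A" & label_b == "A"] <- "A:A"
  out[label_a == "B" & label_b == "B"] <- "B:B"
  out
}

#' Categorize genes into the 7-way genome map
#'
#' Combines per-gene subgenome labels and within-hybrid pairing status
#' into one of 7 categories: A or B member of an A:B pair, member of an
#' A:A or B:B (LOH) pair, unpaired A or B gene, or N. A labeled gene whose
#' pair contains an N partner is treated as effectively unpaired. The
#' categories partition the gene set.
#'
#' @param genes Gene table: data.frame with `gene_id`, `chrom`, `index`
#'   (order along the chromosome), e.g. the `genes` component of an
#'   [annotated_genome()].
#' @param labels Named character vector (gene_id -> label in `{A, B, N}`).
#' @param pairs data.frame with `gene_a`, `gene_b`: within-hybrid homeolog
#'   pairs (each gene in at most one pair).
#' @return list with `genes` (gene table + `label`, `pair_id`,
#'   `pair_type`, `category`), `tracks` (per-chromosome
#'   `category_track` data.frames) and `counts` (named category counts).
#' @export
categorize <- function(genes, labels, pairs) {
  g <- genes
  if (any(duplicated(c(pairs$gene_a, pairs$gene_b)))) {
    stop("inconsistent pair membership: a gene occurs in two pairs")
  }
  g$label <- unname(labels[g$gene_id])
  if (anyNA(g$label)) stop("every gene needs a label")
  partner <- stats::setNames(c(pairs$gene_b, pairs$gene_a),
                             c(pairs$gene_a, pairs$gene_b))
  pair_id <- stats::setNames(rep(seq_len(nrow(pairs)), 2L),
                             c(pairs$gene_a, pairs$gene_b))
  g$partner <- unname(partner[g$gene_id])
  g$pair_id <- unname(pair_id[g$gene_id])
  plab <- unname(labels[g$partner])
  g$pair_type <- ifelse(is.na(g$partner), NA,
                        type_pairs(g$label, plab))
  cat <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    L <- g$label[i]
    if (L == "N") {
      cat[i] <- "N"
    } else if (!is.na(g$pair_type[i]) && g$pair_type[i] == "A:B") {
      cat[i] <- paste0(L, "-in-A:B")
    } else if (!is.na(g$pair_type[i]) && g$pair_type[i] == paste0(L, ":", L)) {
      cat[i] <- paste0(L, "-in-", L, ":", L)
    } else {
      cat[i] <- paste0(L, "-unpaired")
    }
  }
  g$category <- cat
  counts <- table(factor(g$category, levels = .CATEGORIES))
  tracks <- lapply(split(g, g$chrom), function(df) {
    df <- df[order(df$index), , drop = FALSE]
    rownames(df) <- NULL
    class(df) <- c("category_track", class(df))
    df
  })
  list(genes = g, tracks = tracks,
       counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Export a category map as BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open,
#' so `start0 = start - 1`, `end` unchanged.
#'
#' @param genes Categorized gene table (from [categorize()]; needs
#'   `chrom`, `start`, `end`, `gene_id`, `category`).
#' @param path Output BED path.
#' @export
write_category_bed <- function(genes, path) {
  stopifnot(all(c("chrom", "start", "end", "category") %in% names(genes)))
  bed <- data.frame(
    chrom = genes$chrom,
    start = genes$start - 1L,
    end = genes$end,
    name = paste0(genes$gene_id, "|", genes$category),
    stringsAsFactors = FALSE
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a category BED written by [write_category_bed()]
#'
#' Converts back to 1-based inclusive coordinates.
#' @param path BED path.
#' @return data.frame with `chrom`, `start`, `end`, `gene_id`, `category`.
#' @export
read_category_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(bed) <- c("chrom", "start0", "end", "name")
  parts <- strsplit(bed$name, "|", fixed = TRUE)
  data.frame(
    chrom = bed$chrom,
    start = bed$start0 + 1L,
    end = bed$end,
    gene_id = vapply(parts, `[`, character(1L), 1L),
    category = vapply(parts, `[`, character(1L), 2L),
    stringsAsFactors = FALSE
  )
}
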