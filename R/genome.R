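# The annotated genome container: chromosome sequences plus an ordered
# gene table. Internal coordinates are 1-based inclusive (GFF3
# convention). When produced by the simulator the object also carries
# sequence features (MAT cassettes, telomeres) and ground-truth labels.

#' Construct an annotated genome
#'
#' @param seq Named character vector of chromosome sequences.
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` ("+"/"-"); one row per gene, coordinates 1-based inclusive.
#' @param features Optional data.frame of non-gene sequence features
#'   (columns `name`, `type`, `chrom`, `start`, `end`).
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(seq, genes, features = NULL) {
  stopifnot(is.character(seq), !is.null(names(seq)))
  need <- c("gene_id", "chrom", "start", "end", "strand")
  stopifnot(all(need %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
  if (!all(genes$chrom %in% names(seq))) stop("gene on unknown chromosome")
  genes <- genes[order(match(genes$chrom, names(seq)), genes$start), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  genes$index <- stats::ave(seq_len(nrow(genes)), genes$chrom,
                            FUN = seq_along)
  structure(list(seq = seq, genes = genes, features = features),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("Annotated genome: %d chromosomes (%.2f Mb), %d genes\n",
              length(x$seq), sum(nchar(x$seq)) / 1e6, nrow(x$genes)))
  invisible(x)
}

#' Extract coding sequences from an annotated genome
#'
#' Genes on the "-" strand are reverse-complemented so that every returned
#' CDS is in coding orientation.
#'
#' @param genome An `annotated_genome`.
#' @param gene_ids Optional subset of gene ids (default: all genes).
#' @return Named character vector of CDS.
#' @export
extract_cds <- function(genome, gene_ids = NULL) {
  g <- genome$genes
  if (!is.null(gene_ids)) {
    g <- g[match(gene_ids, g$gene_id), , drop = FALSE]
    if (anyNA(g$gene_id)) stop("unknown gene id")
  }
  out <- substr(genome$seq[g$chrom], g$start, g$end)
  neg <- g$strand == "-"
  if (any(neg)) out[neg] <- revcomp(out[neg])
  stats::setNames(unname(out), g$gene_id)
}

#' Proteome of an annotated genome
#'
#' @inheritParams extract_cds
#' @param pseudogene_mode Passed to [translate_cds()]; when `TRUE`, damaged
#'   CDS are translated to the first stop instead of erroring.
#' @return Named character vector of protein sequences.
#' @export
extract_proteome <- function(genome, gene_ids = NULL, pseudogene_mode = TRUE) {
  cds <- extract_cds(genome, gene_ids)
  vapply(cds, function(s) as.character(translate_cds(s, pseudogene_mode)),
         character(1L))
}

#' Write an annotated genome to FASTA + GFF3
#'
#' @param genome An `annotated_genome`.
#' @param fasta,gff Output paths.
#' @export
write_genome <- function(genome, fasta, gff) {
  dna <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(dna, fasta)
  g <- genome$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand
  )
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$ID <- g$gene_id
  S4Vectors::mcols(gr)$source <- "hybridarch"
  S4Vectors::mcols(gr)$phase <- 0L
  rtracklayer::export(gr, gff, format = "gff3")
  invisible(c(fasta = fasta, gff = gff))
}

#' Read an annotated genome from FASTA + GFF3
#'
#' Gene models are taken from `CDS` (or `gene` if no CDS present) records;
#' the `ID` attribute names the genes.
#' @param fasta,gff Input paths.
#' @return An `annotated_genome`.
#' @export
read_genome <- function(fasta, gff) {
  dna <- Biostrings::readDNAStringSet(fasta)
  seq <- stats::setNames(as.character(dna),
                         sub("\\s.*$", "", names(dna)))
  gr <- rtracklayer::import(gff, format = "gff3")
  types <- as.character(S4Vectors::mcols(gr)$type)
  sel <- if (any(types == "CDS")) types == "CDS" else types == "gene"
  gr <- gr[sel]
  ids <- S4Vectors::mcols(gr)$ID
  if (is.null(ids)) ids <- S4Vectors::mcols(gr)$Name
  genes <- data.frame(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  annotated_genome(seq, genes)
}
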