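#' Build a gene table
#'
#' The gene table is the package's in-memory representation of a gene
#' annotation: one row per gene, with the exon structure of a single
#' representative mRNA carried as a list column.  All coordinates are
#' 0-based half-open; file readers and writers convert at the boundary
#' (GFF3 is 1-based inclusive).
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param scaffold scaffold/chromosome name per gene.
#' @param start,end integer gene span, 0-based half-open (`start < end`).
#' @param strand `"+"` or `"-"`.
#' @param exons list of two-column matrices (`start`, `end`; same
#'   convention) giving the exon structure of the representative mRNA.
#'   Exons must be non-overlapping and contained in the gene span.
#' @param cds_length total coding length in bp of the representative mRNA.
#' @param protein_length protein length in amino acids (>= 1).
#' @param rank 0-based ordinal of the gene along its scaffold, or `NA`
#'   before [rank_genes()] has been run.
#'
#' @return A `data.frame` of class `"gene_table"`.
#' @seealso [rank_genes()], [annotation_stats()], [read_gff3()]
#' @export
gene_table <- function(gene_id, scaffold, start, end, strand, exons,
                       cds_length = NULL, protein_length = NULL,
                       rank = NA_integer_) {
  n <- length(gene_id)
  if (length(scaffold) == 1L) scaffold <- rep(scaffold, n)
  if (length(strand) == 1L) strand <- rep(strand, n)
  stopifnot(length(scaffold) == n, length(start) == n, length(end) == n,
            length(strand) == n, length(exons) == n)
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id: ", gene_id[duplicated(gene_id)][1L])
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) stop("gene with start >= end")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (is.null(cds_length))
    cds_length <- vapply(exons, function(e) sum(e[, 2L] - e[, 1L]), 0)
  cds_length <- as.integer(cds_length)
  if (is.null(protein_length)) protein_length <- cds_length %/% 3L
  protein_length <- as.integer(protein_length)
  if (any(protein_length < 1L)) stop("protein_length must be >= 1")
  for (i in seq_len(n)) {
    e <- exons[[i]]
    if (!is.matrix(e) || ncol(e) != 2L) stop("exons must be 2-column matrices")
    e <- e[order(e[, 1L]), , drop = FALSE]
    if (any(e[, 1L] >= e[, 2L])) stop("exon with start >= end in ", gene_id[i])
    if (e[1L, 1L] < start[i] || e[nrow(e), 2L] > end[i])
      stop("exon outside gene span in ", gene_id[i])
    if (nrow(e) > 1L && any(e[-1L, 1L] < e[-nrow(e), 2L]))
      stop("overlapping exons in ", gene_id[i])
    exons[[i]] <- e
  }
  out <- data.frame(gene_id = as.character(gene_id),
                    scaffold = as.character(scaffold),
                    start = start, end = end, strand = strand,
                    cds_length = cds_length,
                    protein_length = protein_length,
                    rank = as.integer(rank),
                    stringsAsFactors = FALSE)
  out$exons <- unname(exons)
  class(out) <- c("gene_table", "data.frame")
  out
}

#' Assign per-scaffold gene ranks
#'
#' Within each scaffold, genes are numbered 0..n-1 in order of their start
#' coordinate.  Ties on start are broken deterministically by end and then
#' by gene id.  This rank space is the coordinate system used by the
#' collinearity module: anchor chaining and gap counting operate on gene
#' ranks, not base pairs.
#'
#' The function is idempotent and depends only on the set of input rows,
#' not their order; the result is returned sorted by (scaffold, rank).
#'
#' @param genes a [gene_table()].
#' @return The gene table with `rank` filled in, sorted by scaffold and rank.
#' @export
rank_genes <- function(genes) {
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id: ", genes$gene_id[duplicated(genes$gene_id)][1L])
  ord <- order(genes$scaffold, genes$start, genes$end, genes$gene_id)
  genes <- genes[ord, ]
  # rows are sorted, so rank is the running index within scaffold
  genes$rank <- as.integer(stats::ave(genes$start, genes$scaffold,
                                      FUN = seq_along) - 1L)
  rownames(genes) <- NULL
  genes
}

#' Gene-feature summary statistics
#'
#' Computes the per-annotation summary used to compare genome annotations:
#' gene count, mean gene/CDS/intron/exon length and the exons-per-mRNA
#' ratio.  One representative mRNA per gene is used (the readers pick the
#' longest); intron lengths are the gaps between its consecutive exons.
#' Annotations without any intron report `mean_intron_length = 0` and
#' `has_introns = FALSE`.
#'
#' @param genes a [gene_table()] with at least one gene.
#' @return An object of class `"annotation_stats"`: a list with elements
#'   `n_genes`, `mean_gene_length`, `mean_cds_length`, `mean_intron_length`,
#'   `mean_exon_length`, `exons_per_mrna` and `has_introns`.
#' @export
annotation_stats <- function(genes) {
  if (!nrow(genes)) stop("annotation_stats needs at least one gene")
  exon_len <- unlist(lapply(genes$exons, function(e) e[, 2L] - e[, 1L]),
                     use.names = FALSE)
  intron_len <- unlist(lapply(genes$exons, function(e) {
    if (nrow(e) < 2L) return(integer())
    e[-1L, 1L] - e[-nrow(e), 2L]
  }), use.names = FALSE)
  n_exons <- vapply(genes$exons, nrow, 0L)
  out <- list(
    n_genes = nrow(genes),
    mean_gene_length = mean(genes$end - genes$start),
    mean_cds_length = mean(genes$cds_length),
    mean_intron_length = if (length(intron_len)) mean(intron_len) else 0,
    mean_exon_length = mean(exon_len),
    exons_per_mrna = sum(n_exons) / nrow(genes),
    has_introns = length(intron_len) > 0L
  )
  class(out) <- "annotation_stats"
  out
}

#' @export
print.annotation_stats <- function(x, ...) {
  cat("Annotation summary\n")
  cat(sprintf("  genes:              %d\n", x$n_genes))
  cat(sprintf("  mean gene length:   %.1f bp\n", x$mean_gene_length))
  cat(sprintf("  mean CDS length:    %.1f bp\n", x$mean_cds_length))
  cat(sprintf("  mean intron length: %.1f bp%s\n", x$mean_intron_length,
              if (!x$has_introns) " (no introns)" else ""))
  cat(sprintf("  mean exon length:   %.1f bp\n", x$mean_exon_length))
  cat(sprintf("  exons per mRNA:     %.2f\n", x$exons_per_mrna))
  invisible(x)
}
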