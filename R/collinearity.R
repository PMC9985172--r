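#' Join single-copy ortholog pairs to gene ranks
#'
#' Builds the anchor set for collinearity analysis: one anchor per 1:1
#' ortholog pair, carrying the scaffold and per-scaffold rank of each gene.
#' Pairs whose genes are missing from either annotation are dropped; the
#' number dropped is attached as attribute `n_dropped`.  A gene occurring
#' in more than one pair violates the single-copy assumption and is an
#' error.
#'
#' @param orthologs data.frame with columns `gene_a`, `gene_b` (see
#'   [read_anchor_table()]).
#' @param genes_a,genes_b ranked [gene_table()]s (see [rank_genes()]).
#' @return data.frame of anchors: `gene_a`, `gene_b`, `scaffold_a`,
#'   `scaffold_b`, `rank_a`, `rank_b`.
#' @export
build_anchors <- function(orthologs, genes_a, genes_b) {
  if (anyDuplicated(orthologs$gene_a) || anyDuplicated(orthologs$gene_b))
    stop("ortholog table is not single-copy: a gene occurs in >1 pair")
  if (anyNA(genes_a$rank) || anyNA(genes_b$rank))
    stop("genes must be ranked first (rank_genes)")
  ia <- match(orthologs$gene_a, genes_a$gene_id)
  ib <- match(orthologs$gene_b, genes_b$gene_id)
  keep <- !is.na(ia) & !is.na(ib)
  out <- data.frame(
    gene_a = orthologs$gene_a[keep], gene_b = orthologs$gene_b[keep],
    scaffold_a = genes_a$scaffold[ia[keep]],
    scaffold_b = genes_b$scaffold[ib[keep]],
    rank_a = genes_a$rank[ia[keep]], rank_b = genes_b$rank[ib[keep]],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$scaffold_a, out$scaffold_b, out$rank_a, out$rank_b), ]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Chain anchors into collinear blocks
#'
#' Re-implementation of s/m block chaining: within each scaffold pair the
#' maximum-anchor-count chain satisfying the gap constraint (at most `m`
#' intervening gene ranks on each genome between consecutive anchors) and
#' a constant orientation is extracted repeatedly, removing its anchors,
#' until the best remaining chain has fewer than `s` anchors.  Ties are
#' broken by smaller total gap, then by the leftmost (lexicographically
#' smallest) anchor sequence, so output is deterministic.  Mixed
#' orientations are not allowed within a block: an inversion inside a
#' collinear region yields separate `+` and `-` blocks.
#'
#' Scoring is deliberately simpler than MCScanX's (no match/gap scores or
#' block E-values): `s` and `m` are the operative knobs.
#'
#' @param anchors anchor data.frame from [build_anchors()].
#' @param s minimum anchors per block (>= 2).
#' @param m maximum gap in genes between consecutive anchors (>= 0).
#' @return An object of class `"collinear_blocks"`: list with `anchors`
#'   (input rows plus `block_id`, `NA` when unchained), `blocks` (one row
#'   per block: id, scaffold pair, orientation, `n_anchors`) and the
#'   parameters.
#' @export
chain_blocks <- function(anchors, s = 5L, m = 25L) {
  s <- as.integer(s); m <- as.integer(m)
  if (s < 2L) stop("s must be >= 2")
  if (m < 0L) stop("m must be >= 0")
  anchors <- anchors[order(anchors$scaffold_a, anchors$scaffold_b,
                           anchors$rank_a, anchors$rank_b), ]
  rownames(anchors) <- NULL
  anchors$block_id <- rep(NA_integer_, nrow(anchors))
  key <- paste(anchors$scaffold_a, anchors$scaffold_b, sep = "\r")
  blocks <- list()
  next_id <- 0L
  for (k in sort(unique(key))) {
    idx <- which(key == k)
    res <- chain_dp(anchors$rank_a[idx], anchors$rank_b[idx], s, m)
    nb <- length(res$orientation)
    if (!nb) next
    anchors$block_id[idx] <- ifelse(res$block > 0L, res$block + next_id,
                                    NA_integer_)
    for (b in seq_len(nb)) {
      in_b <- idx[res$block == b]
      blocks[[length(blocks) + 1L]] <- data.frame(
        block_id = next_id + b,
        scaffold_a = anchors$scaffold_a[in_b[1L]],
        scaffold_b = anchors$scaffold_b[in_b[1L]],
        orientation = res$orientation[b],
        n_anchors = length(in_b),
        rank_a_min = min(anchors$rank_a[in_b]),
        rank_a_max = max(anchors$rank_a[in_b]),
        rank_b_min = min(anchors$rank_b[in_b]),
        rank_b_max = max(anchors$rank_b[in_b]),
        stringsAsFactors = FALSE
      )
    }
    next_id <- next_id + nb
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(block_id = integer(), scaffold_a = character(),
               scaffold_b = character(), orientation = character(),
               n_anchors = integer(), rank_a_min = integer(),
               rank_a_max = integer(), rank_b_min = integer(),
               rank_b_max = integer(), stringsAsFactors = FALSE)
  structure(list(anchors = anchors, blocks = blocks, s = s, m = m),
            class = "collinear_blocks")
}

#' @export
print.collinear_blocks <- function(x, ...) {
  cat(sprintf("Collinear blocks (s = %d, m = %d): %d block(s), %d/%d anchors chained (%.1f%%)\n",
              x$s, x$m, nrow(x$blocks), sum(!is.na(x$anchors$block_id)),
              nrow(x$anchors), percent_collinear(x)))
  invisible(x)
}

#' Percentage of anchors inside collinear blocks
#'
#' @param blocks a `"collinear_blocks"` object from [chain_blocks()].
#' @return `100 * anchors_in_blocks / total_anchors`.
#' @export
percent_collinear <- function(blocks) {
  n <- nrow(blocks$anchors)
  if (!n) stop("no anchors")
  100 * sum(!is.na(blocks$anchors$block_id)) / n
}

#' Average collinearity decay over divergence time
#'
#' Groups per-species-pair collinearity percentages by divergence time and
#' averages within each time, producing the points of a decay curve.
#' Divergence times are user-supplied metadata (literature values), never
#' computed here.
#'
#' @param points data.frame with columns `species_pair`, `divergence_time`
#'   (Ma) and `percent_collinear`.
#' @return data.frame with `divergence_time` and mean `percent_collinear`,
#'   sorted by time.
#' @export
decay_curve <- function(points) {
  if (!nrow(points)) stop("no decay points")
  out <- aggregate(percent_collinear ~ divergence_time, data = points, mean)
  out[order(out$divergence_time), , drop = FALSE]
}

#' Assign scaffolds to chromosomes by modal ortholog hits
#'
#' For a fragmented assembly compared against a chromosome-scale reference,
#' each scaffold with at least `min_hits` orthologous anchors is assigned
#' to the reference chromosome carrying most of its hits.  Ties go to the
#' lexicographically smallest chromosome and are flagged.
#'
#' @param anchors anchor data.frame ([build_anchors()]); `scaffold_a` is
#'   the fragmented side, `scaffold_b` the reference chromosomes.
#' @param min_hits minimum anchors required to report a scaffold.
#' @return data.frame with `scaffold`, `chromosome`, `fraction_modal`,
#'   `n_hits`, `tie`.
#' @export
assign_scaffolds <- function(anchors, min_hits = 10L) {
  rows <- lapply(split(anchors, anchors$scaffold_a), function(d) {
    if (nrow(d) < min_hits) return(NULL)
    tab <- table(d$scaffold_b)
    best <- max(tab)
    winners <- sort(names(tab)[tab == best])
    data.frame(scaffold = d$scaffold_a[1L], chromosome = winners[1L],
               fraction_modal = as.numeric(best) / nrow(d),
               n_hits = nrow(d), tie = length(winners) > 1L,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(scaffold = character(), chromosome = character(),
                      fraction_modal = numeric(), n_hits = integer(),
                      tie = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count inverted blocks per scaffold pair
#'
#' Blocks with `-` orientation are the signature of inversions between the
#' two genomes; counts are reported alongside `+` blocks.
#'
#' @param blocks a `"collinear_blocks"` object.
#' @return data.frame with `scaffold_a`, `scaffold_b`, `n_plus`, `n_minus`.
#' @export
count_inversions <- function(blocks) {
  b <- blocks$blocks
  if (!nrow(b))
    return(data.frame(scaffold_a = character(), scaffold_b = character(),
                      n_plus = integer(), n_minus = integer(),
                      stringsAsFactors = FALSE))
  out <- aggregate(cbind(n_plus = b$orientation == "+",
                         n_minus = b$orientation == "-"),
                   by = list(scaffold_a = b$scaffold_a,
                             scaffold_b = b$scaffold_b), FUN = sum)
  out$n_plus <- as.integer(out$n_plus)
  out$n_minus <- as.integer(out$n_minus)
  out[order(out$scaffold_a, out$scaffold_b), , drop = FALSE]
}
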