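#' Duplicate-gene detection parameters
#'
#' Defaults: a paralog pair needs >= 30% identity over >= 50% of the
#' shorter protein; only genes with proteins strictly longer than 150 aa
#' enter the percent-duplicated denominator; a pair is tandem when at most
#' 5 genes intervene.  Identity/coverage thresholds stand in for an
#' E-value cutoff so no external search tool is needed.
#'
#' @param min_identity minimum fraction identity over the aligned region.
#' @param min_coverage minimum aligned fraction of the shorter protein.
#' @param min_protein_length_aa eligibility cutoff (strictly greater than).
#' @param tandem_max_intervening maximum intervening genes for tandem.
#' @return list of class `"duplication_params"`.
#' @export
duplication_params <- function(min_identity = 0.30, min_coverage = 0.50,
                               min_protein_length_aa = 150L,
                               tandem_max_intervening = 5L) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1,
            min_protein_length_aa > 0, tandem_max_intervening >= 0)
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 min_protein_length_aa = as.integer(min_protein_length_aa),
                 tandem_max_intervening = as.integer(tandem_max_intervening)),
            class = "duplication_params")
}

# unordered candidate pairs sharing >= 2 amino-acid k-mers
.kmer_candidates <- function(proteins, k = 5L) {
  ids <- names(proteins)
  kmers <- lapply(proteins, function(p) {
    n <- nchar(p)
    if (n < k) return(character())
    unique(substring(p, 1:(n - k + 1L), k:n))
  })
  idx_by_kmer <- split(rep(seq_along(ids), lengths(kmers)),
                       unlist(kmers, use.names = FALSE))
  counts <- new.env(hash = TRUE, parent = emptyenv())
  for (members in idx_by_kmer) {
    members <- unique(members)
    if (length(members) < 2L) next
    for (a in seq_len(length(members) - 1L)) {
      for (b in (a + 1L):length(members)) {
        key <- paste0(members[a], "_", members[b])
        counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
      }
    }
  }
  keys <- ls(counts)
  keep <- keys[vapply(keys, function(k2) counts[[k2]] >= 2L, TRUE)]
  if (!length(keep)) return(matrix(integer(), 0L, 2L))
  do.call(rbind, lapply(strsplit(keep, "_", fixed = TRUE),
                        function(p) as.integer(p)))
}

#' Find paralogous protein pairs
#'
#' All-vs-all protein comparison: candidate pairs are prefiltered by
#' shared 5-mer amino-acid words (>= 2 shared), then locally aligned
#' (BLOSUM62); pairs passing both the identity and the
#' shorter-protein-coverage thresholds are reported.  `prefilter = FALSE`
#' disables the word filter and aligns every pair - the exhaustive oracle
#' mode used to validate the filter.
#'
#' @param proteins named character vector of amino-acid sequences (>= 2).
#' @param params a [duplication_params()].
#' @param prefilter use the shared-k-mer prefilter (default `TRUE`).
#' @return data.frame of unordered pairs: `gene_a`, `gene_b` (gene_a <
#'   gene_b), `identity`, `coverage`.
#' @export
find_paralog_pairs <- function(proteins, params = duplication_params(),
                               prefilter = TRUE) {
  if (length(proteins) < 2L) stop("need at least 2 proteins")
  ids <- names(proteins)
  if (is.null(ids) || anyDuplicated(ids)) stop("proteins must have unique names")
  if (prefilter) {
    cand <- .kmer_candidates(proteins)
  } else {
    cand <- t(utils::combn(length(proteins), 2L))
  }
  rows <- list()
  if (nrow(cand)) {
    aa <- Biostrings::AAStringSet(proteins)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1L]; j <- cand[r, 2L]
      al <- Biostrings::pairwiseAlignment(aa[[i]], aa[[j]], type = "local",
                                          substitutionMatrix = "BLOSUM62",
                                          gapOpening = 10, gapExtension = 1)
      wid <- Biostrings::nchar(al)
      if (!wid) next
      identity <- Biostrings::nmatch(al) / wid
      short_len <- min(nchar(proteins[[i]]), nchar(proteins[[j]]))
      span <- min(Biostrings::width(Biostrings::pattern(al)),
                  Biostrings::width(Biostrings::subject(al)))
      coverage <- span / short_len
      if (identity >= params$min_identity && coverage >= params$min_coverage) {
        ga <- ids[i]; gb <- ids[j]
        if (ga > gb) { tmp <- ga; ga <- gb; gb <- tmp }
        rows[[length(rows) + 1L]] <-
          data.frame(gene_a = ga, gene_b = gb, identity = identity,
                     coverage = coverage, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(), gene_b = character(),
               identity = numeric(), coverage = numeric(),
               stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percent-duplicated statistic
#'
#' A gene counts as duplicated iff it participates in at least one paralog
#' pair whose members are both eligible (protein strictly longer than the
#' length cutoff) and is itself eligible; the denominator is the number of
#' eligible genes.  `percent_duplicated = 100 * n_duplicated / n_eligible`.
#'
#' @param genes a [gene_table()] (ranks not required).
#' @param pairs paralog pairs from [find_paralog_pairs()].
#' @param params a [duplication_params()].
#' @return list of class `"duplication_summary"`: `n_annotated`,
#'   `n_eligible`, `n_duplicated`, `percent_duplicated`.
#' @export
percent_duplicated <- function(genes, pairs, params = duplication_params()) {
  unknown <- setdiff(c(pairs$gene_a, pairs$gene_b), genes$gene_id)
  if (length(unknown))
    stop("pair gene id not in gene table: ", unknown[1L])
  eligible <- genes$gene_id[genes$protein_length > params$min_protein_length_aa]
  ok <- pairs$gene_a %in% eligible & pairs$gene_b %in% eligible
  dup <- unique(c(pairs$gene_a[ok], pairs$gene_b[ok]))
  structure(list(
    n_annotated = nrow(genes),
    n_eligible = length(eligible),
    n_duplicated = length(dup),
    percent_duplicated = if (length(eligible))
      100 * length(dup) / length(eligible) else 0
  ), class = "duplication_summary")
}

#' @export
print.duplication_summary <- function(x, ...) {
  cat(sprintf("Duplicated genes: %d / %d eligible (of %d annotated) = %.1f%%\n",
              x$n_duplicated, x$n_eligible, x$n_annotated,
              x$percent_duplicated))
  invisible(x)
}

#' Classify paralog pairs as tandem or dispersed
#'
#' A pair is tandem iff both genes lie on the same scaffold with at most
#' `tandem_max_intervening` genes between them (in rank space); otherwise
#' dispersed.
#'
#' @param pairs paralog pairs ([find_paralog_pairs()]).
#' @param genes a ranked [gene_table()].
#' @param params a [duplication_params()].
#' @return `pairs` with an added `class` column (`tandem`/`dispersed`).
#' @export
classify_tandem <- function(pairs, genes, params = duplication_params()) {
  ia <- match(pairs$gene_a, genes$gene_id)
  ib <- match(pairs$gene_b, genes$gene_id)
  if (anyNA(ia) || anyNA(ib)) stop("pair gene id not in gene table")
  if (anyNA(genes$rank[ia]) || anyNA(genes$rank[ib]))
    stop("genes must be ranked first (rank_genes)")
  same <- genes$scaffold[ia] == genes$scaffold[ib]
  interv <- abs(genes$rank[ia] - genes$rank[ib]) - 1L
  pairs$class <- ifelse(same & interv <= params$tandem_max_intervening,
                        "tandem", "dispersed")
  pairs
}
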