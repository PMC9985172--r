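#' Presence/identity thresholds for gametolog classification
#'
#' @param min_identity minimum alignment identity for a sequence to count
#'   as present in a genome (default 0.95).
#' @param min_coverage minimum aligned fraction of the query (default 0.80).
#' @param same_gametolog_identity identity at or above which the female and
#'   male transcriptome sequences are called the same gametolog
#'   (default 0.99).
#' @param autosomal_scaffold_identity identity above which opposite-sex
#'   scaffolds are considered autosomal counterparts (default 0.99).
#' @return list of class `"presence_params"`.
#' @export
presence_params <- function(min_identity = 0.95, min_coverage = 0.80,
                            same_gametolog_identity = 0.99,
                            autosomal_scaffold_identity = 0.99) {
  stopifnot(min_identity > 0, min_identity <= 1, min_coverage > 0,
            min_coverage <= 1, same_gametolog_identity > 0,
            same_gametolog_identity <= 1)
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 same_gametolog_identity = same_gametolog_identity,
                 autosomal_scaffold_identity = autosomal_scaffold_identity),
            class = "presence_params")
}

#' Neighbor-joining tree from aligned sequences
#'
#' Deterministic stand-in for Bayesian gene-tree inference: K2P distances
#' ([ape::dist.dna()]) followed by neighbor joining ([ape::nj()]),
#' unrooted.  Requires an equal-length alignment of at least four
#' sequences.  An all-identical alignment cannot be resolved; a star tree
#' is returned with attribute `unresolved = TRUE`.  Users with externally
#' computed (e.g. Bayesian) trees can pass them straight to
#' [classify_phylo()].
#'
#' @param seqs named character vector of aligned nucleotide sequences.
#' @return An unrooted [ape] `phylo` tree.
#' @export
build_tree <- function(seqs) {
  if (length(seqs) < 4L) stop("need at least 4 sequences")
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must be aligned to equal length")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  mat <- do.call(rbind, strsplit(tolower(seqs), "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  d <- ape::dist.dna(ape::as.DNAbin(mat), model = "K80",
                     pairwise.deletion = TRUE)
  if (all(d == 0)) {
    tree <- ape::stree(length(seqs), type = "star", tip.label = names(seqs))
    tree$edge.length <- rep(0, nrow(tree$edge))
    attr(tree, "unresolved") <- TRUE
    return(tree)
  }
  tree <- ape::unroot(ape::nj(d))
  attr(tree, "unresolved") <- FALSE
  tree
}

# which tip is paired with `tip` across the internal edge of an unrooted
# binary quartet; NULL when the quartet is unresolved
.quartet_partner <- function(tree, tips, tip) {
  t4 <- ape::unroot(ape::keep.tip(tree, tips))
  if (t4$Nnode < 2L) return(NULL)
  ntip <- 4L
  internal <- t4$edge[, 1L] > ntip & t4$edge[, 2L] > ntip
  if (sum(internal) != 1L) return(NULL)
  support <- if (!is.null(t4$edge.length)) t4$edge.length[internal] else NA_real_
  # tips hanging off one of the two internal nodes form one side
  node <- t4$edge[internal, 2L]
  side <- t4$tip.label[t4$edge[t4$edge[, 1L] == node & t4$edge[, 2L] <= ntip, 2L]]
  if (!(tip %in% side)) side <- setdiff(t4$tip.label, side)
  list(partner = setdiff(side, tip), support = support)
}

#' Phylogenetic U/V/O classification of a gametolog ortholog
#'
#' Applies the quartet rule to an unrooted tree containing the query
#' ortholog, the two reference gametologs and an outgroup: the query is
#' labelled `U` when it pairs with the U gametolog across the internal
#' split, `V` when it pairs with the V gametolog, and `O` (outgroup
#' relationship) when the two reference gametologs pair with each other.
#' The result is invariant to tip order and rooting.  For an unresolved
#' quartet the closest-pair rule on tree distances is used as fallback and
#' the call is flagged with `support = 0`.
#'
#' @param tree a `phylo` tree containing the four tips (extra tips are
#'   ignored).
#' @param lc,mp_u,mp_v,outgroup tip labels of the query ortholog, the U
#'   and V gametologs, and the outgroup.
#' @return list with `label` in `{U, V, O}`, `support` (internal branch
#'   length), `resolved` (logical).
#' @export
classify_phylo <- function(tree, lc, mp_u, mp_v, outgroup) {
  tips <- c(lc, mp_u, mp_v, outgroup)
  if (!all(tips %in% tree$tip.label))
    stop("tree is missing tip(s): ",
         paste(setdiff(tips, tree$tip.label), collapse = ", "))
  q <- .quartet_partner(tree, tips, lc)
  if (!is.null(q) && isTRUE(q$support > 0)) {
    label <- c("U", "V", "O")[match(q$partner, c(mp_u, mp_v, outgroup))]
    return(list(label = label, support = q$support, resolved = TRUE))
  }
  # unresolved: fall back to the closest-pair rule on path distances
  dm <- ape::cophenetic.phylo(ape::keep.tip(tree, tips))
  label <- .closest_pair_label(dm[lc, mp_u], dm[lc, mp_v], dm[mp_u, mp_v])
  list(label = label, support = 0, resolved = FALSE)
}

.closest_pair_label <- function(d_lu, d_lv, d_uv) {
  if (d_uv < min(d_lu, d_lv)) "O" else if (d_lu <= d_lv) "U" else "V"
}

#' Closest-pair U/V/O classification from sequences
#'
#' Outgroup-free fallback mode: compares the K2P distances query-to-U,
#' query-to-V and U-to-V.  When the two reference gametologs are closer to
#' each other than either is to the query, the query has an outgroup
#' relationship (`O`); otherwise it is labelled after the nearer
#' gametolog.
#'
#' @param lc_seq,mp_u_seq,mp_v_seq aligned nucleotide sequences.
#' @return list with `label` in `{U, V, O}`.
#' @export
classify_phylo_distances <- function(lc_seq, mp_u_seq, mp_v_seq) {
  d_lu <- estimate_divergence(lc_seq, mp_u_seq)
  d_lv <- estimate_divergence(lc_seq, mp_v_seq)
  d_uv <- estimate_divergence(mp_u_seq, mp_v_seq)
  list(label = .closest_pair_label(d_lu, d_lv, d_uv))
}

#' Search a genome for a query sequence
#'
#' Seed-and-extend presence test: exact 12-mer seeds sampled along the
#' query are matched against every scaffold; each seed hit nominates a
#' window that is locally aligned to the query.  The query is present
#' when some window reaches `min_identity` over at least `min_coverage`
#' of the query length.
#'
#' @param query nucleotide sequence (character).
#' @param genome named character vector of scaffold sequences.
#' @param params a [presence_params()].
#' @return list with `present`, and when present `scaffold`, `identity`,
#'   `coverage`.
#' @export
find_in_genome <- function(query, genome, params = presence_params()) {
  if (!length(genome) || !sum(nchar(genome))) stop("empty genome")
  k <- 12L
  qlen <- nchar(query)
  if (qlen < k) stop("query shorter than seed length")
  starts <- unique(c(seq(1L, qlen - k + 1L, by = 50L), qlen - k + 1L))
  # one subject: scaffolds joined by N runs (seeds are N-free, so no
  # spurious cross-boundary matches)
  gap <- 20L
  lens <- nchar(genome)
  offsets <- c(0L, cumsum(lens + gap))[seq_along(genome)]
  big <- Biostrings::DNAString(paste(genome, collapse = strrep("N", gap)))
  tried <- character()
  for (si in seq_along(starts)) {
    seed <- substr(query, starts[si], starts[si] + k - 1L)
    hs <- Biostrings::start(Biostrings::matchPattern(seed, big))
    for (h in hs) {
      sc <- findInterval(h, offsets + 1L)
      est <- h - offsets[sc] - (starts[si] - 1L)
      key <- paste0(sc, ":", round(est / 100))
      if (key %in% tried) next
      tried <- c(tried, key)
      win_s <- max(1L, est - 50L)
      win_e <- min(lens[sc], est + qlen + 50L)
      window <- substr(genome[[sc]], win_s, win_e)
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(query), Biostrings::DNAString(window),
        type = "local", substitutionMatrix = .nuc_mat(),
        gapOpening = 5, gapExtension = 2)
      wid <- Biostrings::nchar(al)
      if (!wid) next
      identity <- Biostrings::nmatch(al) / wid
      coverage <- Biostrings::width(Biostrings::pattern(al)) / qlen
      if (identity >= params$min_identity &&
          coverage >= params$min_coverage) {
        return(list(present = TRUE, scaffold = names(genome)[sc],
                    identity = identity, coverage = coverage))
      }
    }
  }
  list(present = FALSE)
}

#' Genomic U-linked/V-linked/autosomal classification
#'
#' A gene residing on the U or V chromosome must be present only in the
#' female or male genome, respectively; presence in both implies an
#' autosomal (or pseudoautosomal) location.  Presence is decided by
#' [find_in_genome()].
#'
#' @param lc_seq query sequence.
#' @param female_genome,male_genome named character vectors of scaffolds.
#' @param params a [presence_params()].
#' @return One of `"U-linked"`, `"V-linked"`, `"autosomal"`, `"unplaced"`.
#' @export
classify_genomic <- function(lc_seq, female_genome, male_genome,
                             params = presence_params()) {
  in_f <- find_in_genome(lc_seq, female_genome, params)$present
  in_m <- find_in_genome(lc_seq, male_genome, params)$present
  if (in_f && in_m) "autosomal"
  else if (in_f) "U-linked"
  else if (in_m) "V-linked"
  else "unplaced"
}

#' Same-gametolog call for a female/male sequence pair
#'
#' `TRUE` iff the two transcriptome sequences are at least
#' `same_gametolog_identity` identical over the aligned region - the
#' situation marked "1" in gametolog tables, indicating that both sexes
#' express the same (hence autosomal or translocated) copy.
#'
#' @param female_seq,male_seq nucleotide sequences.
#' @param params a [presence_params()].
#' @return logical.
#' @export
same_gametolog <- function(female_seq, male_seq,
                           params = presence_params()) {
  alignment_identity(female_seq, male_seq) >= params$same_gametolog_identity
}

#' Percent identity of two opposite-sex scaffolds
#'
#' Global alignment identity with indel columns counted as mismatches,
#' in percent.  Autosomal scaffolds of the two sexes are expected to be
#' >99% identical; sex-specific scaffolds have no counterpart.
#'
#' @param scaffold_f,scaffold_m scaffold sequences.
#' @return identity in percent.
#' @export
scaffold_identity <- function(scaffold_f, scaffold_m) {
  100 * alignment_identity(scaffold_f, scaffold_m)
}

#' Infer U-to-autosome translocations
#'
#' A locus is a translocation candidate iff its ortholog is
#' phylogenetically U-descended, the sequence is found in both sex
#' genomes (autosomal), and no V-descended ortholog is detectable in the
#' male genome - the predicted signature of a U fragment translocated to
#' an autosome with subsequent loss of the corresponding V gametologs
#' (Muller's ratchet).  `O` loci are excluded (strict rule).
#'
#' @param records per-locus data.frame with columns `locus`,
#'   `phylo_label` (of the female-genome copy), `genomic_label`,
#'   `v_present` (logical: any V-descended sequence in the male genome).
#' @return `records` with added logical `translocation_candidate`.
#' @export
infer_translocation <- function(records) {
  if (!nrow(records)) stop("no labelled loci")
  records$translocation_candidate <-
    records$phylo_label == "U" &
    records$genomic_label == "autosomal" &
    !records$v_present
  records
}

#' End-to-end classification of simulated gametolog loci
#'
#' Runs the full classification pipeline on the output of
#' [simulate_sex_loci()]: for every sampled ortholog sequence a quartet
#' tree (query, U and V gametologs, outgroup) is built and classified,
#' genome presence is tested against both sex genomes, per-locus
#' same-gametolog flags are computed, and translocation candidates are
#' inferred.
#'
#' @param sim result of [simulate_sex_loci()].
#' @param params a [presence_params()].
#' @return list with `sequences` (one row per classified sequence:
#'   `locus`, `seq_id`, `sex`, `phylo_label`, `support`, `genomic_label`),
#'   `loci` (per-locus summary with `same_gametolog` and
#'   `translocation_candidate`).
#' @export
classify_gametolog_loci <- function(sim, params = presence_params()) {
  seq_rows <- list()
  for (loc in sim$loci) {
    for (side in c("lc_f", "lc_m")) {
      q <- loc[[side]]
      if (is.null(q) || is.na(q)) next
      tips <- c(lc = "query", mp_u = "mp_u", mp_v = "mp_v", out = "outgroup")
      tree <- build_tree(c(query = q, mp_u = loc$mp_u, mp_v = loc$mp_v,
                           outgroup = loc$outgroup))
      ph <- classify_phylo(tree, "query", "mp_u", "mp_v", "outgroup")
      gl <- classify_genomic(q, sim$female_genome, sim$male_genome, params)
      seq_rows[[length(seq_rows) + 1L]] <- data.frame(
        locus = loc$name,
        seq_id = paste0(loc$name, if (side == "lc_f") "_lcF" else "_lcM"),
        sex = if (side == "lc_f") "female" else "male",
        phylo_label = ph$label, support = ph$support, genomic_label = gl,
        stringsAsFactors = FALSE)
    }
  }
  sequences <- do.call(rbind, seq_rows)
  loci <- lapply(sim$loci, function(loc) {
    rows <- sequences[sequences$locus == loc$name, ]
    fem <- rows[rows$sex == "female", ]
    mal <- rows[rows$sex == "male", ]
    v_present <- any(rows$phylo_label == "V" &
                       rows$genomic_label %in% c("V-linked", "autosomal"))
    data.frame(
      locus = loc$name,
      phylo_label = if (nrow(fem)) fem$phylo_label[1L] else NA_character_,
      genomic_label = if (nrow(fem)) fem$genomic_label[1L] else NA_character_,
      v_present = v_present,
      same_gametolog = if (nrow(fem) && nrow(mal))
        same_gametolog(loc$lc_f, loc$lc_m, params) else NA,
      stringsAsFactors = FALSE)
  })
  loci <- do.call(rbind, loci)
  rownames(loci) <- NULL
  loci <- infer_translocation(loci)
  list(sequences = sequences, loci = loci)
}
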