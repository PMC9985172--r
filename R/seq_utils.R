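# Internal sequence utilities shared across modules.

.DNA <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(.DNA, n, replace = TRUE), collapse = "")
}

# expected JC distance d (substitutions/site) -> per-site substitution prob
jc_site_prob <- function(d) 0.75 * (1 - exp(-4 * d / 3))

# Mutate a sequence under Jukes-Cantor to expected distance d.
# Each site substitutes with probability 3/4*(1-exp(-4d/3)); the replacement
# is uniform over the three other bases.  No indels.
mutate_jc <- function(seq, d) {
  if (d < 0) stop("negative divergence")
  if (d == 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(v)) < jc_site_prob(d))
  if (length(hit)) {
    cur <- match(v[hit], .DNA)
    off <- sample.int(3L, length(hit), replace = TRUE)
    v[hit] <- .DNA[((cur - 1L + off) %% 4L) + 1L]
  }
  paste(v, collapse = "")
}

translate_cds <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3L
  as.character(Biostrings::translate(Biostrings::DNAString(substr(seq, 1L, n)),
                                     if.fuzzy.codon = "X"))
}

.nuc_mat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = TRUE)
}

# Global nucleotide alignment; returns the two aligned strings.
align_global <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                      Biostrings::DNAString(b),
                                      type = "global",
                                      substitutionMatrix = .nuc_mat(),
                                      gapOpening = 5, gapExtension = 2)
  c(as.character(Biostrings::alignedPattern(al)),
    as.character(Biostrings::alignedSubject(al)))
}

# Fraction identical over all alignment columns; indel columns count as
# mismatches.  This is the identity definition used for scaffold
# comparison, same-gametolog calls and LTR pairs.
alignment_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (a == b) return(1)
  al <- align_global(a, b)
  v1 <- strsplit(al[1L], "", fixed = TRUE)[[1L]]
  v2 <- strsplit(al[2L], "", fixed = TRUE)[[1L]]
  mean(v1 == v2 & v1 != "-")
}
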