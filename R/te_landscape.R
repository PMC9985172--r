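#' Divergence of a repeat copy from its family consensus
#'
#' Globally aligns the copy to the consensus and computes the Kimura
#' 2-parameter distance (transitions and transversions weighted
#' separately), expressed in percent.  Alignment columns containing an
#' indel are excluded from the distance.  A plain p-distance is available
#' via `metric = "p"`.  Saturated comparisons, where the K2P logarithms
#' are undefined, raise an error naming the copy.
#'
#' @param copy_seq,consensus_seq nucleotide sequences (character strings).
#' @param metric `"K2P"` (default) or `"p"`.
#' @return Divergence in percent (>= 0).
#' @export
estimate_divergence <- function(copy_seq, consensus_seq,
                                metric = c("K2P", "p")) {
  metric <- match.arg(metric)
  if (copy_seq == consensus_seq) return(0)
  al <- align_global(copy_seq, consensus_seq)
  v1 <- strsplit(al[1L], "", fixed = TRUE)[[1L]]
  v2 <- strsplit(al[2L], "", fixed = TRUE)[[1L]]
  keep <- v1 != "-" & v2 != "-"
  v1 <- v1[keep]; v2 <- v2[keep]
  n <- length(v1)
  if (!n) stop("no aligned columns between copy and consensus")
  diff <- v1 != v2
  if (metric == "p") return(100 * mean(diff))
  purine <- c("A", "G")
  ts <- diff & ((v1 %in% purine) == (v2 %in% purine))
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0)
    stop("K2P distance undefined (saturated comparison)")
  100 * (-0.5 * log(a1) - 0.25 * log(a2))
}

#' Bin repeat abundance by divergence
#'
#' Builds the repeat landscape: summed hit length (bp) per half-open
#' divergence bin `[i*w, (i+1)*w)` and per superfamily.  Bin totals are
#' exact sums of hit lengths, so the landscape conserves total masked bp.
#'
#' @param hits repeat hit data.frame ([read_repeatmasker_out()]) with
#'   `divergence_pct` set on every row.
#' @param bin_width bin width in percent (default 1).
#' @return An object of class `"te_landscape"`: list with `abundance`
#'   (matrix, bins x superfamilies, bp), `breaks`, `bin_width`.
#' @export
bin_landscape <- function(hits, bin_width = 1.0) {
  if (anyNA(hits$divergence_pct))
    stop("divergence_pct must be set on all hits")
  if (any(hits$divergence_pct < 0)) stop("negative divergence")
  if (!nrow(hits)) {
    ab <- matrix(0, 0L, 0L)
    return(structure(list(abundance = ab, breaks = numeric(),
                          bin_width = bin_width), class = "te_landscape"))
  }
  bin <- floor(hits$divergence_pct / bin_width)
  nbin <- max(bin) + 1L
  sf <- sort(unique(hits$superfamily))
  ab <- matrix(0, nrow = nbin, ncol = length(sf),
               dimnames = list(sprintf("[%g,%g)",
                                       (seq_len(nbin) - 1L) * bin_width,
                                       seq_len(nbin) * bin_width), sf))
  len <- hits$end - hits$start
  for (i in seq_len(nrow(hits)))
    ab[bin[i] + 1L, hits$superfamily[i]] <-
      ab[bin[i] + 1L, hits$superfamily[i]] + len[i]
  structure(list(abundance = ab, breaks = (0:nbin) * bin_width,
                 bin_width = bin_width), class = "te_landscape")
}

#' @export
print.te_landscape <- function(x, ...) {
  cat(sprintf("TE landscape: %d bin(s) of %g%%, %d superfamil%s, %.3f Mb total\n",
              nrow(x$abundance), x$bin_width, ncol(x$abundance),
              if (ncol(x$abundance) == 1L) "y" else "ies",
              sum(x$abundance) / 1e6))
  invisible(x)
}

#' Per-family divergence densities for the largest families
#'
#' Ranks families by total masked bp (genome-size contribution, not copy
#' number) and returns a bp-weighted Gaussian kernel density of divergence
#' for each of the `top_k` largest.
#'
#' @param hits repeat hits with `divergence_pct` and `family` set.
#' @param top_k number of families to keep (default 15).
#' @return list with `ranking` (data.frame `family`, `total_bp`) and
#'   `densities` (named list of [stats::density()] objects).
#' @export
family_densities <- function(hits, top_k = 15L) {
  if (top_k < 1L) stop("top_k must be >= 1")
  if (!nrow(hits)) stop("no repeat hits")
  len <- hits$end - hits$start
  tot <- sort(tapply(len, hits$family, sum), decreasing = TRUE)
  fams <- names(tot)[seq_len(min(top_k, length(tot)))]
  dens <- lapply(fams, function(f) {
    i <- hits$family == f
    .weighted_kde(hits$divergence_pct[i], len[i] / sum(len[i]))
  })
  list(ranking = data.frame(family = names(tot), total_bp = as.numeric(tot),
                            stringsAsFactors = FALSE),
       densities = setNames(dens, fams))
}

# Weighted Gaussian-kernel density evaluated exactly on a wide, fine grid
# (no FFT binning), so the returned curve integrates to 1 up to the tiny
# mass beyond `cut` bandwidths.
.weighted_kde <- function(x, w, n = 4096L, cut = 6) {
  bw <- stats::bw.nrd0(x)
  grid <- seq(min(x) - cut * bw, max(x) + cut * bw, length.out = n)
  y <- numeric(n)
  for (idx in split(seq_along(x), ceiling(seq_along(x) / 500))) {
    y <- y + colSums(w[idx] *
                       stats::dnorm(outer(x[idx], grid, "-"), sd = bw))
  }
  structure(list(x = grid, y = y, bw = bw, n = length(x),
                 call = match.call(), data.name = "x", has.na = FALSE),
            class = "density")
}

# peak prominence on a density grid: height above the higher of the two
# valley floors toward the nearest higher terrain on each side
.peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    lmin <- y[p]; i <- p
    while (i > 1L) { i <- i - 1L; if (y[i] > y[p]) break; lmin <- min(lmin, y[i]) }
    if (y[i] <= y[p]) lmin <- min(y[seq_len(p)])  # no higher terrain left
    rmin <- y[p]; i <- p; n <- length(y)
    while (i < n) { i <- i + 1L; if (y[i] > y[p]) break; rmin <- min(rmin, y[i]) }
    if (y[i] <= y[p]) rmin <- min(y[p:n])
    key <- if (any(y > y[p])) max(lmin, rmin) else min(y)
    y[p] - key
  }, 0)
}

#' Detect TE amplification bursts
#'
#' Operationalises visual peak identification in a divergence landscape:
#' bursts are the local maxima of a bp-weighted Gaussian kernel density
#' (Silverman's rule-of-thumb bandwidth) whose prominence is at least
#' `min_prominence` times the global density maximum.  Requires at least
#' 30 copies; with fewer, mode inference is unreliable and an error is
#' raised.
#'
#' @param divergences per-copy divergence values (percent).
#' @param weights_bp per-copy weights, typically copy length in bp
#'   (default: equal weights).
#' @param min_prominence prominence threshold as a fraction of the global
#'   maximum (default 0.1).
#' @return data.frame of modes, sorted by divergence: `divergence_pct`,
#'   `height`, `prominence`.
#' @export
detect_bursts <- function(divergences, weights_bp = NULL,
                          min_prominence = 0.1) {
  n <- length(divergences)
  if (n < 30L)
    stop("burst detection needs >= 30 copies (got ", n,
         "); too few for mode inference")
  if (is.null(weights_bp)) weights_bp <- rep(1, n)
  d <- density(divergences, weights = weights_bp / sum(weights_bp),
               bw = "nrd0", n = 512L)
  y <- d$y
  k <- length(y)
  is_peak <- c(FALSE, y[2:(k - 1L)] > y[1:(k - 2L)] &
                 y[2:(k - 1L)] >= y[3:k], FALSE)
  peaks <- which(is_peak)
  if (!length(peaks)) peaks <- which.max(y)
  prom <- .peak_prominence(y, peaks)
  keep <- prom >= min_prominence * max(y)
  out <- data.frame(divergence_pct = d$x[peaks[keep]],
                    height = y[peaks[keep]], prominence = prom[keep])
  out[order(out$divergence_pct), , drop = FALSE]
}

#' Weighted sample skewness
#'
#' Adjusted Fisher-Pearson standardized third moment, with optional bp
#' weights; used to compare the shape of divergence distributions between
#' species (a distribution skewed toward low divergence indicates recent
#' TE activity).
#'
#' @param x sample values.
#' @param weights_bp optional weights (e.g. copy length in bp).
#' @return Skewness (dimensionless).
#' @export
skewness_weighted <- function(x, weights_bp = NULL) {
  n <- length(x)
  if (n < 3L) stop("skewness needs n >= 3")
  w <- if (is.null(weights_bp)) rep(1, n) else weights_bp
  w <- w / sum(w)
  mu <- sum(w * x)
  m2 <- sum(w * (x - mu)^2)
  if (m2 == 0) stop("zero variance")
  m3 <- sum(w * (x - mu)^3)
  (m3 / m2^1.5) * sqrt(n * (n - 1)) / (n - 2)
}

#' Call full-length LTR retrotransposons
#'
#' An element is full length - hence potentially transposition-competent -
#' iff both long terminal repeats are present, each at least `min_ltr_len`
#' bp, and their pairwise identity (global alignment, indels as
#' mismatches) is at least `min_ltr_identity`.  Elements with exactly one
#' LTR are classified `solo`; everything else is `truncated`.
#'
#' @param elements data.frame with columns `element_id`, `ltr5`, `ltr3`
#'   (nucleotide sequences, `NA` when absent).
#' @param min_ltr_identity minimum LTR pair identity (default 0.85).
#' @param min_ltr_len minimum LTR length in bp (default 100).
#' @return Input with added `ltr_identity` and `status` in
#'   `{full_length, solo, truncated}`.
#' @export
call_full_length <- function(elements, min_ltr_identity = 0.85,
                             min_ltr_len = 100L) {
  has5 <- !is.na(elements$ltr5) & nzchar(elements$ltr5)
  has3 <- !is.na(elements$ltr3) & nzchar(elements$ltr3)
  ident <- rep(NA_real_, nrow(elements))
  status <- rep("truncated", nrow(elements))
  status[xor(has5, has3)] <- "solo"
  for (i in which(has5 & has3)) {
    if (nchar(elements$ltr5[i]) < min_ltr_len ||
        nchar(elements$ltr3[i]) < min_ltr_len) next
    ident[i] <- alignment_identity(elements$ltr5[i], elements$ltr3[i])
    if (ident[i] >= min_ltr_identity) status[i] <- "full_length"
  }
  elements$ltr_identity <- ident
  elements$status <- status
  elements
}
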