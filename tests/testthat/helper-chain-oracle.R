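# Exhaustive-search oracle for block chaining: enumerates every valid chain
# by depth-first search, extracts the best (most anchors, then least total
# gap, then lexicographically smallest index sequence; '+' orientation
# preferred on exact ties) until the best falls below s.  Independent of
# the package's dynamic-programming implementation.

oracle_extract <- function(ra, rb, m) {
  n <- length(ra)
  best <- NULL
  better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    if (a$len != b$len) return(a$len > b$len)
    if (a$gap != b$gap) return(a$gap < b$gap)
    la <- a$chain; lb <- b$chain
    for (i in seq_len(min(length(la), length(lb))))
      if (la[i] != lb[i]) return(la[i] < lb[i])
    FALSE
  }
  for (dir in c(1L, -1L)) {
    dfs <- function(chain, gap) {
      cand <- list(len = length(chain), gap = gap, chain = chain, dir = dir)
      if (better(cand, best)) best <<- cand
      last <- chain[length(chain)]
      for (j in seq_len(n)) {
        if (j <= last) next
        dA <- ra[j] - ra[last]
        if (dA < 1 || dA > m + 1) next
        dB <- dir * (rb[j] - rb[last])
        if (dB < 1 || dB > m + 1) next
        dfs(c(chain, j), gap + (dA - 1) + (dB - 1))
      }
    }
    for (i in seq_len(n)) dfs(i, 0)
  }
  best
}

oracle_chained_count <- function(rank_a, rank_b, s, m) {
  ord <- order(rank_a, rank_b)
  ra <- rank_a[ord]
  rb <- rank_b[ord]
  total <- 0L
  repeat {
    if (!length(ra)) break
    best <- oracle_extract(ra, rb, m)
    if (best$len < s) break
    total <- total + best$len
    ra <- ra[-best$chain]
    rb <- rb[-best$chain]
  }
  total
}

random_rank_instance <- function(max_n = 12L, rank_space = 0:25) {
  n <- sample(4:max_n, 1L)
  list(rank_a = sort(sample(rank_space, n)),
       rank_b = sample(sort(sample(rank_space, n))))
}
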