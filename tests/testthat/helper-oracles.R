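# Independent oracles used across the suite.  Each is deliberately naive
# (exponential recursion, quadratic sweeps, exhaustive enumeration) and
# shares no code with the package implementation it checks.

# Levenshtein by the textbook recursive definition (feasible for length <= 6)
lev_recursive <- function(a, b) {
  if (!length(a)) return(length(b))
  if (!length(b)) return(length(a))
  min(
    lev_recursive(a[-1], b) + 1,
    lev_recursive(a, b[-1]) + 1,
    lev_recursive(a[-1], b[-1]) + (a[1] != b[1])
  )
}

# Levenshtein via character-level adist after mapping tokens to single chars
lev_adist <- function(a, b) {
  alphabet <- unique(c(a, b))
  stopifnot(length(alphabet) <= 52)
  chars <- c(letters, LETTERS)[seq_along(alphabet)]
  enc <- function(x) paste(chars[match(x, alphabet)], collapse = "")
  as.integer(utils::adist(enc(a), enc(b)))
}

# maximum number of concurrent half-open intervals, by point probing at
# every start point (quadratic)
overlap_oracle <- function(start, end) {
  max(vapply(start, function(t) sum(start <= t & t < end), 0L))
}

# exhaustive DFS over a thresholded probability matrix: all acyclic paths
# from any of `starts` to any of `ends`
dfs_paths_oracle <- function(prob, starts, ends, thr) {
  states <- rownames(prob)
  out <- list()
  recurse <- function(path) {
    cur <- path[length(path)]
    if (cur %in% ends) {
      out[[length(out) + 1]] <<- path
      return(invisible())
    }
    for (s in states) {
      if (s %in% path) next
      if (prob[cur, s] >= thr && prob[cur, s] > 0) recurse(c(path, s))
    }
  }
  for (s in intersect(starts, states)) recurse(s)
  out
}

# brute-force single-linkage agglomeration: repeatedly merge the two
# clusters with minimum single-link distance, recording merge heights
single_linkage_oracle <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      link <- min(d[clusters[[i]], clusters[[j]]])
      if (link < best[1]) best <- c(link, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  sort(heights)
}

# two-sided Freeman-Halton p for a 2x2 table by direct hypergeometric
# enumeration over all tables with the observed margins
fisher_2x2_oracle <- function(tab) {
  r <- rowSums(tab); c1 <- colSums(tab)[1]
  ks <- max(0, c1 - r[2]):min(r[1], c1)
  probs <- dhyper(ks, r[1], r[2], c1)
  p_obs <- dhyper(tab[1, 1], r[1], r[2], c1)
  sum(probs[probs <= p_obs + 1e-12])
}

# random token sequence over a small alphabet
random_seq <- function(len, alphabet = c("a", "b", "c", "d")) {
  sample(alphabet, len, replace = TRUE)
}
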