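test_that("token-level Levenshtein matches independent oracles on short pairs", {
  expect_equal(levenshtein("14a-13b-12-4b", "17-14a-13b-12-4b"), 1L)
  expect_equal(levenshtein("15-14a", "15-14a"), 0L)
  set.seed(101)
  for (i in 1:40) {
    a <- random_seq(sample(0:6, 1))
    b <- random_seq(sample(0:6, 1))
    got <- levenshtein(a, b)
    expect_identical(got, as.integer(lev_recursive(a, b)))
    expect_identical(got, lev_adist(a, b))
  }
})

test_that("Levenshtein is a metric on token sequences", {
  set.seed(202)
  seqs <- replicate(12, random_seq(sample(1:8, 1)), simplify = FALSE)
  n <- length(seqs)
  d <- matrix(0L, n, n)
  for (i in 1:n) for (j in 1:n) d[i, j] <- levenshtein(seqs[[i]], seqs[[j]])
  expect_true(all(d == t(d)))                       # symmetry
  expect_true(all(diag(d) == 0))                    # identity
  for (i in 1:n) for (j in 1:n) {
    if (i != j && identical(seqs[[i]], seqs[[j]])) next
    expect_lte(d[i, j], max(length(seqs[[i]]), length(seqs[[j]])))
    for (k in 1:n) expect_lte(d[i, j], d[i, k] + d[k, j])  # triangle
  }
})

test_that("the set median is the member minimizing summed distance", {
  s <- c("a", "b", "c"); t_ <- c("a", "b", "d")
  res <- set_median(list(s, s, t_))
  expect_equal(res$median$labels, s)
  expect_equal(res$summed_distance, 1L)
  expect_equal(res$source, "set_median")

  single <- set_median(list(c("x", "y")))
  expect_equal(single$summed_distance, 0L)

  expect_error(set_median(list()), "empty")

  # brute-force oracle on random sets
  set.seed(303)
  for (rep in 1:10) {
    seqs <- replicate(sample(3:8, 1), random_seq(sample(2:6, 1)),
                      simplify = FALSE)
    res <- set_median(seqs)
    sums <- vapply(seqs, function(cand)
      sum(vapply(seqs, lev_recursive, 0, b = cand)), 0)
    expect_equal(res$summed_distance, as.integer(min(sums)))
  }
})

test_that("set-median ties break by length then token order, deterministically", {
  # both members are medians (summed distance 1); the shorter wins; among
  # equal lengths the lexicographically smaller token sequence wins
  res <- set_median(list(c("b", "a"), c("b")))
  expect_equal(res$median$labels, "b")
  res2 <- set_median(list(c("b", "z"), c("a", "z")))
  expect_equal(res2$median$labels, c("a", "z"))
})

test_that("Kohonen search keeps the set median when no substitution improves", {
  # pairwise LD 1; member median summed distance 2; any substitution at
  # position 2 yields another member (still 2): no strict improvement
  seqs <- list(c("a", "b"), c("a", "c"), c("a", "d"))
  km <- kohonen_median(seqs)
  expect_equal(km$source, "set_median")
  expect_equal(km$summed_distance, 2L)

  # exhaustive check: no single substitution from the median beats it
  sm <- set_median(seqs)
  alphabet <- unique(unlist(seqs))
  for (pos in seq_along(sm$median$labels)) for (tok in alphabet) {
    cand <- sm$median$labels; cand[pos] <- tok
    s <- sum(vapply(seqs, lev_recursive, 0, b = cand))
    expect_gte(s, sm$summed_distance)
  }
})

test_that("Kohonen median finds a strictly better non-member string", {
  # members are one substitution away (in different positions) from an
  # absent center a-b-c: the center beats every member
  seqs <- list(c("x", "b", "c"), c("a", "y", "c"), c("a", "b", "z"))
  sm <- set_median(seqs)
  expect_equal(sm$summed_distance, 4L)
  km <- kohonen_median(seqs, sm)
  expect_equal(km$source, "kohonen_median")
  expect_equal(km$median$labels, c("a", "b", "c"))
  expect_equal(km$summed_distance, 3L)
  # brute force over the full substitution neighborhood of the set median
  alphabet <- unique(unlist(seqs))
  best <- sm$summed_distance
  for (pos in 1:3) for (tok in alphabet) {
    cand <- sm$median$labels; cand[pos] <- tok
    best <- min(best, sum(vapply(seqs, lev_recursive, 0, b = cand)))
  }
  expect_equal(km$summed_distance, as.integer(best))
  # and never worse than the set median on random sets
  set.seed(404)
  for (rep in 1:8) {
    rs <- replicate(5, random_seq(sample(2:5, 1)), simplify = FALSE)
    expect_lte(kohonen_median(rs)$summed_distance,
               set_median(rs)$summed_distance)
  }
})

test_that("single-pass Kohonen mode stops after one substitution", {
  seqs <- list(c("x", "y", "c"), c("a", "b", "c"), c("a", "b", "c"),
               c("a", "b", "d"))
  sm <- set_median(seqs)
  one <- kohonen_median(seqs, sm, mode = "single_pass")
  full <- kohonen_median(seqs, sm, mode = "converge")
  expect_lte(full$summed_distance, one$summed_distance)
})

test_that("LSI normalizes against the longer sequence", {
  expect_equal(lsi("14a-13b-12-4b", "17-14a-13b-12-4b"), 0.8)
  expect_equal(lsi("a-b-c", "a-b-c"), 1)
  expect_equal(lsi(c("a", "b"), c("c", "d")), 0)
  expect_error(lsi(character(0), character(0)), "undefined")
  set.seed(505)
  for (i in 1:20) {
    a <- random_seq(sample(1:7, 1)); b <- random_seq(sample(1:7, 1))
    v <- lsi(a, b)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, lsi(b, a))
    expect_equal(lsi(a, a), 1)
  }
})

test_that("similarity matrices are symmetric with unit diagonal and match recomputation", {
  items <- list(x = c("a", "b", "c"), y = c("a", "b"), z = c("c", "b", "a"))
  s <- similarity_matrix(items)
  expect_equal(diag(unclass(s)), c(x = 1, y = 1, z = 1))
  expect_true(isSymmetric(unname(unclass(s))))
  for (i in 1:3) for (j in 1:3)
    expect_equal(s[i, j], lsi(items[[i]], items[[j]]))
  expect_error(similarity_matrix(list(a = "x", a = "y")), "duplicate")
  ident <- similarity_matrix(list(p = c("a", "b"), q = c("a", "b")))
  expect_true(all(unclass(ident) == 1))
})

test_that("single linkage matches a brute-force agglomeration oracle", {
  set.seed(606)
  for (rep in 1:8) {
    x <- matrix(runif(36), 6)
    d0 <- as.matrix(dist(x))
    tree <- single_linkage(d0)
    expect_equal(sort(tree$height), single_linkage_oracle(d0),
                 tolerance = 1e-12)
    expect_true(all(diff(tree$height) >= -1e-12))  # monotone heights
    # cluster count is non-increasing in the threshold
    hs <- seq(0, max(tree$height) + 0.1, length.out = 8)
    counts <- vapply(hs, function(h) max(cut_clusters(tree, h)), 0)
    expect_true(all(diff(counts) <= 0))
  }
  # three items at mutual distance zero collapse immediately
  z <- matrix(0, 3, 3)
  tz <- single_linkage(z)
  expect_equal(tz$height, c(0, 0))
  expect_equal(max(cut_clusters(tz, 0)), 1)
  expect_error(single_linkage(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("dendrograms export as Newick with height-difference branch lengths", {
  d <- as.dist(matrix(c(0, 0.2, 0.8, 0.2, 0, 0.9, 0.8, 0.9, 0), 3,
                      dimnames = list(c("p1", "p2", "p3"),
                                      c("p1", "p2", "p3"))))
  tree <- single_linkage(d)
  txt <- dendrogram_newick(tree)
  expect_match(txt, "^\\(")
  phy <- ape::read.tree(text = txt)
  expect_setequal(phy$tip.label, c("p1", "p2", "p3"))
})

test_that("Dice's index measures phrase sharing", {
  expect_equal(dice_similarity(c("a", "b"), c("a", "b")), 1)
  expect_equal(dice_similarity(c("a", "b"), c("c", "d")), 0)
  expect_equal(dice_similarity(c("a", "b", "c"), c("b", "c", "d")), 2 / 3)
  expect_equal(dice_similarity(c("a", "a", "b"), c("b")), 2 * 1 / (2 + 1))
  expect_error(dice_similarity(character(0), character(0)))
  # symmetry, and 1 only for equal sets
  set.seed(707)
  for (i in 1:15) {
    a <- unique(random_seq(sample(1:5, 1), letters[1:6]))
    b <- unique(random_seq(sample(1:5, 1), letters[1:6]))
    expect_equal(dice_similarity(a, b), dice_similarity(b, a))
    if (dice_similarity(a, b) == 1) expect_setequal(a, b)
  }
})

test_that("the minimum-transition filter keeps sequences with >= 4 transitions", {
  seqs <- list(c("a", "b", "c", "d", "e"),       # 4 transitions: kept
               c("a", "b", "c", "d"),            # 3 transitions: dropped
               c("a", "b", "c", "d", "e", "f"))
  kept <- filter_min_transitions(seqs, 4)
  expect_length(kept, 2)
})

test_that("the set median recovers the canonical sequence from a noisy set", {
  canonical <- c("17", "15", "14a", "13b", "12", "4b")
  set.seed(808)
  seqs <- generate_noisy_set(canonical, 24)
  # generator guarantee: most sequences within one edit of the canonical
  d <- vapply(seqs, levenshtein, 0L, b = canonical)
  expect_gte(mean(d <= 1), 0.5)
  res <- set_median(seqs)
  expect_equal(res$median$labels, canonical)
})
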