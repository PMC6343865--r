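test_that("transition counting and row normalization are correct", {
  m <- build_transition_matrix(list(c("a", "b"), c("a", "b"), c("a", "c")))
  expect_equal(m$probabilities["a", "b"], 2 / 3)
  expect_equal(m$probabilities["a", "c"], 1 / 3)
  expect_equal(m$n_transitions, 3)

  m2 <- build_transition_matrix(list(c("a", "b", "c")))
  expect_equal(m2$counts["a", "b"], 1L)
  expect_equal(m2$counts["b", "c"], 1L)
  expect_equal(m2$n_transitions, 2)
  # no transitions across sequence boundaries
  m3 <- build_transition_matrix(list(c("a", "b"), c("c", "d")))
  expect_equal(m3$counts["b", "c"], 0L)
})

test_that("counts conserve adjacent pairs and rows are stochastic", {
  set.seed(5)
  seqs <- replicate(20, random_seq(sample(2:10, 1)), simplify = FALSE)
  m <- build_transition_matrix(seqs)
  expect_equal(m$n_transitions, sum(lengths(seqs) - 1))
  rs <- rowSums(m$probabilities)
  live <- rowSums(m$counts) > 0
  expect_true(all(abs(rs[live] - 1) < 1e-9))
})

test_that("empty input yields an empty matrix with zero transitions", {
  m <- build_transition_matrix(list())
  expect_equal(m$n_transitions, 0)
  expect_length(m$states, 0)
})

test_that("transitional tokens are collapsed into the flanking transition", {
  s <- phrase_sequence(c("13b", "t(13b>12)", "12"),
                       transitional = c(FALSE, TRUE, FALSE))
  m <- build_transition_matrix(list(s))
  expect_equal(m$states, c("12", "13b"))
  expect_equal(m$counts["13b", "12"], 1L)
  expect_equal(m$n_transitions, 1)
})

test_that("probabilities recover the generating matrix at >= 500 transitions per row", {
  states <- c("s", "a", "b", "e")
  P <- rbind(s = c(0, 0.7, 0.3, 0),
             a = c(0, 0, 0.4, 0.6),
             b = c(0.1, 0.2, 0, 0.7),
             e = c(0, 0, 0, 0))
  colnames(P) <- states
  set.seed(99)
  # draw explicit transitions so every live row accumulates >= 500 draws
  seqs <- list()
  for (from in c("s", "a", "b")) {
    to <- sample(states, 600, replace = TRUE, prob = P[from, ])
    seqs <- c(seqs, lapply(to, function(x) c(from, x)))
  }
  m <- build_transition_matrix(seqs)
  for (from in c("s", "a", "b"))
    expect_lt(max(abs(m$probabilities[from, states] - P[from, ])), 0.05)
})

test_that("common-path extraction matches an exhaustive DFS oracle", {
  delin <- delineation_config(start_labels = "s", end_labels = "e")
  cfg <- markov_config(min_prob_common = 0.05)
  set.seed(123)
  for (rep in 1:10) {
    # random 5-state chain built from random sequences
    seqs <- replicate(30, {
      n <- sample(2:6, 1)
      c("s", random_seq(n, c("a", "b", "c")), "e")
    }, simplify = FALSE)
    m <- build_transition_matrix(seqs)
    got <- extract_common_paths(m, cfg, delin, include_partial = FALSE)
    want <- dfs_paths_oracle(m$probabilities, "s", "e", cfg$min_prob_common)
    got_keys <- sort(vapply(got, format_sequence, ""))
    want_keys <- sort(vapply(want, paste, "", collapse = "-"))
    expect_identical(got_keys, want_keys)
    # ordering: path probability products are non-increasing
    probs <- vapply(got, attr, 0, "prob")
    expect_true(all(diff(probs) <= 1e-12))
  }
})

test_that("a single super-threshold chain yields exactly that path", {
  # only 14a -> 13b -> 12 -> 4b above threshold
  seqs <- c(replicate(50, c("14a", "13b", "12", "4b"), simplify = FALSE),
            list(c("14a", "3c"), c("13b", "8")))
  m <- build_transition_matrix(seqs)
  paths <- extract_common_paths(m, markov_config(0.05),
                                delineation_config())
  keys <- vapply(paths, format_sequence, "")
  expect_true("14a-13b-12-4b" %in% keys)
  expect_equal(keys[1], "14a-13b-12-4b")
})

test_that("a sub-threshold edge on the only route gives no start-to-end path", {
  # s -> a common, a -> e rare (1 of 30)
  seqs <- c(replicate(29, c("s", "a"), simplify = FALSE),
            list(c("s", "a", "e")),
            replicate(29, c("a", "b"), simplify = FALSE))
  m <- build_transition_matrix(seqs)
  expect_lt(m$probabilities["a", "e"], 0.05)
  paths <- extract_common_paths(m, markov_config(0.05),
                                delineation_config("s", "e"),
                                include_partial = FALSE)
  expect_length(paths, 0)
})

test_that("transitional_fraction is the flagged share of events", {
  ev <- phrase_events("r", "2011-02-05", rep("x", 10), 0:9, 1:10,
                      is_transitional = c(rep(TRUE, 3), rep(FALSE, 7)))
  expect_equal(transitional_fraction(ev), 0.3)
  ev0 <- phrase_events("r", "2011-02-05", rep("x", 4), 0:3, 1:4,
                       is_transitional = FALSE)
  expect_equal(transitional_fraction(ev0), 0)
  ev1 <- phrase_events("r", "2011-02-05", rep("x", 4), 0:3, 1:4,
                       is_transitional = TRUE)
  expect_equal(transitional_fraction(ev1), 1)
  empty <- ev0[0, ]
  expect_error(transitional_fraction(empty), "empty")
})

test_that("matrix export round-trips counts and flags common edges", {
  m <- build_transition_matrix(list(c("a", "b", "c"), c("a", "b")))
  dir <- withr::local_tempdir()
  edges <- export_transition_matrix(m, file.path(dir, "m"))
  expect_true(file.exists(file.path(dir, "m_counts.csv")))
  back <- read.csv(file.path(dir, "m_counts.csv"), row.names = 1)
  expect_equal(as.matrix(back), unclass(m$counts),
               ignore_attr = TRUE)
  expect_true(all(edges$common))
})
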