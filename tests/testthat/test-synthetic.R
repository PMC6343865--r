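small_config <- function(seed = 1, ...) {
  synthetic_config(seed = seed, n_recordings_per_period = 4,
                   n_days_per_period = 2, ...)
}

test_that("configuration validation rejects broken inputs", {
  expect_error(synthetic_config(transitional_prob = 1.3), "transitional_prob")
  expect_error(synthetic_config(window_s = 0), "positive")
  bad <- default_transition_matrices()
  bad[[1]]["15", ] <- 0   # 15 becomes a dead end but is not an end state
  bad[[1]]["17", ] <- 0
  expect_error(synthetic_config(per_period_transition = bad),
               "non-stochastic")
  # a matrix with no start-to-end path is a configuration error
  iso <- default_transition_matrices()
  m <- iso[[1]]; m[] <- 0
  m["17", "15"] <- 1; m["15", "17"] <- 1      # start labels cycle forever
  for (s in setdiff(rownames(m), c("17", "15", "4b", "4a")))
    m[s, "13b"] <- 1
  iso[[1]] <- m
  expect_error(synthetic_config(per_period_transition = iso), "no path")
})

test_that("default per-period matrices are row-stochastic with absorbing ends", {
  mats <- default_transition_matrices()
  expect_length(mats, 4)
  for (m in mats) {
    live <- !(rownames(m) %in% c("4b", "4a"))
    expect_true(all(abs(rowSums(m)[live] - 1) < 1e-9))
    expect_true(all(rowSums(m)[!live] == 0))
    expect_true(all(m >= 0))
  }
})

test_that("degenerate distributions spell the configured chain exactly", {
  al <- phrase_labels(c("17", "14a", "13b", "12", "4b"),
                      c("start", "unassigned", "unassigned", "unassigned",
                        "end"))
  chain <- matrix(0, 5, 5, dimnames = list(al$token, al$token))
  chain["17", "14a"] <- 1; chain["14a", "13b"] <- 1
  chain["13b", "12"] <- 1; chain["12", "4b"] <- 1
  cfg <- synthetic_config(alphabet = al,
                          canonical_sequence = c("17", "14a", "13b", "12", "4b"),
                          per_period_transition = list(chain),
                          repetition_mean = 1, transitional_prob = 0,
                          n_periods = 1, seed = 5)
  set.seed(5)
  tr <- generate_singer_track(cfg, 1)
  expect_equal(tr$events$label, c("17", "14a", "13b", "12", "4b"))
  expect_false(any(tr$events$is_transitional))
  expect_equal(tr$true_sequence$labels, c("17", "14a", "13b", "12", "4b"))
  # timestamps are contiguous and increasing
  expect_equal(tr$events$start_s[-1], tr$events$end_s[-5])
  expect_true(all(tr$events$end_s > tr$events$start_s))

  # transitional_prob = 1: every adjacent theme pair carries a flagged token
  cfg1 <- synthetic_config(alphabet = al,
                           canonical_sequence = c("17", "14a", "13b", "12", "4b"),
                           per_period_transition = list(chain),
                           repetition_mean = 1, transitional_prob = 1,
                           n_periods = 1, seed = 5)
  set.seed(5)
  tr1 <- generate_singer_track(cfg1, 1)
  expect_equal(sum(tr1$events$is_transitional), 4)
  expect_equal(tr1$events$is_transitional,
               rep(c(FALSE, TRUE), length.out = 9))
})

test_that("transitional phrases mark about 26% of theme boundaries", {
  cfg <- synthetic_config(seed = 17)
  set.seed(17)
  flagged <- 0L; boundaries <- 0L
  while (boundaries < 1000) {
    tr <- generate_singer_track(cfg, 1)
    boundaries <- boundaries + length(tr$true_sequence$labels) - 1L
    flagged <- flagged + sum(tr$events$is_transitional)
  }
  expect_lt(abs(flagged / boundaries - 0.26), 0.03)
})

test_that("the same (config, seed) reproduces the corpus bit-for-bit", {
  c1 <- generate_corpus(small_config(seed = 21))
  c2 <- generate_corpus(small_config(seed = 21))
  expect_identical(c1$events, c2$events)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$truth, c2$truth)
  c3 <- generate_corpus(small_config(seed = 22))
  expect_false(identical(c1$events, c3$events))
})

test_that("empirical theme transitions converge to the configured matrix", {
  cfg <- synthetic_config(seed = 33)
  set.seed(33)
  P <- cfg$per_period_transition[[1]]
  counts <- matrix(0, nrow(P), ncol(P), dimnames = dimnames(P))
  # accumulate until the canonical-chain rows have >= 500 transitions
  repeat {
    path <- generate_singer_track(cfg, 1)$true_sequence$labels
    for (i in seq_len(length(path) - 1))
      counts[path[i], path[i + 1]] <- counts[path[i], path[i + 1]] + 1
    if (all(rowSums(counts)[c("17", "15", "14a", "13b", "12")] >= 500)) break
  }
  emp <- counts / rowSums(counts)
  for (s in c("17", "15", "14a", "13b", "12"))
    expect_lt(max(abs(emp[s, ] - P[s, ])), 0.05)
})

test_that("corpus recordings respect the duty-cycle window", {
  corp <- generate_corpus(small_config(seed = 8))
  expect_true(all(corp$events$start_s >= 0))
  expect_true(all(corp$events$end_s <= 600))
  expect_equal(attr(corp$manifest, "window_s"), 600)
  expect_equal(attr(corp$manifest, "gap_s"), 300)
  # adjacent recordings within a day start one window + gap apart
  man <- corp$manifest
  day1 <- man[man$recording_id %in% c("P1-D1-R1", "P1-D1-R2"), ]
  expect_equal(diff(day1$start_posix), 900)
})

test_that("multiple singers produce time-overlapping events from distinct tracks", {
  cfg <- small_config(seed = 13, singers_per_recording = c(`1` = 0, `2` = 1))
  corp <- generate_corpus(cfg)
  ev <- corp$events
  rec <- split(seq_len(nrow(ev)), ev$recording_id)
  found_overlap <- FALSE
  for (idx in rec) {
    e <- ev[idx, ]
    if (length(unique(e$singer_track)) < 2) next
    a <- e[e$singer_track == "s1", ]; b <- e[e$singer_track == "s2", ]
    if (any(outer(a$start_s, b$end_s, `<`) & outer(a$end_s, b$start_s, `>`)))
      found_overlap <- TRUE
  }
  expect_true(found_overlap)
  expect_true(all(vapply(corp$truth$singers, identical, TRUE, y = 2L)))
})

test_that("ground truth counts singers per recording", {
  corp <- generate_corpus(small_config(seed = 3))
  for (rid in names(corp$truth$singers)) {
    n_tracks <- length(unique(
      corp$events$singer_track[corp$events$recording_id == rid]))
    expect_lte(n_tracks, corp$truth$singers[[rid]])
  }
})
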