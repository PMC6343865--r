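#' Default phrase alphabet of the synthetic generator
#'
#' Fifteen phrase types with configured roles: starting phrases 17 and 15,
#' terminal phrases 4b and 4a, static phrases 13b and 12, shifting phrases
#' 14a, 13c and 3c, and a tail of less common and rare phrases.
#'
#' @return a \code{\link{phrase_labels}} data.frame.
#' @export
default_alphabet <- function() {
  phrase_labels(
    tokens = c("17", "15", "11b", "13c", "14a", "14b", "13a", "3c",
               "13b", "12", "4b", "4a", "8", "6", "3a"),
    roles = c("start", "start", "unassigned", "shifting", "shifting",
              "unassigned", "unassigned", "shifting",
              "static", "static", "end", "end", "rare", "rare", "rare")
  )
}

#' Default per-period transition matrices
#'
#' Row-stochastic matrices over the default alphabet encoding a song chain
#' that runs from the starting phrases through the shifting mid-song phrases
#' into the fundamental static ending \code{13b-12-4b}, with the terminal
#' phrases absorbing.  Each period perturbs the shifting rows slightly
#' (probability mass moves between alternative successors period by period)
#' so that transition drift across periods is present by construction, while
#' static rows are identical in every period.
#'
#' @param n_periods number of periods (default 4).
#' @param drift total probability mass moved within shifting rows between
#'   consecutive periods (default 0.08).
#' @return a list of \code{n_periods} row-stochastic matrices.
#' @export
default_transition_matrices <- function(n_periods = 4, drift = 0.08) {
  al <- default_alphabet()$token
  base <- matrix(0, length(al), length(al), dimnames = list(al, al))
  set_row <- function(m, from, ...) {
    p <- c(...)
    m[from, names(p)] <- p
    m
  }
  base <- set_row(base, "17", "15" = 0.55, "14a" = 0.20, "13c" = 0.15, "11b" = 0.10)
  base <- set_row(base, "15", "14a" = 0.85, "13c" = 0.10, "11b" = 0.05)
  base <- set_row(base, "11b", "14a" = 0.80, "13b" = 0.20)
  base <- set_row(base, "13c", "13b" = 0.70, "14a" = 0.30)
  base <- set_row(base, "14a", "13b" = 0.85, "3c" = 0.10, "14b" = 0.05)
  base <- set_row(base, "14b", "13b" = 1)
  base <- set_row(base, "13a", "13b" = 1)
  base <- set_row(base, "3c", "13b" = 1)
  base <- set_row(base, "3a", "13b" = 1)
  base <- set_row(base, "13b", "12" = 0.95, "13a" = 0.05)
  base <- set_row(base, "12", "4b" = 0.86, "4a" = 0.07, "8" = 0.04, "3a" = 0.03)
  base <- set_row(base, "8", "6" = 0.50, "4b" = 0.50)
  base <- set_row(base, "6", "4b" = 1)
  # 4b and 4a are absorbing end states (all-zero rows)

  lapply(seq_len(n_periods), function(p) {
    m <- base
    shift <- drift * (p - 1)
    # shifting rows: move mass from the primary successor to alternatives
    m["17", "15"] <- m["17", "15"] - shift
    m["17", "13c"] <- m["17", "13c"] + shift
    m["14a", "13b"] <- m["14a", "13b"] - shift
    m["14a", "3c"] <- m["14a", "3c"] + shift
    m
  })
}

#' Synthetic song-corpus configuration
#'
#' Defines the statistical structure of a generated corpus: the phrase
#' alphabet with roles, the canonical full-song sequence (containing the
#' fundamental ending \code{13b-12-4b}), per-period theme-transition
#' matrices, the within-theme phrase repetition distribution (geometric,
#' support >= 1), the probability that a theme boundary is marked by a
#' transitional phrase, the singers-per-recording distribution, the
#' recorder's duty cycle, and the recording layout.
#'
#' @param alphabet a \code{\link{phrase_labels}} data.frame.
#' @param canonical_sequence tokens of the canonical full song.
#' @param per_period_transition list of row-stochastic matrices over the
#'   alphabet, one per period; rows of end-role states may be all zero
#'   (absorbing).
#' @param repetition_mean mean number of repeats of a phrase within its
#'   theme (geometric with support >= 1; default 5).
#' @param transitional_prob probability that a theme boundary carries a
#'   flagged transitional phrase (default 0.26).
#' @param singers_per_recording probability weights for 1..5 singers per
#'   recording (default mean about 2.6 singers).
#' @param window_s,gap_s duty-cycle on-window and off-gap seconds
#'   (defaults 600 and 300: 10-minute recordings every 15 minutes).
#' @param phrase_duration_s mean phrase duration in seconds (default 20).
#' @param n_recordings_per_period,n_days_per_period recording layout
#'   (defaults 16 recordings over 4 days per period).
#' @param n_periods number of periods (default 4).
#' @param start_date first recording date.
#' @param offset_max_s maximum uniform start offset of a singer track
#'   within its window, in seconds (singers are unsynchronized).
#' @param seed integer seed; the same (config, seed) pair reproduces the
#'   corpus bit-for-bit.
#' @return an object of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(alphabet = default_alphabet(),
                             canonical_sequence = c("17", "15", "14a",
                                                    "13b", "12", "4b"),
                             per_period_transition = default_transition_matrices(n_periods),
                             repetition_mean = 5,
                             transitional_prob = 0.26,
                             singers_per_recording = c(`1` = 0.20, `2` = 0.30,
                                                       `3` = 0.25, `4` = 0.15,
                                                       `5` = 0.10),
                             window_s = 600, gap_s = 300,
                             phrase_duration_s = 20,
                             n_recordings_per_period = 16,
                             n_days_per_period = 4,
                             n_periods = 4,
                             start_date = as.Date("2011-01-27"),
                             offset_max_s = 120,
                             seed = 1L) {
  cfg <- structure(list(
    alphabet = alphabet,
    canonical_sequence = as.character(canonical_sequence),
    per_period_transition = per_period_transition,
    repetition_mean = repetition_mean,
    transitional_prob = transitional_prob,
    singers_per_recording = singers_per_recording / sum(singers_per_recording),
    window_s = window_s, gap_s = gap_s,
    phrase_duration_s = phrase_duration_s,
    n_recordings_per_period = as.integer(n_recordings_per_period),
    n_days_per_period = as.integer(n_days_per_period),
    n_periods = as.integer(n_periods),
    start_date = as.Date(start_date),
    offset_max_s = offset_max_s,
    seed = as.integer(seed)
  ), class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

start_tokens <- function(cfg) cfg$alphabet$token[cfg$alphabet$role == "start"]
end_tokens <- function(cfg) cfg$alphabet$token[cfg$alphabet$role == "end"]

validate_synthetic_config <- function(cfg) {
  al <- cfg$alphabet$token
  if (cfg$transitional_prob < 0 || cfg$transitional_prob > 1)
    stop("transitional_prob must lie in [0, 1]")
  if (cfg$window_s <= 0 || cfg$gap_s <= 0)
    stop("window_s and gap_s must be positive")
  if (cfg$repetition_mean < 1) stop("repetition_mean must be >= 1")
  if (!all(cfg$canonical_sequence %in% al))
    stop("canonical sequence uses tokens outside the alphabet")
  if (length(cfg$per_period_transition) != cfg$n_periods)
    stop("need one transition matrix per period")
  ends <- end_tokens(cfg)
  starts <- start_tokens(cfg)
  if (!length(starts) || !length(ends))
    stop("alphabet must assign start and end roles")
  for (k in seq_along(cfg$per_period_transition)) {
    m <- cfg$per_period_transition[[k]]
    if (!identical(sort(rownames(m)), sort(al)))
      stop("transition matrix ", k, " states do not match the alphabet")
    rs <- rowSums(m)
    live <- !(rownames(m) %in% ends)
    if (any(abs(rs[live] - 1) > 1e-9))
      stop("transition matrix ", k, " has non-stochastic row(s): ",
           paste(rownames(m)[live][abs(rs[live] - 1) > 1e-9], collapse = ", "))
    if (!path_exists(m, starts, ends))
      stop("transition matrix ", k,
           " admits no path from any start label to any end label")
  }
  invisible(cfg)
}

# reachability of any end state from any start state over positive edges
path_exists <- function(m, starts, ends) {
  reach <- starts
  repeat {
    nxt <- unique(c(reach, unlist(lapply(reach, function(s)
      colnames(m)[m[s, ] > 0]))))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  length(intersect(reach, ends)) > 0
}

# geometric repetition count with support >= 1 and the configured mean
draw_repeats <- function(mean_reps) {
  if (mean_reps <= 1) return(1L)
  1L + stats::rgeom(1L, prob = 1 / mean_reps)
}

transitional_token <- function(x, y) paste0("t(", x, ">", y, ")")

#' Generate one singer's phrase track
#'
#' Samples a theme path from the period's transition matrix (starting at a
#' uniformly chosen start-role phrase, walking until an end-role phrase,
#' which is absorbing), expands each theme into a geometric number of phrase
#' repeats, inserts a flagged transitional phrase at each theme boundary
#' with the configured probability, and assigns contiguous timestamps with
#' gamma-distributed phrase durations.  Uses the current RNG state; seed via
#' \code{set.seed} or \code{\link{generate_corpus}}.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param period_id period index (selects the transition matrix).
#' @param t0 start time of the track, in seconds.
#' @return a list with \code{events} (data.frame: label, start_s, end_s,
#'   is_transitional) and \code{true_sequence} (the theme-level
#'   \code{phrase_sequence} actually walked).
#' @export
generate_singer_track <- function(config, period_id = 1L, t0 = 0) {
  m <- config$per_period_transition[[period_id]]
  starts <- start_tokens(config); ends <- end_tokens(config)
  path <- sample(starts, 1L)
  cur <- path
  while (!(cur %in% ends)) {
    p <- m[cur, ]
    if (sum(p) <= 0) break
    cur <- sample(colnames(m), 1L, prob = p)
    path <- c(path, cur)
  }

  labels <- character(0); flags <- logical(0)
  for (i in seq_along(path)) {
    reps <- draw_repeats(config$repetition_mean)
    labels <- c(labels, rep(path[i], reps))
    flags <- c(flags, rep(FALSE, reps))
    if (i < length(path) && stats::runif(1L) < config$transitional_prob) {
      labels <- c(labels, transitional_token(path[i], path[i + 1L]))
      flags <- c(flags, TRUE)
    }
  }
  dur <- stats::rgamma(length(labels), shape = 4,
                       rate = 4 / config$phrase_duration_s)
  end_t <- t0 + cumsum(dur)
  start_t <- c(t0, utils::head(end_t, -1L))
  list(
    events = data.frame(label = labels, start_s = start_t, end_s = end_t,
                        is_transitional = flags, stringsAsFactors = FALSE),
    true_sequence = phrase_sequence(path, period_id = as.character(period_id))
  )
}

#' Period specification implied by a synthetic configuration
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return a \code{\link{period_spec}}.
#' @export
synthetic_period_spec <- function(config) {
  span <- (config$n_days_per_period - 1L) * 2L
  starts <- config$start_date + (seq_len(config$n_periods) - 1L) * (span + 3L)
  period_spec(period_id = as.character(seq_len(config$n_periods)),
              start = starts, end = starts + span)
}

#' Generate a synthetic song corpus with ground truth
#'
#' Lays recordings on the duty-cycle grid (adjacent 10-minute windows
#' separated by 5-minute gaps within each recording day), draws the number
#' of singers for each recording, and generates each singer's track with an
#' independent uniform start offset (singers are unsynchronized).  A singer
#' keeps singing past the end of the on-window: events starting after the
#' window are absent from the log and the final event is clipped at the
#' window end, emulating fragmentation of continuous song into 10-minute
#' files.  The ground truth records the seed, the true theme sequences per
#' singer, the configured transition matrices, and the true singer count per
#' recording.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return a list with \code{events} (a \code{\link{phrase_events}} table),
#'   \code{manifest} (a \code{\link{corpus_manifest}}), \code{spec}
#'   (a \code{\link{period_spec}}) and \code{truth}.
#' @export
generate_corpus <- function(config) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  spec <- synthetic_period_spec(config)
  per_day <- config$n_recordings_per_period %/% config$n_days_per_period
  slot_s <- config$window_s + config$gap_s

  ev_list <- list(); man_list <- list()
  truth <- list(seed = config$seed,
                transition = config$per_period_transition,
                singers = list(), sequences = list())

  for (p in seq_len(config$n_periods)) {
    for (d in seq_len(config$n_days_per_period)) {
      date <- spec$start[p] + (d - 1L) * 2L
      day_clock0 <- 3 * 3600 + (d - 1L) * 3600   # early-morning sessions
      for (r in seq_len(per_day)) {
        rec_id <- sprintf("P%d-D%d-R%d", p, d, r)
        clock_s <- day_clock0 + (r - 1L) * slot_s
        n_singers <- sample(seq_along(config$singers_per_recording), 1L,
                            prob = config$singers_per_recording)
        truth$singers[[rec_id]] <- n_singers
        rec_events <- list()
        for (s in seq_len(n_singers)) {
          offset <- stats::runif(1L, 0, config$offset_max_s)
          t <- offset
          singer_events <- list(); singer_seqs <- list()
          while (t < config$window_s) {
            tr <- generate_singer_track(config, p, t0 = t)
            singer_events[[length(singer_events) + 1L]] <- tr$events
            singer_seqs[[length(singer_seqs) + 1L]] <- tr$true_sequence
            t <- max(tr$events$end_s)
          }
          se <- do.call(rbind, singer_events)
          # fragmentation: drop events starting past the window, clip the rest
          se <- se[se$start_s < config$window_s, , drop = FALSE]
          se$end_s <- pmin(se$end_s, config$window_s)
          se <- se[se$end_s > se$start_s, , drop = FALSE]
          if (nrow(se)) {
            se$singer_track <- paste0("s", s)
            rec_events[[length(rec_events) + 1L]] <- se
          }
          truth$sequences[[rec_id]][[paste0("s", s)]] <- singer_seqs
        }
        re <- do.call(rbind, rec_events)
        if (!is.null(re) && nrow(re)) {
          re$recording_id <- rec_id
          re$date <- date
          re$period_id <- spec$period_id[p]
          ev_list[[length(ev_list) + 1L]] <- re
        }
        man_list[[length(man_list) + 1L]] <- data.frame(
          recording_id = rec_id, date = date,
          clock_time = sprintf("%02d:%02d", clock_s %/% 3600,
                               (clock_s %% 3600) %/% 60),
          duration_s = config$window_s, stringsAsFactors = FALSE)
      }
    }
  }

  ev <- do.call(rbind, ev_list)
  events <- phrase_events(ev$recording_id, ev$date, ev$label,
                          ev$start_s, ev$end_s, period_id = ev$period_id,
                          singer_track = ev$singer_track,
                          is_transitional = ev$is_transitional)
  man <- do.call(rbind, man_list)
  manifest <- corpus_manifest(man$recording_id, man$date, man$clock_time,
                              man$duration_s, window_s = config$window_s,
                              gap_s = config$gap_s)
  list(events = events, manifest = manifest, spec = spec, truth = truth)
}

#' Generate a noisy set of sequences around a canonical sequence
#'
#' Emulates the within-period variation of delineated song fragments: most
#' sequences equal the canonical theme sequence or differ from it by a
#' single token edit, a minority by two edits.  Used for set-median recovery
#' testing.  Uses the current RNG state.
#'
#' @param canonical token vector (or coercible sequence).
#' @param n number of sequences.
#' @param alphabet tokens available for substitutions/insertions (defaults
#'   to the default alphabet).
#' @param p_edits probability weights for 0, 1 and 2 edits per sequence
#'   (default \code{c(0.35, 0.40, 0.25)}).
#' @return a list of \code{phrase_sequence} objects.
#' @export
generate_noisy_set <- function(canonical, n,
                               alphabet = default_alphabet()$token,
                               p_edits = c(0.35, 0.40, 0.25)) {
  canonical <- seq_tokens(canonical)
  lapply(seq_len(n), function(i) {
    k <- sample(0:2, 1L, prob = p_edits)
    s <- canonical
    for (e in seq_len(k)) {
      op <- sample(c("sub", "ins", "del"), 1L, prob = c(0.6, 0.2, 0.2))
      if (op == "del" && length(s) <= 2L) op <- "sub"
      if (op == "sub") {
        pos <- sample(length(s), 1L)
        s[pos] <- sample(setdiff(alphabet, s[pos]), 1L)
      } else if (op == "ins") {
        pos <- sample(length(s) + 1L, 1L)
        s <- append(s, sample(alphabet, 1L), after = pos - 1L)
      } else {
        s <- s[-sample(length(s), 1L)]
      }
    }
    phrase_sequence(s)
  })
}
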