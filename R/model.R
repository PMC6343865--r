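#' whalesong: symbolic analysis of humpback whale song phrase sequences
#'
#' Humpback whale songs are hierarchically structured: short sound units
#' combine into stereotyped phrases, phrases are repeated to form themes, and
#' an ordered pass through themes constitutes a song.  This package works at
#' the symbolic level: each logged phrase occurrence is a timed, labeled
#' event, and songs are analyzed as token sequences.  It provides sequence
#' delineation, first-order Markov transition analysis, transition-consistency
#' testing across recording periods, token-level Levenshtein similarity with
#' set-median and Kohonen-median representatives, single-linkage clustering,
#' Dice phrase-sharing indices, minimum-singer estimation from interval
#' overlap, and a synthetic corpus generator with ground truth.
#'
#' @docType package
#' @name whalesong-package
#' @aliases whalesong
#' @keywords internal
"_PACKAGE"

# Default token separator used by the hyphen-joined sequence notation
# ("15-14a-13b-12-4b").  Reserved: tokens must not contain it.
WS_SEPARATOR <- "-"

#' Validate phrase tokens
#'
#' Tokens identify phrase types (for example \code{"14a"}, \code{"4b"},
#' \code{"17"}).  A valid token is a non-empty string without whitespace and
#' without the sequence-separator character.  Comparison is by exact,
#' case-sensitive string equality throughout the package.
#'
#' @param tokens character vector of candidate tokens.
#' @param separator reserved separator character (default \code{"-"}).
#' @return invisibly, \code{tokens}; an error is raised for invalid tokens.
#' @export
validate_tokens <- function(tokens, separator = WS_SEPARATOR) {
  if (!is.character(tokens)) stop("tokens must be character")
  bad <- !nzchar(tokens) | grepl("\\s", tokens) |
    grepl(separator, tokens, fixed = TRUE) | is.na(tokens)
  if (any(bad)) {
    stop("invalid phrase token(s): ",
         paste(sQuote(unique(tokens[bad])), collapse = ", "),
         " (tokens must be non-empty, without whitespace or '",
         separator, "')")
  }
  invisible(tokens)
}

#' Phrase label roles
#'
#' Role assignment is configuration, never inferred from data.  Recognised
#' roles: \code{start}, \code{end}, \code{static}, \code{shifting},
#' \code{rare}, \code{unassigned}.
#'
#' @param tokens character vector of phrase tokens.
#' @param roles character vector of roles, recycled to \code{length(tokens)}.
#' @return a data.frame with columns \code{token} and \code{role}.
#' @export
phrase_labels <- function(tokens, roles = "unassigned") {
  validate_tokens(tokens)
  roles <- rep_len(roles, length(tokens))
  ok <- roles %in% c("start", "end", "static", "shifting", "rare", "unassigned")
  if (!all(ok)) stop("unknown role(s): ", paste(unique(roles[!ok]), collapse = ", "))
  if (anyDuplicated(tokens)) stop("duplicate tokens in label set")
  data.frame(token = tokens, role = roles, stringsAsFactors = FALSE)
}

#' Construct a table of phrase events
#'
#' A phrase event is one timed, labeled phrase occurrence within a recording
#' (the atomic log record).  Events are held in a data.frame with class
#' \code{"phrase_events"} and columns \code{recording_id}, \code{date}
#' (\code{Date}), \code{period_id}, \code{singer_track}, \code{label},
#' \code{start_s}, \code{end_s} and \code{is_transitional}.
#'
#' @param recording_id character, recording identifiers.
#' @param date recording dates (\code{Date} or ISO-8601 strings).
#' @param label phrase tokens.
#' @param start_s,end_s event start/end in seconds from recording start;
#'   \code{end_s} must exceed \code{start_s} and \code{start_s} must be
#'   non-negative.
#' @param period_id period identifiers (may be \code{NA} before grouping).
#' @param singer_track optional manual singer-track labels (\code{NA} if the
#'   events are not attributed to singers).
#' @param is_transitional logical flag marking transitional phrases (hybrid
#'   phrases emitted at theme boundaries).
#' @return a \code{phrase_events} data.frame sorted by recording and start time.
#' @export
phrase_events <- function(recording_id, date, label, start_s, end_s,
                          period_id = NA_character_,
                          singer_track = NA_character_,
                          is_transitional = FALSE) {
  n <- length(label)
  validate_tokens(label)
  df <- data.frame(
    recording_id = rep_len(as.character(recording_id), n),
    date = rep_len(as.Date(date), n),
    period_id = rep_len(as.character(period_id), n),
    singer_track = rep_len(as.character(singer_track), n),
    label = as.character(label),
    start_s = rep_len(as.numeric(start_s), n),
    end_s = rep_len(as.numeric(end_s), n),
    is_transitional = rep_len(as.logical(is_transitional), n),
    stringsAsFactors = FALSE
  )
  bad <- which(!(df$end_s > df$start_s) | df$start_s < 0)
  if (length(bad)) {
    stop("invalid event interval(s) at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         ": need 0 <= start_s < end_s")
  }
  df <- df[order(df$recording_id, df$start_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("phrase_events", "data.frame")
  df
}

#' Construct a phrase sequence
#'
#' An ordered run of phrase tokens attributed to one singer: the unit of
#' delineation and of edit-distance analysis.  Times, when present, are
#' parallel to the labels and non-decreasing in start time.
#'
#' @param labels character vector of phrase tokens (non-empty).
#' @param transitional logical vector flagging transitional tokens.
#' @param start_s,end_s optional numeric vectors of event times.
#' @param recording_id,period_id,singer_track optional provenance.
#' @return an object of class \code{"phrase_sequence"}.
#' @export
phrase_sequence <- function(labels, transitional = FALSE,
                            start_s = NULL, end_s = NULL,
                            recording_id = NA_character_,
                            period_id = NA_character_,
                            singer_track = NA_character_) {
  labels <- as.character(labels)
  if (!length(labels)) stop("a phrase sequence must contain at least one token")
  validate_tokens(labels)
  transitional <- rep_len(as.logical(transitional), length(labels))
  if (!is.null(start_s)) {
    if (length(start_s) != length(labels) || length(end_s) != length(labels))
      stop("times, when given, must parallel the labels")
    if (is.unsorted(start_s)) stop("start times must be non-decreasing")
  }
  structure(
    list(labels = labels, transitional = transitional,
         start_s = start_s, end_s = end_s,
         recording_id = as.character(recording_id),
         period_id = as.character(period_id),
         singer_track = as.character(singer_track)),
    class = "phrase_sequence"
  )
}

#' @export
print.phrase_sequence <- function(x, ...) {
  cat("<phrase_sequence> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.phrase_sequence <- function(x, ...) format_sequence(x)

#' @export
length.phrase_sequence <- function(x) length(x$labels)

#' Coerce to a phrase sequence
#'
#' @param x a \code{phrase_sequence}, a character vector of tokens, or a
#'   hyphen-joined string such as \code{"15-14a-13b-12-4b"}.
#' @param ... passed on to \code{\link{phrase_sequence}}.
#' @return a \code{phrase_sequence}.
#' @export
as_phrase_sequence <- function(x, ...) {
  if (inherits(x, "phrase_sequence")) return(x)
  if (is.character(x) && length(x) == 1L && grepl(WS_SEPARATOR, x, fixed = TRUE))
    return(parse_sequence(x, ...))
  phrase_sequence(as.character(x), ...)
}

#' Parse and format hyphen-joined sequence notation
#'
#' Sequences are conventionally written with tokens joined by a hyphen,
#' e.g. \code{"15-14a-13b-12-4b"}; the hyphen marks the transition between
#' themes.  These helpers round-trip that notation.
#'
#' @param x for \code{parse_sequence}, a single string; for
#'   \code{format_sequence}, a \code{phrase_sequence} or character vector.
#' @param separator separator character (default \code{"-"}).
#' @param ... passed to \code{\link{phrase_sequence}}.
#' @return \code{parse_sequence}: a \code{phrase_sequence};
#'   \code{format_sequence}: a single string.
#' @examples
#' format_sequence(parse_sequence("15-14a-13b-12-4b"))
#' @export
parse_sequence <- function(x, separator = WS_SEPARATOR, ...) {
  stopifnot(is.character(x), length(x) == 1L)
  phrase_sequence(strsplit(trimws(x), separator, fixed = TRUE)[[1L]], ...)
}

#' @rdname parse_sequence
#' @export
format_sequence <- function(x, separator = WS_SEPARATOR) {
  labels <- if (inherits(x, "phrase_sequence")) x$labels else as.character(x)
  paste(labels, collapse = separator)
}

#' Collapse repeated phrases into themes
#'
#' Themes are composed of repeated phrases; at the theme level, consecutive
#' identical tokens carry no extra information.  \code{collapse_runs} merges
#' every run of adjacent identical tokens into a single token, preserving
#' relative order.  The operation is idempotent and never lengthens a
#' sequence.  When times are present the merged token spans from the first
#' repeat's start to the last repeat's end.
#'
#' @param seq a \code{phrase_sequence} (or coercible).
#' @return a theme-level \code{phrase_sequence}.
#' @examples
#' format_sequence(collapse_runs(c("14a", "14a", "14a", "13b", "13b", "12")))
#' @export
collapse_runs <- function(seq) {
  seq <- as_phrase_sequence(seq)
  lab <- seq$labels
  keep <- c(TRUE, lab[-1L] != lab[-length(lab)])
  if (all(keep)) return(seq)
  run_id <- cumsum(keep)
  out <- seq
  out$labels <- lab[keep]
  out$transitional <- as.logical(tapply(seq$transitional, run_id, any))
  if (!is.null(seq$start_s)) {
    out$start_s <- as.numeric(tapply(seq$start_s, run_id, min))
    out$end_s <- as.numeric(tapply(seq$end_s, run_id, max))
  }
  out
}

#' Build per-singer phrase sequences from an event log
#'
#' Events are grouped by recording and singer track (unattributed events form
#' one track per recording) and ordered by start time; each group becomes one
#' \code{phrase_sequence}.
#'
#' @param events a \code{phrase_events} data.frame.
#' @return a list of \code{phrase_sequence} objects.
#' @export
events_to_sequences <- function(events) {
  if (!nrow(events)) return(list())
  track <- ifelse(is.na(events$singer_track), "", events$singer_track)
  key <- paste(events$recording_id, track, sep = "\r")
  idx <- split(seq_len(nrow(events)), key)
  # preserve recording order, then track order
  ord <- order(vapply(idx, function(i) events$recording_id[i[1L]], ""),
               vapply(idx, function(i) track[i[1L]], ""))
  lapply(idx[ord], function(i) {
    i <- i[order(events$start_s[i])]
    phrase_sequence(
      labels = events$label[i],
      transitional = events$is_transitional[i],
      start_s = events$start_s[i], end_s = events$end_s[i],
      recording_id = unique(events$recording_id[i]),
      period_id = unique(events$period_id[i])[1L],
      singer_track = unique(track[i])
    )
  })
}

#' Declare the period structure of a corpus
#'
#' Recording days are grouped into periods (sets): blocks of days treated as
#' one sampling unit of singers.  Membership is decided by the calendar date
#' of the recording's start.
#'
#' @param period_id character vector of period identifiers, in chronological
#'   order of their date ranges.
#' @param start,end first and last calendar date of each period (inclusive).
#' @return a data.frame with class \code{"period_spec"}.
#' @export
period_spec <- function(period_id, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (any(end < start)) stop("period end date precedes start date")
  spec <- data.frame(period_id = as.character(period_id), start = start,
                     end = end, stringsAsFactors = FALSE)
  spec <- spec[order(spec$start), , drop = FALSE]
  for (i in seq_len(nrow(spec) - 1L))
    if (spec$end[i] >= spec$start[i + 1L]) stop("period date ranges overlap")
  rownames(spec) <- NULL
  class(spec) <- c("period_spec", "data.frame")
  spec
}

#' Group phrase events into period sets
#'
#' Partitions an event log into periods according to a declared period
#' specification, builds per-singer sequences within each period, and derives
#' each period's phrase inventory (the union of tokens over its sequences).
#' Periods are returned in chronological order of their date ranges.
#'
#' @param events a \code{phrase_events} data.frame with valid dates.
#' @param spec a \code{\link{period_spec}}.
#' @return a list of period sets; each element is a list with
#'   \code{period_id}, \code{dates}, \code{sequences} (list of
#'   \code{phrase_sequence}), \code{events} and \code{phrase_inventory}.
#' @export
group_into_periods <- function(events, spec) {
  if (!inherits(spec, "period_spec")) stop("spec must be a period_spec")
  if (!nrow(events)) return(list())
  period_of <- rep(NA_character_, nrow(events))
  for (i in seq_len(nrow(spec))) {
    hit <- events$date >= spec$start[i] & events$date <= spec$end[i]
    period_of[hit] <- spec$period_id[i]
  }
  if (anyNA(period_of)) {
    off <- unique(events$recording_id[is.na(period_of)])
    stop("recording(s) dated outside all declared periods: ",
         paste(off, collapse = ", "))
  }
  lapply(seq_len(nrow(spec)), function(i) {
    pid <- spec$period_id[i]
    ev <- events[period_of == pid, , drop = FALSE]
    ev$period_id <- pid
    class(ev) <- class(events)
    seqs <- events_to_sequences(ev)
    structure(list(
      period_id = pid,
      dates = sort(unique(ev$date)),
      sequences = seqs,
      events = ev,
      phrase_inventory = sort(unique(ev$label[!ev$is_transitional]))
    ), class = "period_set")
  })
}

#' @export
print.period_set <- function(x, ...) {
  cat("<period_set> ", x$period_id, ": ", length(x$sequences),
      " sequence(s), ", nrow(x$events), " event(s), inventory {",
      paste(x$phrase_inventory, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Construct a corpus manifest
#'
#' Records the recordings' dates, clock times and durations, plus the duty
#' cycle of the recorder (on-window and off-gap, in seconds).  Clock times
#' are stored timezone-naive (local clock time).
#'
#' @param recording_id character recording identifiers.
#' @param date recording dates.
#' @param clock_time recording start clock times, \code{"HH:MM"} or
#'   \code{"HH:MM:SS"} strings.
#' @param duration_s recording durations in seconds (> 0).
#' @param window_s,gap_s duty-cycle on-window and off-gap in seconds.
#' @return a data.frame of class \code{"corpus_manifest"} with an added
#'   \code{start_posix} column (seconds since the corpus epoch).
#' @export
corpus_manifest <- function(recording_id, date, clock_time, duration_s,
                            window_s = 600, gap_s = 300) {
  if (window_s <= 0 || gap_s <= 0) stop("window_s and gap_s must be positive")
  date <- as.Date(date)
  if (anyNA(date)) stop("unparseable date(s) in manifest")
  duration_s <- as.numeric(duration_s)
  if (any(duration_s <= 0)) stop("durations must be positive")
  secs <- clock_to_seconds(clock_time)
  df <- data.frame(recording_id = as.character(recording_id), date = date,
                   clock_time = as.character(clock_time),
                   duration_s = duration_s, stringsAsFactors = FALSE)
  df$start_posix <- as.numeric(df$date - min(df$date)) * 86400 + secs
  attr(df, "window_s") <- window_s
  attr(df, "gap_s") <- gap_s
  class(df) <- c("corpus_manifest", "data.frame")
  df
}

clock_to_seconds <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.numeric(p)
    if (anyNA(p) || length(p) < 2L || length(p) > 3L)
      stop("unparseable clock time")
    sum(p * c(3600, 60, 1)[seq_along(p)])
  }, numeric(1))
}

#' Check the 24-hour singer-independence assumption
#'
#' Recording days assigned to different singer groups are assumed to sample
#' different sets of singers only if at least 24 hours separate their
#' recordings.  Separation is measured between recording start times: for
#' each pair of days in different groups, the closest pair of start times is
#' compared against the threshold.  Every pair of days in different groups
#' whose recordings start closer than 24 hours apart is reported; an empty
#' result means the corpus satisfies the independence assumption.
#'
#' @param manifest a \code{\link{corpus_manifest}}.
#' @param grouping named character vector mapping dates (ISO-8601 strings)
#'   to singer-group identifiers; days sharing a group are exempt.
#' @param min_gap_h minimum separation in hours (default 24).
#' @return a data.frame of violating day pairs (possibly empty) with the
#'   observed gap in hours.
#' @export
validate_independence <- function(manifest, grouping, min_gap_h = 24) {
  if (!nrow(manifest)) stop("manifest is empty")
  days <- as.character(manifest$date)
  if (!all(days %in% names(grouping)))
    stop("grouping is missing date(s): ",
         paste(setdiff(days, names(grouping)), collapse = ", "))
  # earliest and latest recording start per day
  agg_lo <- tapply(manifest$start_posix, days, min)
  agg_hi <- tapply(manifest$start_posix, days, max)
  ud <- names(agg_lo)
  out <- data.frame(day1 = character(), day2 = character(),
                    gap_h = numeric(), stringsAsFactors = FALSE)
  if (length(ud) < 2L) return(out)
  for (i in seq_len(length(ud) - 1L)) for (j in (i + 1L):length(ud)) {
    if (grouping[[ud[i]]] == grouping[[ud[j]]]) next
    gap_s <- max(agg_lo[[ud[j]]] - agg_hi[[ud[i]]],
                 agg_lo[[ud[i]]] - agg_hi[[ud[j]]])
    if (gap_s < min_gap_h * 3600)
      out[nrow(out) + 1L, ] <- list(ud[i], ud[j], gap_s / 3600)
  }
  out
}
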