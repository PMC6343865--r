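#' Minimum number of simultaneous singers in a recording
#'
#' Phrases overlapping in time cannot be produced by the same whale, so the
#' maximum number of phrase intervals covering any single instant is a lower
#' bound on the number of singers within detection range.  Intervals are
#' treated as half-open [start, end): two phrases meeting exactly at a
#' boundary do not overlap.  When manual singer-track labels are present
#' they override interval inference (the number of distinct tracks is
#' returned).
#'
#' @param events a \code{phrase_events} data.frame for one recording
#'   (non-empty).
#' @param use_tracks honor \code{singer_track} annotations when all events
#'   carry one (default \code{TRUE}).
#' @return an integer >= 1.
#' @examples
#' ev <- phrase_events("r1", "2011-02-05", c("14a", "13b"),
#'                     start_s = c(0, 5), end_s = c(10, 15))
#' min_singers(ev)  # 2
#' @export
min_singers <- function(events, use_tracks = TRUE) {
  if (!nrow(events)) stop("no events: no evidence of any singer")
  if (length(unique(events$recording_id)) > 1L)
    stop("min_singers expects events from a single recording")
  if (use_tracks && !anyNA(events$singer_track))
    return(length(unique(events$singer_track)))
  # sweep over sorted endpoints; starts before ends at equal time points so
  # that [a, b) and [b, c) never count as concurrent
  t <- c(events$start_s, events$end_s)
  delta <- rep(c(1L, -1L), each = nrow(events))
  ord <- order(t, delta)   # -1 (end) sorts before +1 (start) at ties
  max(cumsum(delta[ord]))
}

#' Classify a recording by its detection rate
#'
#' Detection rates (automatic detections per minute of effort) index how
#' many whales are chorusing: above 30 detections/min recordings always
#' contained at least four to five singers; above 15, two or more; below 10,
#' recordings were more likely to contain solo singers (though low-rate
#' files can still hide several quiet singers).  Rates between 10 and 15
#' are left ambiguous.  The classification is a heuristic bound, never an
#' exact count.
#'
#' @param rate detections per minute of effort (>= 0).
#' @param thresholds named numeric vector \code{c(solo_below, ambiguous_to,
#'   chorus4_above)} giving the three cut points (defaults 10, 15, 30).
#' @return a factor level among \code{likely_solo < ambiguous <
#'   chorus_2plus < chorus_4plus}.
#' @export
classify_rate <- function(rate, thresholds = c(solo_below = 10,
                                               ambiguous_to = 15,
                                               chorus4_above = 30)) {
  if (any(rate < 0)) stop("detection rate cannot be negative")
  lv <- c("likely_solo", "ambiguous", "chorus_2plus", "chorus_4plus")
  cls <- ifelse(rate > thresholds[["chorus4_above"]], "chorus_4plus",
         ifelse(rate > thresholds[["ambiguous_to"]], "chorus_2plus",
         ifelse(rate < thresholds[["solo_below"]], "likely_solo",
                "ambiguous")))
  factor(cls, levels = lv, ordered = TRUE)
}

#' Summarize per-recording detections
#'
#' @param recording_id,date recording identifiers and dates.
#' @param detections automatic detection counts per recording.
#' @param effort_minutes minutes of analyzed audio per recording (> 0).
#' @return a data.frame of class \code{"detection_summary"} with the derived
#'   \code{rate} (detections per minute of effort).
#' @export
detection_summary <- function(recording_id, date, detections,
                              effort_minutes) {
  effort_minutes <- as.numeric(effort_minutes)
  if (any(effort_minutes <= 0)) stop("effort_minutes must be positive")
  df <- data.frame(recording_id = as.character(recording_id),
                   date = as.Date(date),
                   detections = as.numeric(detections),
                   effort_minutes = effort_minutes,
                   stringsAsFactors = FALSE)
  df$rate <- df$detections / df$effort_minutes
  class(df) <- c("detection_summary", "data.frame")
  df
}

#' Read detection summaries from CSV
#'
#' Expects columns \code{recording_id}, \code{date}, \code{detections},
#' \code{effort_minutes}.
#'
#' @param path CSV file path.
#' @return a \code{\link{detection_summary}} data.frame.
#' @export
read_detection_summary <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("recording_id", "date", "detections", "effort_minutes")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  detection_summary(df$recording_id, df$date, df$detections,
                    df$effort_minutes)
}

#' Daily distribution of detection rates
#'
#' Summarizes per-recording detection rates by day (minimum, quartiles,
#' maximum), the boxplot-style view used to read chorusing activity off a
#' season of recordings.
#'
#' @param summaries a \code{\link{detection_summary}} data.frame.
#' @return a data.frame with one row per day: \code{date}, \code{n},
#'   \code{min}, \code{q1}, \code{median}, \code{q3}, \code{max},
#'   \code{mean}.
#' @export
daily_detection_profile <- function(summaries) {
  sp <- split(summaries$rate, summaries$date)
  out <- do.call(rbind, lapply(names(sp), function(d) {
    r <- sp[[d]]
    q <- stats::quantile(r, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(date = as.Date(d), n = length(r), min = q[1], q1 = q[2],
               median = q[3], q3 = q[4], max = q[5], mean = mean(r),
               stringsAsFactors = FALSE)
  }))
  out[order(out$date), , drop = FALSE]
}

#' Fraction of days with song detections
#'
#' @param summaries a \code{\link{detection_summary}} data.frame covering
#'   the recording season (one or more rows per day).
#' @param min_detections a day counts as a detection day when any of its
#'   recordings reaches this many detections (default 1).
#' @return a list with \code{detection_days}, \code{total_days} and
#'   \code{fraction}.
#' @export
detection_day_fraction <- function(summaries, min_detections = 1) {
  per_day <- tapply(summaries$detections, as.character(summaries$date), max)
  k <- sum(per_day >= min_detections)
  n <- length(per_day)
  list(detection_days = as.integer(k), total_days = as.integer(n),
       fraction = k / n)
}
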