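#' Delineation configuration
#'
#' Song sequences rarely come with obvious boundaries in fragmented
#' recordings.  Delineation relies on the most likely starting phrases
#' (by default 17 and 15) and ending phrases (by default 4b and 4a) of the
#' songs, identified from the Markov analysis.
#'
#' @param start_labels tokens that typically begin a song (default
#'   \code{c("17", "15")}).
#' @param end_labels tokens that typically end a song (default
#'   \code{c("4b", "4a")}).
#' @return an object of class \code{"delineation_config"}.
#' @export
delineation_config <- function(start_labels = c("17", "15"),
                               end_labels = c("4b", "4a")) {
  validate_tokens(start_labels); validate_tokens(end_labels)
  if (!length(start_labels) || !length(end_labels))
    stop("start and end label sets must be non-empty")
  if (length(intersect(start_labels, end_labels)))
    stop("start and end label sets must be disjoint")
  structure(list(start_labels = start_labels, end_labels = end_labels),
            class = "delineation_config")
}

#' Delineate a theme-level sequence into song fragments
#'
#' Two rules split a theme-level sequence (no adjacent duplicate tokens;
#' apply \code{\link{collapse_runs}} first):
#' \enumerate{
#'   \item \strong{Boundary rule} (takes precedence): wherever an ending
#'     phrase is immediately followed by a starting phrase, the sequence is
#'     split between them.
#'   \item \strong{Repeat rule}: within each fragment, when a phrase
#'     reoccurs the fragment is terminated at the phrase directly preceding
#'     the reoccurrence, and a new fragment begins at the reoccurrence.  The
#'     scan restarts in each new fragment, so no fragment contains a
#'     duplicate phrase.
#' }
#' Transitional-flagged tokens are transparent: they neither trigger the
#' repeat rule nor form boundaries, and they travel with the fragment
#' containing the theme that precedes them.  Concatenating the fragments
#' always reproduces the input token-for-token.  An ending phrase that is
#' the final token of the sequence triggers no split (nothing follows it).
#'
#' @param seq a theme-level \code{phrase_sequence} (or coercible).
#' @param cfg a \code{\link{delineation_config}}.
#' @return an object of class \code{"delineation_result"}: a list with
#'   \code{fragments} (list of \code{phrase_sequence}) and
#'   \code{rule_applied} (character, \code{"boundary"} or \code{"repeat"},
#'   one entry per split).
#' @examples
#' d <- delineate("15-14a-13b-12-4b-15-14a", delineation_config())
#' sapply(d$fragments, format_sequence)
#' @export
delineate <- function(seq, cfg = delineation_config()) {
  seq <- as_phrase_sequence(seq)
  core_idx <- which(!seq$transitional)
  core <- seq$labels[core_idx]
  if (length(core) > 1L && any(core[-1L] == core[-length(core)]))
    stop("sequence has adjacent duplicate tokens; apply collapse_runs() first")

  # split points are positions (in core) after which a cut occurs
  cuts <- integer(0); rules <- character(0)

  # boundary rule first, on the whole sequence
  if (length(core) > 1L) {
    b <- which(core[-length(core)] %in% cfg$end_labels &
                 core[-1L] %in% cfg$start_labels)
    cuts <- b
    rules <- rep("boundary", length(b))
  }

  # repeat rule within each boundary fragment, left-to-right, restarting
  # the seen-set at every new fragment
  frag_starts <- c(1L, cuts + 1L)
  frag_ends <- c(cuts, length(core))
  for (k in seq_along(frag_starts)) {
    if (frag_ends[k] < frag_starts[k]) next
    seen <- character(0)
    for (i in frag_starts[k]:frag_ends[k]) {
      if (core[i] %in% seen) {
        cuts <- c(cuts, i - 1L)
        rules <- c(rules, "repeat")
        seen <- character(0)
      }
      seen <- c(seen, core[i])
    }
  }
  ord <- order(cuts)
  cuts <- cuts[ord]; rules <- rules[ord]

  # map core cut positions back to full-sequence positions: a transitional
  # token between theme i and theme i+1 stays with the preceding fragment
  frag_of_core <- findInterval(seq_along(core) - 1L, cuts) + 1L
  frag_of_full <- integer(length(seq$labels))
  frag_of_full[core_idx] <- frag_of_core
  last <- 1L
  for (i in seq_along(frag_of_full)) {
    if (frag_of_full[i] == 0L) frag_of_full[i] <- last else last <- frag_of_full[i]
  }

  fragments <- lapply(seq_len(length(cuts) + 1L), function(k) {
    i <- which(frag_of_full == k)
    subset_sequence(seq, i)
  })
  structure(list(fragments = fragments, rule_applied = rules,
                 config = cfg), class = "delineation_result")
}

subset_sequence <- function(seq, i) {
  phrase_sequence(
    labels = seq$labels[i], transitional = seq$transitional[i],
    start_s = if (!is.null(seq$start_s)) seq$start_s[i],
    end_s = if (!is.null(seq$end_s)) seq$end_s[i],
    recording_id = seq$recording_id, period_id = seq$period_id,
    singer_track = seq$singer_track
  )
}

#' @export
print.delineation_result <- function(x, ...) {
  cat("<delineation_result> ", length(x$fragments), " fragment(s)\n", sep = "")
  for (k in seq_along(x$fragments)) {
    cat(sprintf("  [%d] %s%s\n", k, format_sequence(x$fragments[[k]]),
                if (k <= length(x$rule_applied))
                  paste0("  | split: ", x$rule_applied[k]) else ""))
  }
  invisible(x)
}

#' Is a sequence a full song?
#'
#' Under the delineation protocol a fragment constitutes a full song when it
#' begins with a starting phrase and ends with an ending phrase.
#'
#' @param seq a theme-level \code{phrase_sequence} (or coercible).
#' @param cfg a \code{\link{delineation_config}}.
#' @return \code{TRUE} or \code{FALSE}.
#' @examples
#' is_full_song("15-14a-13b-12-4b")  # TRUE
#' is_full_song("15-14a")            # FALSE
#' @export
is_full_song <- function(seq, cfg = delineation_config()) {
  seq <- as_phrase_sequence(seq)
  core <- seq$labels[!seq$transitional]
  length(core) > 0L &&
    core[1L] %in% cfg$start_labels &&
    core[length(core)] %in% cfg$end_labels
}

#' Full song by theme recurrence
#'
#' An alternative full-song definition used for songs captured whole within
#' one sound file: a sequence is considered a full song when a theme type
#' reoccurs, and the song ends on the theme occurring directly before the
#' first reoccurrence.  Returns \code{NULL} when no theme reoccurs (no full
#' song captured).
#'
#' @param seq a theme-level \code{phrase_sequence} (or coercible).
#' @return the full-song prefix as a \code{phrase_sequence}, or \code{NULL}.
#' @examples
#' format_sequence(full_song_by_recurrence("15-14a-13b-12-4b-15"))
#' @export
full_song_by_recurrence <- function(seq) {
  seq <- as_phrase_sequence(seq)
  core_idx <- which(!seq$transitional)
  core <- seq$labels[core_idx]
  dup <- which(duplicated(core))
  if (!length(dup)) return(NULL)
  cut_full <- core_idx[dup[1L] - 1L]   # last kept position in full sequence
  subset_sequence(seq, seq_len(cut_full))
}

#' Count distinct themes in a sequence
#'
#' Counts the unique phrase tokens of a sequence, excluding
#' transitional-flagged tokens.
#'
#' @param seq a \code{phrase_sequence} (or coercible).
#' @return an integer count.
#' @export
count_distinct_themes <- function(seq) {
  seq <- as_phrase_sequence(seq)
  length(unique(seq$labels[!seq$transitional]))
}
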