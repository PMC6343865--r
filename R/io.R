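#' Write a phrase log as TSV
#'
#' The phrase-log schema is tab-separated with a header row and columns
#' \code{recording_id}, \code{date} (ISO-8601), \code{period_id},
#' \code{singer_track}, \code{label}, \code{start_s}, \code{end_s},
#' \code{is_transitional} (0/1).  Times are 0-based seconds from recording
#' start.
#'
#' @param events a \code{\link{phrase_events}} data.frame.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_phrase_log <- function(events, path) {
  df <- as.data.frame(events)
  df$date <- format(df$date, "%Y-%m-%d")
  df$is_transitional <- as.integer(df$is_transitional)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a phrase log TSV
#'
#' Validates each row; malformed rows (non-numeric or inverted times,
#' missing labels) are dropped and reported with their line numbers in the
#' \code{"diagnostics"} attribute.  Missing required columns are an error.
#'
#' @param path input file path.
#' @return a \code{\link{phrase_events}} data.frame with attribute
#'   \code{diagnostics} (character vector, empty when all rows parsed).
#' @export
read_phrase_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          na.strings = NULL)
  need <- c("recording_id", "date", "period_id", "singer_track", "label",
            "start_s", "end_s", "is_transitional")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phrase log is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (!nrow(df)) {
    out <- phrase_events(character(0), as.Date(character(0)), character(0),
                         numeric(0), numeric(0))
    attr(out, "diagnostics") <- character(0)
    return(out)
  }
  start_s <- suppressWarnings(as.numeric(df$start_s))
  end_s <- suppressWarnings(as.numeric(df$end_s))
  date <- suppressWarnings(as.Date(df$date, format = "%Y-%m-%d"))
  bad <- is.na(start_s) | is.na(end_s) | !nzchar(df$label) | is.na(date) |
    !(end_s > start_s) | start_s < 0
  diagnostics <- if (any(bad)) {
    sprintf("line %d: malformed row (%s)", which(bad) + 1L,
            df$label[bad])
  } else character(0)
  df <- df[!bad, , drop = FALSE]
  out <- phrase_events(
    df$recording_id, date[!bad], df$label, start_s[!bad], end_s[!bad],
    period_id = ifelse(nzchar(df$period_id), df$period_id, NA),
    singer_track = ifelse(nzchar(df$singer_track), df$singer_track, NA),
    is_transitional = df$is_transitional %in% c("1", "TRUE", "true")
  )
  attr(out, "diagnostics") <- diagnostics
  out
}

#' Read a selection-table TSV
#'
#' Parses the tab-separated selection-table dialect exported by
#' spectrogram-annotation tools: one row per selection with begin/end time
#' columns in seconds (\code{"Begin Time (s)"} / \code{"End Time (s)"}) and
#' a user annotation column carrying the phrase label.  Selections without
#' a label are skipped; the skip count is reported in the
#' \code{"skipped"} attribute.
#'
#' @param path input file path.
#' @param label_column name of the annotation column holding phrase labels.
#' @param recording_id recording identifier to assign (default: file name).
#' @param date recording date (default \code{NA}).
#' @param transitional_column optional 0/1 column flagging transitional
#'   phrases.
#' @return a \code{\link{phrase_events}} data.frame with attribute
#'   \code{skipped}.
#' @export
read_selection_table <- function(path, label_column,
                                 recording_id = basename(path),
                                 date = NA,
                                 transitional_column = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "",
                          colClasses = "character", na.strings = NULL)
  if (!label_column %in% names(df))
    stop("unknown label column: ", sQuote(label_column))
  begin_col <- grep("^Begin Time", names(df), value = TRUE)
  end_col <- grep("^End Time", names(df), value = TRUE)
  if (!length(begin_col) || !length(end_col))
    stop("selection table lacks Begin/End Time columns")
  labs <- trimws(df[[label_column]])
  keep <- nzchar(labs)
  trans <- if (!is.null(transitional_column))
    df[[transitional_column]][keep] %in% c("1", "TRUE", "true") else FALSE
  out <- phrase_events(
    recording_id, date, labs[keep],
    start_s = as.numeric(df[[begin_col[1L]]][keep]),
    end_s = as.numeric(df[[end_col[1L]]][keep]),
    is_transitional = trans
  )
  attr(out, "skipped") <- sum(!keep)
  out
}

#' Run configuration for the song-analysis pipeline
#'
#' @param delineation a \code{\link{delineation_config}}.
#' @param markov a \code{\link{markov_config}}.
#' @param consistency a \code{\link{consistency_config}}.
#' @param min_transitions similarity-analysis filter: minimum phrase
#'   transitions per sequence (default 4).
#' @param cluster_threshold dissimilarity cut height for reporting cluster
#'   membership (default 0.6, i.e. similarity >= 0.4 within clusters).
#' @param seed integer seed echoed into every output.
#' @param output_dir optional directory; when set, report files are written.
#' @return an object of class \code{"run_config"}.
#' @export
run_config <- function(delineation = delineation_config(),
                       markov = markov_config(),
                       consistency = consistency_config(),
                       min_transitions = 4L,
                       cluster_threshold = 0.6,
                       seed = 1L,
                       output_dir = NULL) {
  structure(list(delineation = delineation, markov = markov,
                 consistency = consistency,
                 min_transitions = as.integer(min_transitions),
                 cluster_threshold = cluster_threshold,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Run the full song-analysis pipeline
#'
#' Orchestrates the analysis end to end: groups events into periods, builds
#' theme-level sequences (collapsing repeated phrases), delineates them into
#' song fragments, and runs the Markov, consistency, similarity and singer
#' analyses.  The result bundles a corpus summary, the per-phrase
#' consistency table, per-period transition matrices with common full-song
#' paths, per-period set medians (with the Kohonen-median check), the LSI
#' similarity matrix of the period representatives with its single-linkage
#' dendrogram and cluster memberships, the Dice phrase-sharing matrix
#' between periods, and per-recording minimum singer counts.  Given the same
#' inputs and configuration the result is deterministic.  When
#' \code{config$output_dir} is set, CSV/TSV/Newick/JSON artifacts are
#' written there with the seed echoed.
#'
#' @param events a \code{\link{phrase_events}} table.
#' @param spec a \code{\link{period_spec}}.
#' @param config a \code{\link{run_config}}.
#' @return an object of class \code{"song_analysis"}.
#' @export
run_pipeline <- function(events, spec, config = run_config()) {
  periods <- group_into_periods(events, spec)
  pids <- vapply(periods, `[[`, "", "period_id")

  theme_seqs <- lapply(periods, function(ps)
    lapply(ps$sequences, collapse_runs))
  names(theme_seqs) <- pids

  fragments <- lapply(theme_seqs, function(seqs) {
    unlist(lapply(seqs, function(s)
      delineate(s, config$delineation)$fragments), recursive = FALSE)
  })

  matrices <- lapply(fragments, build_transition_matrix)
  names(matrices) <- pids
  common_paths <- lapply(matrices, function(m) {
    if (!length(m$states) || m$n_transitions == 0) return(list())
    extract_common_paths(m, config$markov, config$delineation)
  })

  cons <- tryCatch(consistency_table(matrices, config$consistency),
                   error = function(e) NULL)

  # the edit-distance stage uses sequences as extracted from the
  # recordings (phrase level, min_transitions filter) collapsed to themes
  medians <- list(); skipped_periods <- character(0)
  raw_seqs <- stats::setNames(lapply(periods, `[[`, "sequences"), pids)
  for (pid in pids) {
    eligible <- lapply(
      filter_min_transitions(raw_seqs[[pid]], config$min_transitions),
      collapse_runs)
    if (length(eligible) < 2L) {
      skipped_periods <- c(skipped_periods, pid)
      warning("period ", pid, ": fewer than 2 sequences pass the ",
              config$min_transitions, "-transition filter; ",
              "similarity stage skipped", call. = FALSE)
      next
    }
    sm <- set_median(eligible)
    medians[[pid]] <- kohonen_median(eligible, sm)
    attr(medians[[pid]], "n_sequences") <- length(eligible)
  }

  sim <- NULL; tree <- NULL; clusters <- NULL
  if (length(medians) >= 2L) {
    sim <- similarity_matrix(lapply(medians, `[[`, "median"))
    tree <- single_linkage(as_dissimilarity(sim))
    clusters <- cut_clusters(tree, config$cluster_threshold)
  }

  dice <- dice_matrix(stats::setNames(
    lapply(periods, `[[`, "phrase_inventory"), pids))

  singer_counts <- do.call(rbind, lapply(periods, function(ps) {
    recs <- split(seq_len(nrow(ps$events)), ps$events$recording_id)
    do.call(rbind, lapply(names(recs), function(rid) {
      ev <- ps$events[recs[[rid]], , drop = FALSE]
      class(ev) <- class(ps$events)
      data.frame(period_id = ps$period_id, recording_id = rid,
                 n_events = nrow(ev), min_singers = min_singers(ev),
                 stringsAsFactors = FALSE)
    }))
  }))

  summary_tab <- do.call(rbind, lapply(periods, function(ps) {
    data.frame(
      period_id = ps$period_id,
      n_days = length(ps$dates),
      n_recordings = length(unique(ps$events$recording_id)),
      n_events = nrow(ps$events),
      n_sequences = length(ps$sequences),
      n_ld_sequences = length(filter_min_transitions(
        ps$sequences, config$min_transitions)),
      stringsAsFactors = FALSE)
  }))

  res <- structure(list(
    summary = summary_tab,
    consistency = cons,
    matrices = matrices,
    common_paths = common_paths,
    medians = medians,
    similarity = sim,
    dendrogram = tree,
    clusters = clusters,
    dice = dice,
    singers = singer_counts,
    transitional_fraction = transitional_fraction(events),
    skipped_periods = skipped_periods,
    config = config,
    seed = config$seed
  ), class = "song_analysis")

  if (!is.null(config$output_dir)) write_report(res, config$output_dir)
  res
}

#' @export
print.song_analysis <- function(x, ...) {
  cat("<song_analysis> ", nrow(x$summary), " period(s), ",
      sum(x$summary$n_events), " event(s), ",
      sum(x$summary$n_sequences), " sequence(s)\n", sep = "")
  cat("transitional fraction: ",
      sprintf("%.1f%%", 100 * x$transitional_fraction), "\n", sep = "")
  for (pid in names(x$medians)) {
    cat("period ", pid, " median: ",
        format_sequence(x$medians[[pid]]$median),
        " (", x$medians[[pid]]$source, ")\n", sep = "")
  }
  if (!is.null(x$similarity))
    cat("min pairwise LSI among period medians: ",
        sprintf("%.2f", min(x$similarity)), "\n", sep = "")
  invisible(x)
}

#' @export
summary.song_analysis <- function(object, ...) {
  cat("Corpus summary\n"); print(object$summary)
  if (!is.null(object$consistency)) {
    cat("\nTransition consistency (static/shifting)\n")
    print(object$consistency)
  }
  if (!is.null(object$similarity)) {
    cat("\nLSI similarity of period medians\n")
    print(round(unclass(object$similarity), 3))
    cat("\nClusters at dissimilarity <= ", object$config$cluster_threshold,
        ":\n", sep = "")
    print(object$clusters)
  }
  cat("\nDice phrase sharing between periods\n")
  print(round(object$dice, 3))
  invisible(object)
}

write_report <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- list(seed = res$seed,
                config_hash = config_hash(res$config))
  jsonlite::write_json(stamp, file.path(dir, "run_info.json"),
                       auto_unbox = TRUE)
  utils::write.csv(cbind(res$summary, seed = res$seed),
                   file.path(dir, "corpus_summary.csv"), row.names = FALSE)
  if (!is.null(res$consistency))
    utils::write.csv(cbind(res$consistency, seed = res$seed),
                     file.path(dir, "consistency.csv"), row.names = FALSE)
  for (pid in names(res$matrices))
    export_transition_matrix(res$matrices[[pid]],
                             file.path(dir, paste0("markov_period_", pid)),
                             res$config$markov)
  med <- do.call(rbind, lapply(names(res$medians), function(pid) {
    m <- res$medians[[pid]]
    paths <- vapply(res$common_paths[[pid]], format_sequence, "")
    data.frame(period_id = pid, set_median = format_sequence(m$median),
               source = m$source, summed_distance = m$summed_distance,
               common_markov_paths = paste(paths, collapse = "; "),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(med))
    utils::write.csv(cbind(med, seed = res$seed),
                     file.path(dir, "medians.csv"), row.names = FALSE)
  if (!is.null(res$similarity)) {
    utils::write.csv(unclass(res$similarity),
                     file.path(dir, "lsi_similarity.csv"))
    utils::write.csv(1 - unclass(res$similarity),
                     file.path(dir, "lsi_dissimilarity.csv"))
    dendrogram_newick(res$dendrogram, file.path(dir, "dendrogram.nwk"))
  }
  utils::write.csv(res$dice, file.path(dir, "dice.csv"))
  utils::write.csv(cbind(res$singers, seed = res$seed),
                   file.path(dir, "singers.csv"), row.names = FALSE)
  invisible(dir)
}

config_hash <- function(config) {
  # stable digest of the serialized analysis configuration (no external
  # deps); the output directory is a run location, not an analysis
  # parameter, so it is excluded
  config$output_dir <- NULL
  raw <- serialize(config, NULL, version = 2)
  sum(as.integer(raw) * (seq_along(raw) %% 251 + 1)) %% .Machine$integer.max
}
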