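#' Markov analysis configuration
#'
#' @param min_prob_common probability threshold above which a transition is
#'   considered "common" (default 0.05, i.e. transitions occurring a minimum
#'   of 5\% of the time from their source phrase).
#' @return an object of class \code{"markov_config"}.
#' @export
markov_config <- function(min_prob_common = 0.05) {
  if (!is.numeric(min_prob_common) || min_prob_common <= 0 ||
      min_prob_common >= 1)
    stop("min_prob_common must lie in (0, 1)")
  structure(list(min_prob_common = min_prob_common), class = "markov_config")
}

#' Build a first-order transition matrix from theme sequences
#'
#' Counts every adjacent ordered pair of themes within each sequence; no
#' transitions are counted across sequence boundaries.  Transitional-flagged
#' tokens are collapsed: a transition x -> t -> y (t transitional) is counted
#' once as x -> y, since a transitional phrase marks the boundary of the
#' x-to-y transition rather than a state of its own.  Probabilities are the
#' row-normalized counts.
#'
#' @param sequences list of theme-level \code{phrase_sequence} objects (or
#'   coercibles).
#' @return an object of class \code{"transition_matrix"}: a list with
#'   \code{states} (ordered tokens), \code{counts} and \code{probabilities}
#'   (square matrices), and \code{n_transitions}.
#' @examples
#' m <- build_transition_matrix(list(c("a", "b"), c("a", "b"), c("a", "c")))
#' m$probabilities["a", ]
#' @export
build_transition_matrix <- function(sequences) {
  seqs <- lapply(sequences, as_phrase_sequence)
  cores <- lapply(seqs, function(s) s$labels[!s$transitional])
  states <- sort(unique(unlist(cores)))
  n <- length(states)
  counts <- matrix(0L, n, n, dimnames = list(from = states, to = states))
  for (core in cores) {
    if (length(core) < 2L) next
    for (i in seq_len(length(core) - 1L))
      counts[core[i], core[i + 1L]] <- counts[core[i], core[i + 1L]] + 1L
  }
  rs <- rowSums(counts)
  probabilities <- counts / ifelse(rs > 0, rs, 1)
  probabilities[rs == 0, ] <- 0
  structure(list(states = states, counts = counts,
                 probabilities = probabilities,
                 n_transitions = sum(counts)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, digits = 3, ...) {
  cat("<transition_matrix> ", length(x$states), " state(s), ",
      x$n_transitions, " transition(s)\n", sep = "")
  if (length(x$states)) print(round(x$probabilities, digits))
  invisible(x)
}

#' @export
summary.transition_matrix <- function(object, ...) {
  rs <- rowSums(object$counts)
  data.frame(state = object$states, n_out = as.integer(rs),
             n_successors = as.integer(rowSums(object$counts > 0)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate theme sequences from a transition matrix
#'
#' Draws sequences by walking the chain from a uniformly chosen start label
#' until an end label (absorbing) is reached or \code{max_len} themes have
#' been emitted.
#'
#' @param object a \code{transition_matrix}.
#' @param nsim number of sequences to draw.
#' @param seed optional integer seed.
#' @param cfg a \code{\link{delineation_config}} naming start/end labels.
#' @param max_len maximum sequence length (guards non-absorbing chains).
#' @param ... unused.
#' @return a list of \code{phrase_sequence} objects.
#' @export
simulate.transition_matrix <- function(object, nsim = 1, seed = NULL,
                                       cfg = delineation_config(),
                                       max_len = 50L, ...) {
  if (!is.null(seed)) set.seed(seed)
  starts <- intersect(cfg$start_labels, object$states)
  if (!length(starts)) stop("no start label present among the states")
  replicate(nsim, {
    cur <- sample(starts, 1L)
    out <- cur
    while (!(cur %in% cfg$end_labels) && length(out) < max_len) {
      p <- object$probabilities[cur, ]
      if (sum(p) <= 0) break
      cur <- sample(object$states, 1L, prob = p)
      out <- c(out, cur)
    }
    phrase_sequence(out)
  }, simplify = FALSE)
}

#' Extract common full-song paths from a transition matrix
#'
#' Enumerates all acyclic paths from any start label to any end label using
#' only transitions at or above the common-transition probability threshold.
#' For completeness, maximal qualifying paths beginning at non-start states
#' (states with no common incoming transition) are also returned: fragmented
#' recordings often capture songs mid-cycle, so common sequences such as
#' \code{14a-13b-12-4b} legitimately begin away from a start label.  Paths
#' are ordered by the product of their transition probabilities, descending,
#' with ties broken by lexicographic token order.
#'
#' @param m a \code{transition_matrix}.
#' @param cfg a \code{\link{markov_config}}.
#' @param delin a \code{\link{delineation_config}} naming start/end labels.
#' @param include_partial also return maximal paths from non-start states
#'   (default \code{TRUE}).
#' @return a list of \code{phrase_sequence} objects, each with attributes
#'   \code{prob} (path probability product) and \code{from_start} (logical).
#' @export
extract_common_paths <- function(m, cfg = markov_config(),
                                 delin = delineation_config(),
                                 include_partial = TRUE) {
  if (!length(m$states)) stop("empty transition matrix")
  thr <- cfg$min_prob_common
  adj <- m$probabilities >= thr & m$counts > 0
  states <- m$states
  ends <- intersect(delin$end_labels, states)
  starts <- intersect(delin$start_labels, states)

  paths <- list(); probs <- numeric(0); from_start <- logical(0)
  dfs <- function(path, prob) {
    cur <- path[length(path)]
    if (cur %in% ends) {
      paths[[length(paths) + 1L]] <<- path
      probs <<- c(probs, prob)
      return(invisible())
    }
    nxt <- states[adj[cur, ]]
    for (s in setdiff(nxt, path))
      dfs(c(path, s), prob * m$probabilities[cur, s])
  }
  for (s in starts) dfs(s, 1)
  n_start_paths <- length(paths)

  if (include_partial) {
    partial_roots <- setdiff(states[colSums(adj) == 0], c(starts, ends))
    for (s in partial_roots) dfs(s, 1)
  }
  from_start <- c(rep(TRUE, n_start_paths),
                  rep(FALSE, length(paths) - n_start_paths))

  if (!length(paths)) return(list())
  keys <- vapply(paths, paste, "", collapse = "\r")
  ord <- order(-probs, keys)
  lapply(ord, function(i) {
    s <- phrase_sequence(paths[[i]])
    attr(s, "prob") <- probs[i]
    attr(s, "from_start") <- from_start[i]
    s
  })
}

#' Fraction of transitional phrases in an event log
#'
#' Transitional phrases are hybrid phrases marking theme boundaries; their
#' prevalence quantifies how often theme changes are acoustically bridged.
#'
#' @param events a \code{phrase_events} data.frame (non-empty).
#' @return the fraction of events flagged transitional, in [0, 1].
#' @export
transitional_fraction <- function(events) {
  if (!nrow(events)) stop("transitional fraction undefined for empty input")
  mean(events$is_transitional)
}

#' Export a transition matrix as labeled tables
#'
#' Writes counts and probabilities as labeled CSV files (rows = from-state,
#' columns = to-state) and an edge list (from, to, count, probability,
#' common flag) for graph rendering.
#'
#' @param m a \code{transition_matrix}.
#' @param path_prefix file prefix; files \code{<prefix>_counts.csv},
#'   \code{<prefix>_probabilities.csv} and \code{<prefix>_edges.csv} are
#'   written.
#' @param cfg a \code{\link{markov_config}} used for the common flag.
#' @return invisibly, the edge-list data.frame.
#' @export
export_transition_matrix <- function(m, path_prefix,
                                     cfg = markov_config()) {
  utils::write.csv(m$counts, paste0(path_prefix, "_counts.csv"))
  utils::write.csv(m$probabilities, paste0(path_prefix, "_probabilities.csv"))
  idx <- which(m$counts > 0, arr.ind = TRUE)
  edges <- data.frame(
    from = m$states[idx[, 1L]], to = m$states[idx[, 2L]],
    count = m$counts[idx], probability = m$probabilities[idx],
    common = m$probabilities[idx] >= cfg$min_prob_common,
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  utils::write.csv(edges, paste0(path_prefix, "_edges.csv"), row.names = FALSE)
  invisible(edges)
}
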