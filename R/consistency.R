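#' Consistency-test configuration
#'
#' @param alpha significance level used to classify phrases (default 0.05).
#' @param mc_replicates Monte-Carlo replicate count for tables too large for
#'   complete enumeration (default 1e5).
#' @param mc_seed integer seed for the Monte-Carlo p-value (default 1).
#' @param workspace workspace size for the exact network algorithm.
#' @return an object of class \code{"consistency_config"}.
#' @export
consistency_config <- function(alpha = 0.05, mc_replicates = 1e5,
                               mc_seed = 1L, workspace = 2e7,
                               enumeration_bound = 1e7) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(alpha = alpha, mc_replicates = as.integer(mc_replicates),
                 mc_seed = as.integer(mc_seed), workspace = workspace,
                 enumeration_bound = enumeration_bound),
            class = "consistency_config")
}

# upper bound on the number of candidate tables sharing the row margins:
# tables are enumerated exactly only when this stays below the configured
# bound, otherwise the Monte-Carlo estimate is used
n_candidate_tables <- function(tab) {
  k <- ncol(tab)
  prod(vapply(rowSums(tab), function(r) choose(r + k - 1, k - 1), 0))
}

#' Build a period-by-successor contingency table for one phrase
#'
#' The null hypothesis of transition consistency is that a phrase
#' transitions proportionally the same to the same successors in all
#' periods.  The table has one row per period and one column per successor
#' observed in at least one period; cell (p, y) counts transitions
#' focal -> y during period p.  All-zero rows (periods where the focal
#' phrase never transitions) are dropped.
#'
#' @param focal the phrase token under test.
#' @param periods a named list of \code{transition_matrix} objects, one per
#'   period (names are the period ids), or a list of
#'   \code{(period_id, matrix)} pairs.
#' @return a matrix of counts with class \code{"contingency_table"} and
#'   attribute \code{focal}.
#' @export
build_contingency <- function(focal, periods) {
  if (is.null(names(periods)) || any(!nzchar(names(periods))))
    stop("periods must be a named list of transition matrices")
  rows <- lapply(periods, function(m) {
    if (!focal %in% m$states) return(NULL)
    cnt <- m$counts[focal, ]
    cnt[cnt > 0]
  })
  rows <- Filter(function(r) !is.null(r) && length(r) && sum(r) > 0, rows)
  if (!length(rows))
    stop("phrase ", sQuote(focal), " never observed as a transition source")
  successors <- sort(unique(unlist(lapply(rows, names))))
  tab <- matrix(0L, length(rows), length(successors),
                dimnames = list(period = names(rows),
                                successor = successors))
  for (p in names(rows)) tab[p, names(rows[[p]])] <- as.integer(rows[[p]])
  structure(tab, focal = focal, class = c("contingency_table", class(tab)))
}

#' Fisher's exact test for an r x c contingency table
#'
#' Tests the independence of rows (periods) and columns (successor phrases)
#' conditionally on the margins, i.e. the Freeman-Halton generalization of
#' Fisher's exact test.  The two-sided p-value sums the probabilities of all
#' tables with the observed margins whose probability does not exceed the
#' observed table's.  Complete enumeration (the network algorithm) is used
#' when feasible; otherwise a fixed-seed Monte-Carlo estimate with
#' \code{mc_replicates} replicates is returned and flagged in the
#' \code{"method"} attribute.  Degenerate tables (a single row or a single
#' column) carry no information about inconsistency and return p = 1,
#' flagged \code{"degenerate"}.
#'
#' @param tab an integer matrix of counts (rows = periods, columns =
#'   successors), e.g. from \code{\link{build_contingency}}.
#' @param cfg a \code{\link{consistency_config}}.
#' @return the p-value in [0, 1], with attribute \code{method} one of
#'   \code{"exact"}, \code{"monte_carlo"} or \code{"degenerate"}.
#' @examples
#' fisher_exact_rc(matrix(c(2, 0, 0, 2), 2))  # 1/3
#' @export
fisher_exact_rc <- function(tab, cfg = consistency_config()) {
  tab <- as.matrix(tab)
  storage.mode(tab) <- "integer"
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    return(structure(1, method = "degenerate"))
  p <- NULL
  if (n_candidate_tables(tab) <= cfg$enumeration_bound) {
    p <- tryCatch({
      res <- stats::fisher.test(tab, workspace = cfg$workspace)
      structure(min(1, res$p.value), method = "exact")
    }, error = function(e) NULL)
  }
  if (is.null(p)) {
    p <- withr_seed(cfg$mc_seed, {
      res <- stats::fisher.test(tab, simulate.p.value = TRUE,
                                B = cfg$mc_replicates)
      structure(min(1, res$p.value), method = "monte_carlo",
                replicates = cfg$mc_replicates)
    })
  }
  p
}

# evaluate expr under a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Classify a phrase as static or shifting
#'
#' A phrase whose successor distribution differs significantly between
#' periods (p below \code{alpha}) is a shifting phrase; otherwise it is
#' static.  The boundary p = alpha is classified static (strict inequality).
#'
#' @param p_value p-value from \code{\link{fisher_exact_rc}}.
#' @param cfg a \code{\link{consistency_config}}.
#' @return \code{"shifting"} or \code{"static"}.
#' @export
classify_phrase <- function(p_value, cfg = consistency_config()) {
  if (is.na(p_value) || p_value < 0 || p_value > 1)
    stop("p_value must lie in [0, 1]")
  if (p_value < cfg$alpha) "shifting" else "static"
}

#' Transition-consistency table across periods
#'
#' Runs \code{\link{build_contingency}}, \code{\link{fisher_exact_rc}} and
#' \code{\link{classify_phrase}} for every phrase observed as a transition
#' source in any period, producing a per-phrase results table: token,
#' transition occurrence count, raw p-value, Holm-adjusted p-value (reported
#' for reference; classification uses the raw p-value) and classification.
#'
#' @param periods named list of per-period \code{transition_matrix} objects.
#' @param cfg a \code{\link{consistency_config}}.
#' @return a data.frame with columns \code{token}, \code{occurrences},
#'   \code{p_value}, \code{p_holm}, \code{method}, \code{classification}.
#' @export
consistency_table <- function(periods, cfg = consistency_config()) {
  tokens <- sort(unique(unlist(lapply(periods, function(m)
    m$states[rowSums(m$counts) > 0]))))
  rows <- lapply(tokens, function(tok) {
    tab <- build_contingency(tok, periods)
    p <- fisher_exact_rc(tab, cfg)
    data.frame(token = tok, occurrences = sum(tab),
               p_value = as.numeric(p), method = attr(p, "method"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  out$classification <- vapply(out$p_value, classify_phrase, "", cfg = cfg)
  out[, c("token", "occurrences", "p_value", "p_holm", "method",
          "classification")]
}
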