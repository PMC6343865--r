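#' Token-level Levenshtein distance between phrase sequences
#'
#' The minimum number of single-token insertions, deletions and
#' substitutions (unit cost each) needed to transform one sequence of
#' phrases into another.  Edits operate on whole phrase tokens, never on
#' characters: the phrases are the symbols of the song.
#'
#' @param a,b \code{phrase_sequence} objects or character vectors of tokens
#'   (hyphen-joined strings are parsed).  Either may be empty, in which case
#'   the distance is the other's length.
#' @return a non-negative integer.
#' @examples
#' levenshtein("14a-13b-12-4b", "17-14a-13b-12-4b")  # 1 insertion
#' @export
levenshtein <- function(a, b) {
  a <- seq_tokens(a); b <- seq_tokens(b)
  n <- length(a); m <- length(b)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1L] <- i
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L,          # deletion
                         cur[j] + 1L,                # insertion
                         prev[j] + (a[i] != b[j]))   # substitution/match
    }
    prev <- cur
  }
  as.integer(prev[m + 1L])
}

# tokens of a sequence-like object (transitional tokens excluded:
# edit-distance analysis is over themes, not boundary markers)
seq_tokens <- function(x) {
  if (inherits(x, "phrase_sequence")) return(x$labels[!x$transitional])
  if (is.character(x) && length(x) == 1L && grepl(WS_SEPARATOR, x, fixed = TRUE))
    return(strsplit(trimws(x), WS_SEPARATOR, fixed = TRUE)[[1L]])
  as.character(x)
}

#' Set median of a set of phrase sequences
#'
#' The set median (SM) is the member of a set with the smallest summed
#' Levenshtein distance to all other members; it serves as the
#' representative sequence of a period.  Ties are broken deterministically:
#' smaller summed distance first, then shorter length, then lexicographic
#' token order.
#'
#' @param seqs non-empty list of sequences (coercibles accepted).
#' @return an object of class \code{"set_median_result"}: a list with
#'   \code{median} (a \code{phrase_sequence}), \code{summed_distance},
#'   \code{source} (\code{"set_median"}) and \code{candidate_distances}
#'   (summed distance of every member).
#' @export
set_median <- function(seqs) {
  if (!length(seqs)) stop("set median undefined for an empty set")
  toks <- lapply(seqs, seq_tokens)
  n <- length(toks)
  d <- matrix(0L, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- levenshtein(toks[[i]], toks[[j]])
  }
  sums <- rowSums(d)
  keys <- vapply(toks, paste, "", collapse = "\r")
  ord <- order(sums, lengths(toks), keys)
  best <- ord[1L]
  structure(list(
    median = as_phrase_sequence(toks[[best]]),
    summed_distance = as.integer(sums[best]),
    source = "set_median",
    candidate_distances = as.integer(sums)
  ), class = "set_median_result")
}

#' @export
print.set_median_result <- function(x, ...) {
  cat("<", x$source, "> ", format_sequence(x$median),
      "  (summed LD ", x$summed_distance, ")\n", sep = "")
  invisible(x)
}

#' Kohonen median: hypothetical improvement of the set median
#'
#' Starting from the set median, systematically substitutes each position
#' with every phrase found within the set and keeps the single substitution
#' that most reduces the summed Levenshtein distance (steepest descent,
#' incumbent kept on ties).  By default the search iterates until no
#' substitution improves; \code{mode = "single_pass"} stops after one
#' substitution round.  If the resulting hypothetical sequence has a
#' strictly smaller summed distance than the set median it is reported with
#' \code{source = "kohonen_median"}; otherwise the set median stands.
#'
#' @param seqs the set of sequences the median represents.
#' @param start the \code{\link{set_median}} of \code{seqs} (computed if
#'   omitted).
#' @param mode \code{"converge"} (default) or \code{"single_pass"}.
#' @return a \code{set_median_result} with \code{source} set to
#'   \code{"kohonen_median"} only when the hill-climb strictly improved on
#'   the set median.
#' @export
kohonen_median <- function(seqs, start = set_median(seqs),
                           mode = c("converge", "single_pass")) {
  mode <- match.arg(mode)
  toks <- lapply(seqs, seq_tokens)
  alphabet <- sort(unique(unlist(toks)))
  cur <- seq_tokens(start$median)
  cur_sum <- sum(vapply(toks, levenshtein, 0L, b = cur))

  # steepest descent: strict improvement required, and among equally good
  # substitutions the first in (position, lexicographic token) scan order
  # wins, so the search is deterministic and keeps the incumbent on ties
  repeat {
    best_sub <- NULL; best_sum <- cur_sum
    for (pos in seq_along(cur)) for (tok in alphabet) {
      if (tok == cur[pos]) next
      cand <- cur; cand[pos] <- tok
      s <- sum(vapply(toks, levenshtein, 0L, b = cand))
      if (s < best_sum) { best_sub <- list(pos = pos, tok = tok); best_sum <- s }
    }
    if (is.null(best_sub)) break
    cur[best_sub$pos] <- best_sub$tok
    cur_sum <- best_sum
    if (mode == "single_pass") break
  }

  if (cur_sum < start$summed_distance) {
    structure(list(median = as_phrase_sequence(cur),
                   summed_distance = as.integer(cur_sum),
                   source = "kohonen_median",
                   candidate_distances = start$candidate_distances),
              class = "set_median_result")
  } else {
    start
  }
}

#' Levenshtein similarity index (LSI)
#'
#' Normalizes the Levenshtein distance against the longer of the two
#' sequences: \code{LSI = 1 - LD / max(|a|, |b|)}.  The index ranges from 0
#' (no similarity) to 1 (identical), and makes comparisons independent of
#' sequence length so that phrase composition and order drive the score.
#'
#' @param a,b sequences (coercibles accepted); at least one non-empty.
#' @return a similarity in [0, 1].
#' @examples
#' lsi("14a-13b-12-4b", "17-14a-13b-12-4b")  # 0.8
#' @export
lsi <- function(a, b) {
  a <- seq_tokens(a); b <- seq_tokens(b)
  L <- max(length(a), length(b))
  if (L == 0L) stop("LSI undefined when both sequences are empty")
  1 - levenshtein(a, b) / L
}

#' Pairwise LSI similarity matrix
#'
#' @param items non-empty list (>= 2) of sequences; names, when present,
#'   become the item ids and must be unique.
#' @return a symmetric numeric matrix of class \code{"similarity_matrix"}
#'   with unit diagonal.
#' @export
similarity_matrix <- function(items) {
  if (length(items) < 2L) stop("need at least two items")
  ids <- names(items)
  if (is.null(ids)) ids <- paste0("seq", seq_along(items))
  if (anyDuplicated(ids)) stop("duplicate item ids")
  toks <- lapply(items, seq_tokens)
  n <- length(toks)
  s <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    s[i, j] <- s[j, i] <- lsi(toks[[i]], toks[[j]])
  structure(s, class = c("similarity_matrix", class(s)))
}

#' Convert an LSI similarity matrix to dissimilarity form
#'
#' Dissimilarity is 1 minus similarity: zero diagonal, values in [0, 1].
#'
#' @param s a \code{similarity_matrix}.
#' @return a \code{\link[stats]{dist}} object.
#' @export
as_dissimilarity <- function(s) {
  stats::as.dist(1 - unclass(s))
}

#' Single-linkage clustering of a dissimilarity matrix
#'
#' Agglomerative nearest-neighbor clustering: at each step the two clusters
#' with the smallest single-link (minimum pairwise) dissimilarity merge at
#' that height.  Merge heights are non-decreasing, so cutting the tree at a
#' threshold yields clusters whose between-cluster single-link distance
#' exceeds the threshold.
#'
#' @param d a \code{dist} dissimilarity (see \code{\link{as_dissimilarity}})
#'   or a symmetric matrix in dissimilarity form.
#' @return an \code{\link[stats]{hclust}} tree.
#' @export
single_linkage <- function(d) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(unclass(d))))
      stop("dissimilarity matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  stats::hclust(d, method = "single")
}

#' Cut a single-linkage tree into clusters
#'
#' @param tree an \code{hclust} from \code{\link{single_linkage}}.
#' @param h dissimilarity threshold; items merged at height <= h share a
#'   cluster.
#' @return integer cluster memberships named by item id.
#' @export
cut_clusters <- function(tree, h) {
  stats::cutree(tree, h = h)
}

#' Export a dendrogram as a Newick tree
#'
#' Branch lengths equal merge-height differences, so root-to-leaf path
#' lengths reproduce the merge heights.
#'
#' @param tree an \code{hclust}.
#' @param path optional file path; when given the Newick string is written
#'   there.
#' @return the Newick string, invisibly when written to a file.
#' @export
dendrogram_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Dice's similarity index of phrase sharing
#'
#' \code{SI = 2A / (B + C)} where A is the number of phrase types shared by
#' the two inventories and B, C are the inventory sizes.  The index ignores
#' sequential structure: it measures repertoire sharing only.  It equals 1
#' only for identical inventories and 0 for disjoint ones.
#'
#' @param inv1,inv2 character vectors of phrase tokens (duplicates
#'   ignored); not both empty.
#' @return a similarity in [0, 1].
#' @examples
#' dice_similarity(c("a", "b", "c"), c("b", "c", "d"))  # 2*2/(3+3)
#' @export
dice_similarity <- function(inv1, inv2) {
  inv1 <- unique(as.character(inv1)); inv2 <- unique(as.character(inv2))
  B <- length(inv1); C <- length(inv2)
  if (B + C == 0L) stop("Dice index undefined for two empty inventories")
  A <- length(intersect(inv1, inv2))
  2 * A / (B + C)
}

#' Pairwise Dice matrix between period inventories
#'
#' @param inventories named list of token vectors (one per period).
#' @return a symmetric matrix of Dice indices with unit diagonal.
#' @export
dice_matrix <- function(inventories) {
  ids <- names(inventories)
  if (is.null(ids)) ids <- paste0("period", seq_along(inventories))
  n <- length(inventories)
  m <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    m[i, j] <- m[j, i] <- dice_similarity(inventories[[i]], inventories[[j]])
  m
}

#' Filter sequences for similarity analysis
#'
#' Small sequence fragments are unlikely representatives of song sequences;
#' only sequences with at least \code{min_transitions} phrase transitions
#' (i.e. \code{min_transitions + 1} logged phrases, transitional phrases
#' included) enter the edit-distance analysis.  The filter is applied to
#' sequences as extracted from the recordings, before repeated phrases are
#' collapsed into themes.
#'
#' @param seqs list of sequences.
#' @param min_transitions minimum number of phrase transitions (default 4).
#' @return the filtered list.
#' @export
filter_min_transitions <- function(seqs, min_transitions = 4L) {
  n_tokens <- function(s) {
    if (inherits(s, "phrase_sequence")) length(s$labels)
    else length(seq_tokens(s))
  }
  Filter(function(s) n_tokens(s) >= min_transitions + 1L, seqs)
}
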