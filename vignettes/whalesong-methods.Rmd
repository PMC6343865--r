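---
title: "Methods: symbolic analysis of humpback song phrase sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: symbolic analysis of humpback song phrase sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whalesong)
```

## The model

The package works on one data type: a table of **phrase events**
(`phrase_events()`), each a labelled, timed interval `[start_s, end_s)`
within a recording, optionally assigned to a singer track and flagged as
transitional. Everything downstream is symbolic:

- a **phrase sequence** is the time-ordered label vector of one recording
  (or one singer track within it), written in hyphen notation, e.g.
  `15-14a-13b-12-4b`;
- a **theme sequence** is the phrase sequence with adjacent repeats merged
  (`collapse_runs()`), since a theme is by definition a run of repeated
  phrases of one type;
- a **transitional phrase** `t(x>y)` is a hybrid marking the boundary
  between themes `x` and `y`. It attributes both themes to one singer but
  is not itself a theme, so it is excluded from theme counting, Markov
  states (an `x -> t(x>y) -> y` step counts as `x -> y`), and edit
  distances, while still counting toward the phrase-level sequence-length
  filter.

Assumptions worth stating: phrase labels are taken as given (the package
starts after acoustic classification); themes are first-order Markov within
a period; recordings on days at least 24 hours apart sample different
singers (`validate_independence()` audits a calendar against this, using
gaps between recording start times); and sequences within one period are
pooled when fitting that period's transition matrix, because individual
recordings rarely contain enough transitions to fit alone.

## Delineation

`delineate()` splits a collapsed sequence into song fragments with two
rules. The **boundary rule** cuts between an ending phrase (`4b`, `4a` by
default) and an immediately following starting phrase (`17`, `15`); it
takes precedence. The **repeat rule** then scans each remaining fragment
left to right and cuts before the first reoccurrence of any phrase already
seen in that fragment, restarting the seen-set after each cut. An ending
phrase as the final token is a no-op (there is nothing after it to cut
from). Transitional phrases attach to the fragment of the preceding core
phrase. Concatenating the fragments always restores the input.

A cut can satisfy both rules at once (an `end -> start` adjacency where the
starting phrase is also a reoccurrence); the fragment boundaries are
identical either way and the result records it under the precedence-taking
boundary rule.

Two full-song notions are provided: `is_full_song()` (begins with a
starting phrase and ends with an ending phrase) and
`full_song_by_recurrence()` (the prefix before the first phrase
reoccurrence, the natural "one pass through the song" reading).

## Markov stage

`build_transition_matrix()` counts first-order transitions over the pooled
theme sequences of a period and row-normalizes. `extract_common_paths()`
walks the graph of transitions with probability at least
`min_prob_common = 0.05` (and nonzero count), depth-first and acyclic, from
every starting phrase; with `include_partial = TRUE` it also roots paths at
states with no qualifying inbound edge, so common partial songs that never
begin with a canonical starting phrase are still reported. The 5% floor
keeps the path set to transitions seen repeatedly rather than once.

## Consistency stage

For each phrase, `build_contingency()` tabulates transition counts
period-by-successor, and `fisher_exact_rc()` applies the Freeman–Halton
r×c generalization of Fisher's exact test via `stats::fisher.test`.
Complete enumeration is used while the candidate-table bound
`prod(choose(r_i + c - 1, c - 1))` stays below `1e7`; beyond that a
Monte-Carlo estimate with `1e5` replicates runs under a fixed local seed
(the caller's RNG state is restored). Degenerate tables — one informative
row or column — return p = 1 rather than an error, since they carry no
evidence of inconsistency. `classify_phrase()` calls a phrase **shifting**
iff p < alpha (strictly; the boundary is static) with alpha = 0.05;
`consistency_table()` also reports Holm-adjusted p-values for reference,
but classification follows the per-phrase raw p-value convention.

## Similarity stage

`levenshtein()` is a two-row dynamic-programming edit distance over phrase
**tokens** (so `14a` is one symbol, not three characters). The **set
median** (`set_median()`) is the member of a set minimizing summed distance
to all members, with deterministic tie-breaking by summed distance, then
length, then lexicographic order. The **Kohonen median**
(`kohonen_median()`) refines it by steepest-descent single-symbol
substitution: each pass tries every position × alphabet symbol and keeps
the first scanned candidate achieving the strictly best improvement,
stopping at a local minimum (mode `"converge"`) or after one pass
(`"single_pass"`). Only a strict improvement changes the result, so the
Kohonen median is never worse than the set median and ties never cause
drift.

The similarity index is `lsi(a, b) = 1 − LD(a, b) / max(length)`;
dissimilarity `1 − LSI` feeds `stats::hclust(method = "single")`
(`single_linkage()`), with `cut_clusters()` for a height cut and
`dendrogram_newick()` (via `ape`) for export. `dice_similarity()` gives the
phrase-sharing index `2A / (B + C)` between period inventories.

Sequences enter this stage only if the raw phrase-level sequence (all
labels, including transitional phrases and repeats) has more than four
transitions, i.e. at least five logged phrases
(`filter_min_transitions()`, default `min_transitions = 4`). The filter is
applied *before* collapsing runs: it is a recording-quality criterion, and
filtering after collapse would discard legitimate short theme sequences
such as the four-theme medians the analysis is designed to find.

## Singers

`min_singers()` lower-bounds concurrent singers as the maximum overlap of
phrase intervals, using a sweep line over half-open intervals (ends sort
before starts at ties, so abutting phrases do not double-count). When
singer-track annotations are present they override the sweep, since an
analyst's track assignment is strictly more informative.
`classify_rate()` maps detections-per-minute to chorusing classes:
`> 30` chorus of four or more, `(15, 30]` chorus of two or more,
`[10, 15]` ambiguous, `< 10` likely solo.

## Synthetic generator

`generate_corpus()` exists so every pipeline stage can be tested against
known truth; its defaults describe the field conditions the package
targets, fixed up front rather than tuned to test outcomes:

- a 15-token alphabet with role annotations; canonical full song
  `17-15-14a-13b-12-4b`;
- per-period row-stochastic theme transition matrices, with period drift
  (default 0.08 probability mass per period) applied to designated
  shifting rows — validated for stochasticity and reachability before use;
- theme lengths of `1 + rgeom(p = 1/mean)` phrases (`repetition_mean = 5`):
  geometric because phrase repetition is well modelled as "continue the
  theme with constant probability", and the +1 guarantees every visited
  theme is sung at least once;
- a transitional phrase at each theme boundary with probability
  `transitional_prob = 0.26`;
- 1–5 singers per recording (mean ≈ 2.65), gamma-distributed phrase
  durations (shape 4, mean 20 s), uniform start offsets on [0, 120] s, and
  a 600 s recording window with a 300 s gap — sequences are clipped at the
  window end, so fragmentation is part of the ground truth;
- one integer seed drives everything; the same seed yields a bit-identical
  corpus and pipeline result.

Scope and limits: the generator produces phrase-level logs, not audio; it
does not model mislabelling, unit-level structure, or singer movement, and
its drift model perturbs whole matrix rows rather than inventing new
phrase types mid-period.

## Problem sizes and numerics

The edit-distance stage is quadratic per pair in sequence length; observed
sequences are tens of tokens, set-median computation is quadratic in set
size (tens of sequences per period), and the Kohonen descent tries
(length × alphabet) candidates per pass — all trivial at these scales.
Exact Fisher tests are bounded by the enumeration guard above; the type-I
error of the whole test-and-classify chain is verified by simulation in
the test suite (rejection rate within [0.02, 0.09] at alpha 0.05 over 250
null corpora). All probability rows are checked stochastic to 1e-9, and
every stochastic component (generator, Monte-Carlo p-values, pipeline)
runs under explicit seeds.
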