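#' Similarity search and data fusion
#'
#' A screen ranks every library compound by Tanimoto similarity to one or
#' more query (active) structures under one or more fingerprint measures.
#' The per-(query, measure) scores form the score table; data fusion reduces
#' them with the MAX or SUM rule, either across measures for one query
#' (*similarity fusion*) or across queries for one measure (*group fusion*).
#' Three screening strategies are supported:
#'
#' * **method A** — no fusion: one ranking per (query, measure) pair;
#' * **method B** — similarity fusion: per query, MAX and SUM rankings over
#'   its measures;
#' * **method C** — group fusion: per measure, MAX and SUM rankings over all
#'   queries.
#'
#' With 28 actives and 4 measures this yields 112, 56 and 8 rankings.
#' Rankings sort by fused score descending, with ties broken by
#' lexicographic compound id so results are deterministic and
#' permutation-stable.
#'
#' @name vsfuse-fusion
NULL

#' Query-versus-library Tanimoto score table
#'
#' @param queries,library molecule tibbles.
#' @param measures fingerprint kinds to score.
#' @param query_fps,library_fps optional precomputed fingerprint tables
#'   (from [fingerprint_table()]) to avoid recomputation.
#' @return tibble `(query, measure, library_id, sim)`, complete over the
#'   cross product, `sim` in `[0, 1]`.
#' @export
similarity_search <- function(queries, library, measures = FP_KINDS,
                              query_fps = NULL, library_fps = NULL) {
  measures <- match.arg(measures, FP_KINDS, several.ok = TRUE)
  if (nrow(queries) == 0 || nrow(library) == 0 || length(measures) == 0)
    abort("similarity_search needs non-empty queries, library and measures")
  if (is.null(query_fps)) query_fps <- fingerprint_table(queries, measures)
  if (is.null(library_fps)) library_fps <- fingerprint_table(library, measures)
  out <- list()
  for (m in measures) {
    qf <- query_fps[query_fps$kind == m, ]
    lf <- library_fps[library_fps$kind == m, ]
    sim <- tanimoto_matrix(setNames(qf$bits, qf$id),
                           setNames(lf$bits, lf$id))
    out[[m]] <- tibble(
      query = rep(qf$id, times = nrow(lf)),
      measure = m,
      library_id = rep(lf$id, each = nrow(qf)),
      sim = as.vector(sim)
    )
  }
  res <- bind_rows(out)
  class(res) <- c("vs_score_table", class(res))
  res
}

#' MAX and SUM fusion rules
#'
#' `fuse_max()` returns the highest of the similarity scores being fused;
#' `fuse_sum()` their plain (unnormalised) arithmetic sum.  Both require a
#' non-empty score list.  Ranking by SUM equals ranking by the mean whenever
#' every compound fuses the same number of scores.
#'
#' @param scores numeric vector of SIM values.
#' @return fused score (scalar).
#' @examples
#' fuse_max(c(0.3, 0.83871, 0.5))
#' fuse_sum(c(0.2, 0.3))
#' @export
fuse_max <- function(scores) {
  if (length(scores) == 0) abort("cannot fuse an empty score list")
  max(scores)
}

#' @rdname fuse_max
#' @export
fuse_sum <- function(scores) {
  if (length(scores) == 0) abort("cannot fuse an empty score list")
  sum(scores)
}

rank_entries <- function(df) {
  df <- df[order(-df$score, df$library_id), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  df
}

finish_rankings <- function(res) {
  class(res) <- c("vs_rankings", class(res))
  res
}

#' @export
print.vs_rankings <- function(x, ...) {
  groups <- dplyr::distinct(as_tibble(x)[c("method", "rule", "query",
                                           "measure")])
  cat("# Screening rankings: ", nrow(groups), " ranking(s), ",
      length(unique(x$library_id)), " library compounds\n", sep = "")
  NextMethod()
}

#' Number of distinct rankings in a rankings table
#'
#' @param rankings result of a `run_method_*()` call.
#' @return integer count of (method, rule, query, measure) groups.
#' @export
n_rankings <- function(rankings) {
  nrow(dplyr::distinct(as_tibble(rankings)[c("method", "rule", "query",
                                             "measure")]))
}

method_scores <- function(actives, library, measures, scores) {
  if (is.null(scores)) scores <- similarity_search(actives, library, measures)
  scores
}

#' Screening method A: raw single-query, single-measure rankings
#'
#' @param actives,library molecule tibbles (ignored when `scores` given).
#' @param measures fingerprint kinds.
#' @param scores optional precomputed [similarity_search()] table.
#' @return a `vs_rankings` tibble with columns `method`, `rule`, `query`,
#'   `measure`, `library_id`, `score`, `rank`; one ranking per
#'   (active, measure) pair.
#' @export
run_method_a <- function(actives, library, measures = FP_KINDS,
                         scores = NULL) {
  scores <- method_scores(actives, library, measures, scores)
  res <- scores |>
    rename(score = "sim") |>
    mutate(method = "A", rule = "raw") |>
    group_by(.data$query, .data$measure) |>
    dplyr::group_modify(~rank_entries(.x)) |>
    ungroup() |>
    select("method", "rule", "query", "measure", "library_id",
           "score", "rank")
  finish_rankings(res)
}

#' Screening method B: similarity fusion across measures, per query
#'
#' @inheritParams run_method_a
#' @param rules fusion rules to apply.
#' @return `vs_rankings` with one MAX and one SUM ranking per active.
#' @export
run_method_b <- function(actives, library, measures = FP_KINDS,
                         rules = c("max", "sum"), scores = NULL) {
  scores <- method_scores(actives, library, measures, scores)
  if (length(unique(scores$measure)) < 2)
    warn("method B with a single measure: fusion is degenerate")
  fused <- scores |>
    group_by(.data$query, .data$library_id) |>
    summarise(max = fuse_max(.data$sim), sum = fuse_sum(.data$sim),
              .groups = "drop") |>
    tidyr::pivot_longer(c("max", "sum"), names_to = "rule",
                        values_to = "score") |>
    filter(.data$rule %in% rules) |>
    mutate(method = "B", measure = "fused")
  res <- fused |>
    group_by(.data$query, .data$rule) |>
    dplyr::group_modify(~rank_entries(.x)) |>
    ungroup() |>
    select("method", "rule", "query", "measure", "library_id",
           "score", "rank")
  finish_rankings(res)
}

#' Screening method C: group fusion across all queries, per measure
#'
#' @inheritParams run_method_b
#' @return `vs_rankings` with one MAX and one SUM ranking per measure.
#' @export
run_method_c <- function(actives, library, measures = FP_KINDS,
                         rules = c("max", "sum"), scores = NULL) {
  scores <- method_scores(actives, library, measures, scores)
  if (length(unique(scores$query)) < 2)
    warn("method C with a single query: group fusion is degenerate")
  fused <- scores |>
    group_by(.data$measure, .data$library_id) |>
    summarise(max = fuse_max(.data$sim), sum = fuse_sum(.data$sim),
              .groups = "drop") |>
    tidyr::pivot_longer(c("max", "sum"), names_to = "rule",
                        values_to = "score") |>
    filter(.data$rule %in% rules) |>
    mutate(method = "C", query = "fused")
  res <- fused |>
    group_by(.data$measure, .data$rule) |>
    dplyr::group_modify(~rank_entries(.x)) |>
    ungroup() |>
    select("method", "rule", "query", "measure", "library_id",
           "score", "rank")
  finish_rankings(res)
}

#' Run all three screening methods on one score table
#'
#' Computes the score table once and derives the method A, B and C rankings
#' from it.
#'
#' @inheritParams run_method_a
#' @param methods subset of `c("A", "B", "C")`.
#' @return `vs_rankings` tibble combining the requested methods.
#' @export
screen_methods <- function(actives, library, measures = FP_KINDS,
                           methods = c("A", "B", "C"), scores = NULL) {
  methods <- match.arg(methods, c("A", "B", "C"), several.ok = TRUE)
  scores <- method_scores(actives, library, measures, scores)
  parts <- list()
  if ("A" %in% methods) parts$A <- run_method_a(scores = scores)
  if ("B" %in% methods) parts$B <- run_method_b(scores = scores)
  if ("C" %in% methods) parts$C <- run_method_c(scores = scores)
  finish_rankings(bind_rows(parts))
}

#' Write rankings to CSV
#'
#' Columns: `library_id`, `score`, `rank`, `rule`, `method`, `query`,
#' `measure`.
#'
#' @param rankings `vs_rankings` tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rankings <- function(rankings, path) {
  write.csv(as_tibble(rankings)[c("library_id", "score", "rank", "rule",
                                  "method", "query", "measure")],
            path, row.names = FALSE)
  invisible(path)
}
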