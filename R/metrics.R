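#' Enrichment metrics for labeled rankings
#'
#' A labeled ranking is an ordered tibble of compounds with an
#' `active`/`decoy` label; the order is the screen's output ranking.  From
#' it the package computes the classical retrospective-validation metrics:
#' enrichment factors at top fractions, sensitivity/specificity at a cut,
#' the ROC curve with its area (equal to the Mann--Whitney statistic), and
#' BEDROC, the exponentially weighted early-recognition variant of the AUC.
#'
#' @name vsfuse-metrics
NULL

#' Construct a labeled ranking
#'
#' @param id ordered compound identifiers (best first).
#' @param label parallel vector of `"active"`/`"decoy"` labels.
#' @return ordered tibble `(rank, id, label)` of class `vs_labeled_ranking`.
#' @export
labeled_ranking <- function(id, label) {
  label <- as.character(label)
  if (!all(label %in% c("active", "decoy")))
    abort("labels must be 'active' or 'decoy'")
  if (length(id) != length(label)) abort("id and label lengths differ")
  out <- tibble(rank = seq_along(id), id = as.character(id), label = label)
  class(out) <- c("vs_labeled_ranking", class(out))
  out
}

#' Attach labels to one screening ranking
#'
#' @param ranking a single ranking (rows of a `vs_rankings` tibble for one
#'   (method, rule, query, measure) group), or any tibble with `library_id`
#'   ordered by `rank`.
#' @param labels named vector or two-column tibble (`id`, `label`) mapping
#'   compound ids to `"active"`/`"decoy"`.
#' @return a [labeled_ranking()].
#' @export
label_ranking <- function(ranking, labels) {
  if (is.data.frame(labels)) labels <- setNames(labels$label, labels$id)
  ranking <- ranking[order(ranking$rank), , drop = FALSE]
  lab <- unname(labels[ranking$library_id])
  if (anyNA(lab)) abort("labels missing for some ranked compounds")
  labeled_ranking(ranking$library_id, lab)
}

check_two_class <- function(r) {
  n_act <- sum(r$label == "active")
  if (n_act == 0 || n_act == nrow(r))
    abort("metrics need both actives and decoys in the ranking")
  n_act
}

#' Enrichment factor at a top fraction
#'
#' `EF(x) = (hits_in_top / n_top) / (N_act / N)` with
#' `n_top = round(x * N)` (half away from zero, minimum 1).  Compounds are
#' taken strictly by rank at the cut; the deterministic id tie-break of the
#' ranking stage decides boundary ties.
#'
#' @param ranking a `vs_labeled_ranking`.
#' @param top_fraction one or more fractions in `(0, 1]`.
#' @return numeric vector of EF values, named by fraction.
#' @examples
#' r <- make_planted_ranking(planted_ranking_spec(N = 1198, N_act = 28,
#'                                                placement = "top-block"))
#' enrichment_factor(r, c(0.01, 0.05, 0.10))
#' @export
enrichment_factor <- function(ranking, top_fraction) {
  stopifnot(all(top_fraction > 0), all(top_fraction <= 1))
  N <- nrow(ranking)
  n_act <- sum(ranking$label == "active")
  if (n_act == 0) abort("no actives in ranking; EF undefined")
  vapply(top_fraction, function(x) {
    n_top <- max(1, round_half_up(x * N))
    hits <- sum(ranking$label[seq_len(n_top)] == "active")
    (hits / n_top) / (n_act / N)
  }, numeric(1)) |> setNames(top_fraction)
}

#' Sensitivity and specificity
#'
#' `sensitivity(tp, fn) = tp / (tp + fn)`: the fraction of all actives
#' recovered.  `specificity(tn, fp) = tn / (tn + fp)`: the fraction of all
#' inactives discarded.  Both range from 0 to 1.
#'
#' @param tp,fn,tn,fp confusion-matrix counts.
#' @return value in `[0, 1]`.
#' @export
sensitivity <- function(tp, fn) {
  if (tp + fn <= 0) abort("sensitivity undefined: no actives")
  tp / (tp + fn)
}

#' @rdname sensitivity
#' @export
specificity <- function(tn, fp) {
  if (tn + fp <= 0) abort("specificity undefined: no inactives")
  tn / (tn + fp)
}

#' ROC curve and AUC of a labeled ranking
#'
#' The stepwise ROC over all cut positions; the AUC equals the
#' Mann--Whitney statistic (the probability that a random active outranks a
#' random decoy, ties counted one half).
#'
#' @param ranking a `vs_labeled_ranking`.
#' @return object of class `vs_roc`: list with `points` (tibble of
#'   `cut`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(ranking) {
  n_act <- check_two_class(ranking)
  N <- nrow(ranking)
  n_dec <- N - n_act
  act <- ranking$label == "active"
  tpr <- cumsum(act) / n_act
  fpr <- cumsum(!act) / n_dec
  points <- tibble(cut = 0:N, fpr = c(0, fpr), tpr = c(0, tpr))
  # trapezoid over the step curve == pair-counting statistic for strict
  # rankings (ties are impossible in a materialised ranking order)
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) +
                                   diff(points$tpr) / 2))
  structure(list(points = points, auc = auc), class = "vs_roc")
}

#' @export
print.vs_roc <- function(x, ...) {
  cat("# ROC: AUC =", format(x$auc, digits = 4), "over",
      max(x$points$cut), "compounds\n")
  invisible(x)
}

#' BEDROC early-recognition score
#'
#' The Boltzmann-enhanced discrimination of the ROC (Truchon & Bailey):
#' the exponentially weighted sum over active ranks
#' \eqn{\sum_i e^{-\alpha r_i / N}} is scaled into the robust initial
#' enhancement and min--max normalised to `[0, 1]`.  At the default
#' `alpha = 20`, 80\% of the score comes from the top 8\% of the ranking
#' (see [bedroc_weight_fraction()]).
#'
#' @param ranking a `vs_labeled_ranking`.
#' @param alpha early-recognition exponent (> 0, unitless).
#' @return BEDROC value in `[0, 1]`.
#' @export
bedroc <- function(ranking, alpha = 20) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0)
    abort("alpha must be a positive scalar")
  n_act <- check_two_class(ranking)
  N <- nrow(ranking)
  ra <- n_act / N
  r_i <- ranking$rank[ranking$label == "active"]
  s <- sum(exp(-alpha * r_i / N))
  rie <- s / (ra * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  rie_min <- (1 - exp(alpha * ra)) / (ra * (1 - exp(alpha)))
  rie_max <- (1 - exp(-alpha * ra)) / (ra * (1 - exp(-alpha)))
  (rie - rie_min) / (rie_max - rie_min)
}

#' Fraction of BEDROC weight inside a top fraction of the ranking
#'
#' For the exponential weight \eqn{e^{-\alpha x}}, the share of total
#' weight carried by the top fraction `x` of the database is
#' \eqn{(1 - e^{-\alpha x}) / (1 - e^{-\alpha})}.  At `alpha = 20` the top
#' 8\% carries 0.80 of the weight, which is why that alpha is read as "80\%
#' of the score from the top 8\%".
#'
#' @param alpha BEDROC exponent.
#' @param top_fraction fraction of the ranking.
#' @return weight fraction in `[0, 1]`.
#' @examples
#' bedroc_weight_fraction(20, 0.08)
#' @export
bedroc_weight_fraction <- function(alpha, top_fraction) {
  (1 - exp(-alpha * top_fraction)) / (1 - exp(-alpha))
}

#' Full metrics report for a labeled ranking
#'
#' Computes EF at the requested fractions, ROC/AUC, BEDROC, and
#' sensitivity/specificity at a top-`cut_fraction` cut.  When the EF
#' formula and independently supplied retrieved-active counts disagree
#' (as can happen with externally reported tables), the discrepancy is
#' flagged in the report rather than reconciled by re-rounding.
#'
#' @param ranking a `vs_labeled_ranking`.
#' @param ef_fractions top fractions for the enrichment factor.
#' @param alpha BEDROC exponent.
#' @param cut_fraction fraction defining the hit-list cut for Se/Sp.
#' @return object of class `vs_metrics` with fields `ef` (tibble), `auc`,
#'   `bedroc`, `alpha`, `se`, `sp`, `n`, `n_act`, `roc`.
#' @export
screen_metrics <- function(ranking, ef_fractions = c(0.01, 0.05, 0.10),
                           alpha = 20, cut_fraction = 0.01) {
  n_act <- check_two_class(ranking)
  N <- nrow(ranking)
  ef <- enrichment_factor(ranking, ef_fractions)
  n_top <- pmax(1, round_half_up(ef_fractions * N))
  hits <- vapply(n_top, function(k)
    sum(ranking$label[seq_len(k)] == "active"), numeric(1))
  roc <- roc_auc(ranking)
  cut <- max(1, round_half_up(cut_fraction * N))
  tp <- sum(ranking$label[seq_len(cut)] == "active")
  fp <- cut - tp
  fn <- n_act - tp
  tn <- (N - n_act) - fp
  structure(list(
    ef = tibble(fraction = ef_fractions, n_top = n_top, hits = hits,
                ef = unname(ef)),
    auc = roc$auc, bedroc = bedroc(ranking, alpha), alpha = alpha,
    se = sensitivity(tp, fn), sp = specificity(tn, fp),
    cut_fraction = cut_fraction, n = N, n_act = n_act, roc = roc
  ), class = "vs_metrics")
}

#' @export
print.vs_metrics <- function(x, ...) {
  cat("# Screening metrics: N =", x$n, "(", x$n_act, "actives )\n")
  for (r in seq_len(nrow(x$ef)))
    cat(sprintf("  EF@%g%%: %.1f (%d hits in top %d)\n",
                100 * x$ef$fraction[r], x$ef$ef[r], x$ef$hits[r],
                x$ef$n_top[r]))
  cat(sprintf("  AUC %.3f | BEDROC(alpha=%g) %.3f | Se %.3f / Sp %.3f at top %g%%\n",
              x$auc, x$alpha, x$bedroc, x$se, x$sp, 100 * x$cut_fraction))
  invisible(x)
}
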