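#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a metrics report
#'
#' @param x a `vs_metrics` object.
#' @param ... unused.
#' @return a tibble with one row per metric (`metric`, `value`).
#' @export
tidy.vs_metrics <- function(x, ...) {
  bind_rows(
    tibble(metric = sprintf("ef_%g", x$ef$fraction), value = x$ef$ef),
    tibble(metric = c("auc", "bedroc", "se", "sp"),
           value = c(x$auc, x$bedroc, x$se, x$sp))
  )
}

#' @rdname tidy.vs_metrics
#' @return `glance()`: a one-row tibble with the headline metrics.
#' @export
glance.vs_metrics <- function(x, ...) {
  ef <- setNames(as.list(x$ef$ef), sprintf("ef_%g", x$ef$fraction))
  as_tibble(c(ef, list(auc = x$auc, bedroc = x$bedroc, alpha = x$alpha,
                       se = x$se, sp = x$sp, n = x$n, n_act = x$n_act)))
}

#' Tidy a ROC curve
#'
#' @param x a `vs_roc` object.
#' @param ... unused.
#' @return tibble of curve points (`cut`, `fpr`, `tpr`).
#' @export
tidy.vs_roc <- function(x, ...) x$points

#' @rdname tidy.vs_roc
#' @export
glance.vs_roc <- function(x, ...) tibble(auc = x$auc)

#' Tidy a pharmacophore screen
#'
#' @param x a `vs_pharm_screen` object.
#' @param ... unused.
#' @return `tidy()`: the per-compound hit table; `glance()`: one-row
#'   summary.
#' @export
tidy.vs_pharm_screen <- function(x, ...) as_tibble(x$hits)

#' @rdname tidy.vs_pharm_screen
#' @export
glance.vs_pharm_screen <- function(x, ...) {
  tibble(hit_rate = x$hit_rate, se = x$se, sp = x$sp, auc = x$roc$auc)
}

#' Tidy a filter report
#'
#' @param x a `vs_filter_report`.
#' @param ... unused.
#' @return tibble of exclusive failure counts per rule plus the pass row.
#' @export
tidy.vs_filter_report <- function(x, ...) {
  bind_rows(
    tibble(rule = "passed", n = x$n_passed),
    tibble(rule = "parse", n = x$n_failed_parse),
    if (length(x$failures))
      tibble(rule = names(x$failures),
             n = as.integer(unlist(x$failures)))
  )
}

#' @rdname tidy.vs_filter_report
#' @export
glance.vs_filter_report <- function(x, ...) {
  tibble(rule_set = x$rule_set, n_input = x$n_input,
         n_passed = x$n_passed, n_failed_parse = x$n_failed_parse,
         n_rejected = x$n_input - x$n_passed - x$n_failed_parse)
}
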