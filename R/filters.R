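#' Drug-likeness rule set
#'
#' Thresholds for the lead-like prefilter: a molecular-weight window of
#' 150--450 g/mol and clogP of at most 5, combined with the Lipinski
#' hydrogen-bonding caps (donors at most 5, acceptors at most 10) and the
#' Veber flexibility/polarity caps (rotatable bonds at most 10, TPSA at most
#' 140 square Angstrom).  All thresholds are configurable.
#'
#' @param mw_min,mw_max molecular-weight window (g/mol).
#' @param clogp_max maximum computed logP.
#' @param hbd_max,hba_max Lipinski donor/acceptor caps.
#' @param rotb_max,tpsa_max Veber caps.
#' @return a named list of thresholds (class `vs_druglike_rules`).
#' @export
druglike_rules <- function(mw_min = 150, mw_max = 450, clogp_max = 5,
                           hbd_max = 5, hba_max = 10,
                           rotb_max = 10, tpsa_max = 140) {
  structure(list(mw_min = mw_min, mw_max = mw_max, clogp_max = clogp_max,
                 hbd_max = hbd_max, hba_max = hba_max,
                 rotb_max = rotb_max, tpsa_max = tpsa_max),
            class = "vs_druglike_rules")
}

#' Default reactive/assay-interference substructure alerts
#'
#' A small documented alert list in the spirit of REOS/PAINS prefilters:
#' acyl halides, aldehydes, Michael-acceptor enones, alkyl halides,
#' isocyanates, epoxides/aziridines, quinones, azo compounds, anhydrides and
#' peroxides.  It is a stand-in for the full proprietary rule collections;
#' users screening real libraries should supply their own complete SMARTS
#' lists through the `alerts` argument of [filter_reactive()].
#'
#' @return named character vector of SMARTS patterns.
#' @export
default_alerts <- function() {
  c(
    acyl_halide     = "[CX3](=[OX1])[F,Cl,Br,I]",
    aldehyde        = "[CX3H1](=O)[#6]",
    michael_enone   = "[CX3]=[CX3][CX3]=[OX1]",
    alkyl_halide    = "[CX4][Cl,Br,I]",
    isocyanate      = "[NX2]=[CX2]=[OX1]",
    epoxide_aziridine = "[OX2r3,NX3r3]1[#6r3][#6r3]1",
    quinone         = "O=C1C=CC(=O)C=C1",
    azo             = "[#6][NX2]=[NX2][#6]",
    anhydride       = "[CX3](=[OX1])[OX2][CX3](=[OX1])",
    peroxide        = "[OX2][OX2]"
  )
}

new_filter_report <- function(n_input, n_passed, n_failed_parse, failures,
                              rule_set) {
  structure(list(n_input = n_input, n_passed = n_passed,
                 n_failed_parse = n_failed_parse,
                 failures = failures, rule_set = rule_set),
            class = "vs_filter_report")
}

#' @export
print.vs_filter_report <- function(x, ...) {
  cat("# Filter report (", x$rule_set, ")\n", sep = "")
  cat("  input:        ", x$n_input, "\n")
  cat("  passed:       ", x$n_passed, "\n")
  cat("  parse failed: ", x$n_failed_parse, "\n")
  if (length(x$failures)) {
    for (nm in names(x$failures))
      cat("  failed ", nm, ": ", x$failures[[nm]], "\n", sep = "")
  }
  invisible(x)
}

#' Retrieve the filter report attached to a filtered library
#'
#' @param mols result of [filter_druglike()] or [filter_reactive()].
#' @return the `vs_filter_report`.
#' @export
filter_report <- function(mols) {
  rep <- attr(mols, "filter_report")
  if (is.null(rep)) abort("no filter report attached; run a filter first")
  rep
}

attach_report <- function(mols, report) {
  attr(mols, "filter_report") <- report
  mols
}

#' Drug-likeness filter
#'
#' Keeps compounds inside the molecular-weight window with clogP, Lipinski
#' and Veber descriptors within their caps.  Failure attribution is
#' exclusive and deterministic: each rejected compound is charged to the
#' first failing rule in the fixed order mw, clogp, hbd, hba, rotb, tpsa,
#' so the report counts always satisfy
#' `n_passed + sum(failures) + n_failed_parse == n_input`.
#'
#' @param mols molecule tibble with properties (see [compute_properties()]).
#' @param rules a [druglike_rules()] object.
#' @return the passing subset, with a `vs_filter_report` attached
#'   (see [filter_report()]).
#' @export
filter_druglike <- function(mols, rules = druglike_rules()) {
  stopifnot(inherits(rules, "vs_druglike_rules"))
  if (!has_properties(mols)) {
    bad <- if ("mw" %in% names(mols)) mols$id[is.na(mols$mw)] else mols$id
    abort(paste0("properties missing for: ",
                 paste(head(bad, 5), collapse = ", "),
                 "; run compute_properties() first"))
  }
  checks <- list(
    mw    = mols$mw >= rules$mw_min & mols$mw <= rules$mw_max,
    clogp = mols$clogp <= rules$clogp_max,
    hbd   = mols$hbd <= rules$hbd_max,
    hba   = mols$hba <= rules$hba_max,
    rotb  = mols$rotb <= rules$rotb_max,
    tpsa  = mols$tpsa <= rules$tpsa_max
  )
  first_fail <- rep(NA_character_, nrow(mols))
  for (nm in rev(names(checks))) first_fail[!checks[[nm]]] <- nm
  pass <- is.na(first_fail)
  failures <- as.list(table(factor(first_fail[!pass], levels = names(checks))))
  failures <- failures[vapply(failures, function(x) x > 0, logical(1))]
  pf <- attr(mols, "parse_failures")
  report <- new_filter_report(
    n_input = nrow(mols), n_passed = sum(pass),
    n_failed_parse = if (is.null(pf)) 0L else nrow(pf),
    failures = failures, rule_set = "druglike")
  attach_report(mols[pass, , drop = FALSE], report)
}

#' Reactive-group / interference filter
#'
#' Removes compounds matching any substructure alert.  A compound is
#' attributed to the first matching alert in list order.  An empty alert
#' list passes everything.
#'
#' @param mols molecule tibble.
#' @param alerts named character vector of SMARTS patterns
#'   (default [default_alerts()]); invalid patterns are fatal at load time.
#' @return passing subset with a `vs_filter_report` attached.
#' @export
filter_reactive <- function(mols, alerts = default_alerts()) {
  stopifnot(nrow(mols) > 0)
  if (length(alerts) > 0 && is.null(names(alerts)))
    names(alerts) <- paste0("alert", seq_along(alerts))
  first_fail <- rep(NA_character_, nrow(mols))
  if (length(alerts) > 0) {
    refs <- obmols_from_smiles(mols$smiles, mols$id)
    for (nm in rev(names(alerts))) {
      hits <- tryCatch(
        ChemmineOB::smartsSearch_OB(refs, alerts[[nm]]),
        error = function(e) abort(paste0("invalid alert SMARTS '", nm, "': ",
                                         alerts[[nm]])))
      first_fail[hits > 0] <- nm
    }
  }
  pass <- is.na(first_fail)
  failures <- as.list(table(factor(first_fail[!pass], levels = names(alerts))))
  failures <- failures[vapply(failures, function(x) x > 0, logical(1))]
  pf <- attr(mols, "parse_failures")
  report <- new_filter_report(
    n_input = nrow(mols), n_passed = sum(pass),
    n_failed_parse = if (is.null(pf)) 0L else nrow(pf),
    failures = failures, rule_set = "reactive")
  attach_report(mols[pass, , drop = FALSE], report)
}
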