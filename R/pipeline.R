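#' Config-driven screening pipeline
#'
#' Orchestrates the funnel synth -> filter -> screen -> validate
#' (-> pharm) from a YAML or list configuration.  Every stage writes its
#' parameters, an input hash and its outputs into its own subdirectory of
#' the run directory; a stage whose parameter/input hash is unchanged from
#' a previous run is skipped and its cached outputs reused.  A final
#' `summary.json` aggregates filter reports, ranking inventories and
#' validation metrics.  Reruns with the same config and seed produce
#' byte-identical summaries.
#'
#' @name vsfuse-pipeline
NULL

PIPELINE_KEYS <- list(
  top = c("seed", "out_dir", "stages", "synth", "filter", "screen",
          "validate", "pharm"),
  synth = c("n_actives", "n_decoys", "decoy_ratio", "scaffold",
            "similarity_floor", "similarity_ceiling"),
  filter = c("mw_min", "mw_max", "clogp_max", "hbd_max", "hba_max",
             "rotb_max", "tpsa_max", "reactive"),
  screen = c("measures", "methods"),
  validate = c("ef_fractions", "alpha", "cut_fraction"),
  pharm = c("hypothesis", "max_conformers", "energy_window",
            "noise_sd", "n_active", "n_decoy", "planted")
)

check_config_keys <- function(config) {
  bad <- setdiff(names(config), PIPELINE_KEYS$top)
  if (length(bad))
    abort(paste0("unknown pipeline config key(s): ",
                 paste(bad, collapse = ", ")))
  for (stage in intersect(names(config), names(PIPELINE_KEYS))) {
    if (stage == "top") next
    bad <- setdiff(names(config[[stage]]), PIPELINE_KEYS[[stage]])
    if (length(bad))
      abort(paste0("unknown key(s) in '", stage, "' config: ",
                   paste(bad, collapse = ", ")))
  }
  invisible(config)
}

config_hash <- function(...) {
  json <- jsonlite::toJSON(list(...), auto_unbox = TRUE, digits = NA)
  format(fnv1a32(as.character(json)), scientific = FALSE)
}

stage_cached <- function(dir, hash) {
  hf <- file.path(dir, "stage-hash.txt")
  file.exists(hf) && identical(readLines(hf, warn = FALSE)[1], hash)
}

stage_commit <- function(dir, hash, params) {
  writeLines(hash, file.path(dir, "stage-hash.txt"))
  jsonlite::write_json(params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Run the screening pipeline
#'
#' @param config a YAML file path or a nested list; unknown keys are fatal
#'   before any stage executes.  Recognised stages: `synth`, `filter`,
#'   `screen`, `validate`, `pharm` (the last only in planted mode here).
#' @param quiet suppress progress messages.
#' @return invisibly, the summary list (also written as
#'   `summary.json` in the run directory).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  check_config_keys(config)
  seed <- config$seed %||% abort("config needs a seed")
  out_dir <- config$out_dir %||% abort("config needs an out_dir")
  stages <- config$stages %||% c("synth", "filter", "screen", "validate")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) inform(paste0(...))
  t_start <- Sys.time()
  summary <- list(seed = seed, stages = stages)

  # --- synth -------------------------------------------------------------
  sy <- config$synth %||% list()
  spec <- benchmark_spec(
    n_actives = sy$n_actives %||% 28,
    n_decoys = sy$n_decoys %||% 1170,
    decoy_ratio = sy$decoy_ratio,
    scaffold = sy$scaffold %||% formals(benchmark_spec)$scaffold,
    similarity_floor = sy$similarity_floor %||% 0.4,
    similarity_ceiling = sy$similarity_ceiling %||% 0.35,
    seed = seed)
  sdir <- file.path(out_dir, "synth")
  dir.create(sdir, showWarnings = FALSE)
  shash <- config_hash(stage = "synth", spec = unclass(spec))
  if (!("synth" %in% stages)) abort("pipeline currently starts at 'synth'")
  if (stage_cached(sdir, shash)) {
    say("[synth] cached, skipping")
    actives <- compute_properties(read_library(file.path(sdir,
                                                         "actives.smi")))
    decoys <- read_library(file.path(sdir, "decoys.smi"))
    labels <- as_tibble(read.table(file.path(sdir, "labels.csv"),
                                   header = TRUE, sep = ",",
                                   colClasses = "character"))
  } else {
    say("[synth] generating benchmark: ", spec$n_actives, " actives + ",
        spec$n_decoys, " decoys")
    bench <- make_benchmark(spec)
    actives <- bench$actives
    decoys <- bench$decoys
    labels <- bench$labels
    write_library(actives, file.path(sdir, "actives.smi"))
    write_library(decoys, file.path(sdir, "decoys.smi"))
    write.csv(labels, file.path(sdir, "labels.csv"), row.names = FALSE)
    stage_commit(sdir, shash, unclass(spec))
  }
  library_mols <- bind_rows(actives[c("id", "smiles", "graph")],
                            decoys[c("id", "smiles", "graph")])
  summary$synth <- list(n_actives = nrow(actives), n_decoys = nrow(decoys))

  # --- filter ------------------------------------------------------------
  if ("filter" %in% stages) {
    fl <- config$filter %||% list()
    rules <- druglike_rules(
      mw_min = fl$mw_min %||% 150, mw_max = fl$mw_max %||% 450,
      clogp_max = fl$clogp_max %||% 5, hbd_max = fl$hbd_max %||% 5,
      hba_max = fl$hba_max %||% 10, rotb_max = fl$rotb_max %||% 10,
      tpsa_max = fl$tpsa_max %||% 140)
    fdir <- file.path(out_dir, "filter")
    dir.create(fdir, showWarnings = FALSE)
    fhash <- config_hash(stage = "filter", rules = unclass(rules),
                         reactive = fl$reactive %||% TRUE, input = shash)
    if (stage_cached(fdir, fhash)) {
      say("[filter] cached, skipping")
      library_mols <- read_library(file.path(fdir, "filtered.smi"))
      freport <- jsonlite::read_json(file.path(fdir, "filter-report.json"))
    } else {
      withprops <- compute_properties(library_mols)
      passed <- filter_druglike(withprops, rules)
      rep1 <- filter_report(passed)
      if (isTRUE(fl$reactive %||% TRUE)) {
        passed <- filter_reactive(passed)
        rep2 <- filter_report(passed)
      } else rep2 <- NULL
      say("[filter] ", rep1$n_input, " -> ", nrow(passed), " compounds")
      write_library(passed, file.path(fdir, "filtered.smi"))
      freport <- list(druglike = glance(rep1),
                      reactive = if (!is.null(rep2)) glance(rep2))
      jsonlite::write_json(freport, file.path(fdir, "filter-report.json"),
                           auto_unbox = TRUE, digits = NA)
      stage_commit(fdir, fhash, unclass(rules))
      library_mols <- passed
    }
    summary$filter <- freport
  }

  # --- screen ------------------------------------------------------------
  rankings <- NULL
  if ("screen" %in% stages) {
    sc <- config$screen %||% list()
    measures <- sc$measures %||% FP_KINDS
    methods <- sc$methods %||% c("A", "B", "C")
    cdir <- file.path(out_dir, "screen")
    dir.create(cdir, showWarnings = FALSE)
    chash <- config_hash(stage = "screen", measures = measures,
                         methods = methods, input = shash)
    if (stage_cached(cdir, chash)) {
      say("[screen] cached, skipping")
      rankings <- as_tibble(read.table(file.path(cdir, "rankings.csv"),
                                       header = TRUE, sep = ","))
    } else {
      say("[screen] methods ", paste(methods, collapse = "/"), " over ",
          paste(measures, collapse = ","))
      rankings <- screen_methods(actives, library_mols, measures, methods)
      write_rankings(rankings, file.path(cdir, "rankings.csv"))
      stage_commit(cdir, chash, list(measures = measures,
                                     methods = methods))
    }
    counts <- rankings |>
      dplyr::distinct(.data$method, .data$rule, .data$query,
                      .data$measure) |>
      dplyr::count(.data$method)
    summary$screen <- setNames(as.list(counts$n),
                               paste0("rankings_", counts$method))
  }

  # --- validate ----------------------------------------------------------
  if ("validate" %in% stages && !is.null(rankings)) {
    va <- config$validate %||% list()
    ef_fractions <- unlist(va$ef_fractions %||% c(0.01, 0.05, 0.10))
    alpha <- va$alpha %||% 20
    vdir <- file.path(out_dir, "validate")
    dir.create(vdir, showWarnings = FALSE)
    lab_vec <- setNames(labels$label, labels$id)
    groups <- rankings |>
      group_by(.data$method, .data$rule, .data$query, .data$measure)
    metrics <- dplyr::group_map(groups, function(df, key) {
      df <- df[df$library_id %in% names(lab_vec), , drop = FALSE]
      df$rank <- order(order(df$rank))
      m <- screen_metrics(label_ranking(df, lab_vec),
                          ef_fractions = ef_fractions, alpha = alpha,
                          cut_fraction = va$cut_fraction %||% 0.01)
      bind_cols(key, glance(m))
    }) |> bind_rows()
    write.csv(metrics, file.path(vdir, "metrics.csv"), row.names = FALSE)
    best <- metrics[order(-metrics[[sprintf("ef_%g", ef_fractions[1])]]), ]
    summary$validate <- list(
      n_models = nrow(metrics),
      best = as.list(best[1, c("method", "rule", "query", "measure",
                               "auc", "bedroc")]))
    summary$metrics_csv <- file.path("validate", "metrics.csv")
  }

  say(sprintf("[done] %.1fs", as.numeric(Sys.time() - t_start, "secs")))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(summary)
}
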