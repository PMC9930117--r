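#' Synthetic benchmark generation
#'
#' All pipeline inputs can be generated synthetically and deterministically:
#' an active series sharing a scaffold (mutually similar above a Tanimoto
#' floor), a property-matched but topologically dissimilar decoy pool, fully
#' planted labeled rankings with known enrichment, and planted pharmacophore
#' geometries.  Generators are pure functions of (spec, seed) and their
#' outputs are verified against their own constraints post hoc rather than
#' trusted.
#'
#' @name vsfuse-synthetic
NULL

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

# substituent vocabulary used to decorate scaffolds (kept small so every
# generated SMILES stays chemically valid)
SUBSTITUENTS <- c("", "C", "F", "Cl", "Br", "O", "OC", "N", "C(=O)O")

# linker options substituted for the "{L}" marker in decoy templates
DECOY_LINKERS <- c("C", "CC", "CCC", "C(C)", "CO")

# decoy scaffold families: different topology (aliphatic heterocycle,
# cyclohexyl, isoxazole, sulfonamide cores), property ranges overlapping the
# active series; "([*])" marks substituent slots, "{L}" a linker slot
DECOY_TEMPLATES <- c(
  "OC(=O)C1CCN(CC1)C(=O){L}c1cc(Cl)c([*])c([*])c1",
  "OC(=O)C(Cc1cc([*])c([*])c([*])c1)NC(C)=O",
  "O=C(NC{L}c1cncc([*])c1)C1CCC([*])CC1",
  "OC(=O)CN1CCC(C{L}c2ccc([*])c([*])c2)CC1",
  "Oc1ccc(C{L}C2CCC(CC(=O)O)CC2)c([*])c1[*]",
  "OC(=O)c1cc(C{L}c2ccc([*])c([*])c2)on1",
  "COc1ccc(S(=O)(=O)NCC2CCC([*])C([*])C2)cc1[*]",
  "OC(=O)CC1CCN(C(=O)C2CC([*])C([*])C([*])C2)CC1",
  "O=C(N{L}Cc1ccc([*])c([*])c1)C1CCCO1",
  "O=S(=O)(C)N1CCC(C{L}c2ccc(O)c([*])c2[*])CC1",
  "OC(=O)COc1cc([*])c(CC2CCCC2)c([*])c1[*]",
  "O=C(NCC{L}c1ccc([*])c([*])c1)C1CCOCC1"
)

fill_template <- function(template, subs, linker = "") {
  out <- gsub("{L}", linker, template, fixed = TRUE)
  for (s in subs) {
    if (grepl("([*])", out, fixed = TRUE)) {
      # parenthesised slot: substituent becomes a branch
      rep <- if (nzchar(s)) paste0("(", s, ")") else ""
      out <- sub("([*])", rep, out, fixed = TRUE)
    } else if (grepl("[*]", out, fixed = TRUE)) {
      # bare slot (after a ring closure): substituent continues the chain
      out <- sub("[*]", s, out, fixed = TRUE)
    }
  }
  # unfilled slots collapse to hydrogen
  out <- gsub("([*])", "", out, fixed = TRUE)
  gsub("[*]", "", out, fixed = TRUE)
}

template_slots <- function(template) {
  lengths(regmatches(template, gregexpr("[*]", template, fixed = TRUE)))
}

#' Benchmark specification
#'
#' Defines the synthetic study conditions.  The default mirrors the shape
#' of the retrospective validation set this package is designed around:
#' 28 actives and 1170 decoys (1198 compounds), so methods A/B/C with four
#' measures produce 112/56/8 rankings.  The default decoy count corresponds
#' to a decoys/ligand ratio of about 42; generation via `decoy_ratio`
#' enforces the conventional 4--36 window instead.
#'
#' @param n_actives number of actives.
#' @param n_decoys explicit decoy count (takes precedence over
#'   `decoy_ratio`).
#' @param decoy_ratio decoys per active, within `[4, 36]`.
#' @param scaffold active scaffold as SMILES with `([*])` attachment slots.
#' @param similarity_floor minimum pairwise radial Tanimoto among actives.
#' @param similarity_ceiling maximum radial Tanimoto of any decoy to any
#'   active.
#' @param seed integer seed; all generation is a pure function of the spec.
#' @return list of class `vs_benchmark_spec`.
#' @export
benchmark_spec <- function(n_actives = 28, n_decoys = 1170,
                           decoy_ratio = NULL,
                           scaffold = "OC(=O)c1ccc(Nc2ccc([*])c([*])c2)c([*])c1",
                           similarity_floor = 0.4,
                           similarity_ceiling = 0.35,
                           seed = 1) {
  if (is.null(n_decoys)) {
    if (is.null(decoy_ratio)) abort("give n_decoys or decoy_ratio")
    stopifnot(decoy_ratio >= 4, decoy_ratio <= 36)
    n_decoys <- as.integer(round(decoy_ratio * n_actives))
  }
  stopifnot(n_actives >= 1, n_decoys >= 1,
            similarity_ceiling > 0, similarity_ceiling < similarity_floor,
            similarity_floor <= 1)
  structure(list(n_actives = as.integer(n_actives),
                 n_decoys = as.integer(n_decoys),
                 scaffold = scaffold,
                 similarity_floor = similarity_floor,
                 similarity_ceiling = similarity_ceiling,
                 seed = as.integer(seed)),
            class = "vs_benchmark_spec")
}

decorate_scaffold <- function(template, n, seed, forbid = character(0),
                              oversample = 4) {
  n_slots <- template_slots(template)
  has_linker <- grepl("{L}", template, fixed = TRUE)
  restore <- local_seed(seed)
  on.exit(restore())
  combos <- unique(replicate(
    oversample * n + 20,
    list(subs = sample(SUBSTITUENTS, n_slots, replace = TRUE),
         linker = if (has_linker) sample(DECOY_LINKERS, 1) else ""),
    simplify = FALSE))
  smis <- vapply(combos, function(cmb)
    fill_template(template, cmb$subs, cmb$linker), character(1))
  smis <- unique(smis)
  setdiff(smis, forbid)
}

#' Generate the synthetic active series
#'
#' Decorates the scaffold with substituents (methyl, halogens, hydroxyl,
#' methoxy, amino, carboxyl) at its attachment slots, keeps a set whose
#' pairwise radial Tanimoto similarity stays at or above the spec floor
#' (verified post hoc by direct pairwise computation, pruning offenders and
#' refilling within a bounded number of rounds), and attaches synthetic
#' potencies (pIC50 drawn uniformly on 5--8, i.e. log-uniform IC50).
#'
#' @param spec a [benchmark_spec()].
#' @return molecule tibble with properties and a `potency` column.
#' @export
make_active_series <- function(spec) {
  stopifnot(inherits(spec, "vs_benchmark_spec"))
  cand_smis <- decorate_scaffold(spec$scaffold, spec$n_actives, spec$seed,
                                 oversample = 6)
  if (length(cand_smis) < spec$n_actives)
    abort("scaffold does not admit enough distinct decorated variants")
  cand <- parse_molecules(cand_smis, paste0("ACT", seq_along(cand_smis)),
                          formal_charges = FALSE)
  fps <- map(cand$graph, fp_radial)
  sim <- tanimoto_matrix(fps, fps)
  # greedy: keep candidates compatible (>= floor) with everything selected
  sel <- integer(0)
  for (k in seq_len(nrow(cand))) {
    if (all(sim[k, sel] >= spec$similarity_floor)) sel <- c(sel, k)
    if (length(sel) == spec$n_actives) break
  }
  if (length(sel) < spec$n_actives)
    abort(paste0("could not assemble ", spec$n_actives, " actives with ",
                 "pairwise radial Tanimoto >= ", spec$similarity_floor,
                 " (best: ", length(sel), "); lower the floor or use a ",
                 "larger scaffold"))
  actives <- cand[sel, , drop = FALSE]
  actives$id <- paste0("ACT", seq_len(nrow(actives)))
  # post-hoc verification, independent of the greedy bookkeeping
  vfp <- map(actives$graph, fp_radial)
  vsim <- tanimoto_matrix(vfp, vfp)
  if (min(vsim) < spec$similarity_floor)
    abort("active series failed post-hoc similarity-floor verification")
  restore <- local_seed(spec$seed + 1L)
  on.exit(restore())
  actives <- compute_properties(actives)
  actives$potency <- runif(nrow(actives), 5, 8)
  actives
}

#' Generate the property-matched decoy pool
#'
#' Decorates a fixed panel of topologically unrelated scaffold families,
#' keeps candidates that fall within the default [decoy_spec()] property
#' tolerances of at least one active while staying at or below the
#' spec ceiling in radial Tanimoto to **all** actives (verified post hoc),
#' and returns the requested number of decoys.
#'
#' @param spec a [benchmark_spec()].
#' @param actives the active series (with properties).
#' @param max_rounds candidate-generation rounds before a shortfall is
#'   fatal; each round widens the sampled template decorations.
#' @return molecule tibble of decoys with properties.
#' @export
make_decoy_pool <- function(spec, actives, max_rounds = 4) {
  stopifnot(inherits(spec, "vs_benchmark_spec"))
  dspec <- decoy_spec(max_tanimoto = spec$similarity_ceiling)
  # small requests still sample broadly: the joint property window against
  # a small active panel is narrow, so eligibility rates vary with seed
  per_round <- max(50, ceiling(spec$n_decoys / length(DECOY_TEMPLATES) / 1.2))
  seen <- character(0)
  pool <- NULL
  ok <- logical(0)
  for (round in seq_len(max_rounds)) {
    smis <- character(0)
    for (t in seq_along(DECOY_TEMPLATES)) {
      smis <- c(smis, decorate_scaffold(
        DECOY_TEMPLATES[t], round * per_round,
        spec$seed + 100L + t, forbid = seen, oversample = 2 * round))
    }
    smis <- unique(smis)
    seen <- c(seen, smis)
    if (length(smis) == 0) next
    batch <- parse_molecules(smis, paste0("DECc", length(seen),
                                          "_", seq_along(smis)),
                             formal_charges = FALSE)
    batch <- compute_properties(batch)
    elig <- decoy_eligibility(actives, batch, dspec)
    ok_batch <- elig$sim_ok & rowSums(elig$prop_ok) > 0
    pool <- if (is.null(pool)) batch else bind_rows(pool, batch)
    ok <- c(ok, ok_batch)
    if (sum(ok) >= spec$n_decoys) break
  }
  if (sum(ok) < spec$n_decoys)
    abort(paste0("decoy generation shortfall: ", sum(ok), " eligible of ",
                 spec$n_decoys, " requested; relax the spec or add ",
                 "templates"))
  decoys <- pool[which(ok)[seq_len(spec$n_decoys)], , drop = FALSE]
  decoys$id <- paste0("DEC", seq_len(nrow(decoys)))
  # post-hoc verification with a fresh fingerprint computation
  dfp <- map(decoys$graph, fp_radial)
  afp <- map(actives$graph, fp_radial)
  if (max(tanimoto_matrix(dfp, afp)) > spec$similarity_ceiling)
    abort("decoy pool failed post-hoc similarity-ceiling verification")
  decoys
}

#' Build the full synthetic benchmark
#'
#' @param spec a [benchmark_spec()].
#' @return list with `actives`, `decoys`, `library` (actives + decoys) and
#'   `labels` (tibble `id`, `label`).
#' @examples
#' \donttest{
#' bench <- make_benchmark(benchmark_spec(n_actives = 4, n_decoys = 20,
#'                                        seed = 7))
#' nrow(bench$library)
#' }
#' @export
make_benchmark <- function(spec = benchmark_spec()) {
  actives <- make_active_series(spec)
  decoys <- make_decoy_pool(spec, actives)
  library <- bind_rows(actives[setdiff(names(actives), "potency")], decoys)
  labels <- tibble(id = library$id,
                   label = c(rep("active", nrow(actives)),
                             rep("decoy", nrow(decoys))))
  list(actives = actives, decoys = decoys, library = library,
       labels = labels, spec = spec)
}

#' Planted-ranking specification
#'
#' @param N total compounds; `N_act` actives among them.
#' @param N_act active count.
#' @param placement `"top-block"` (actives at ranks 1..N_act),
#'   `"uniform"` (random ranks) or `"exponential"` (early-biased ranks
#'   with rate `lambda`).
#' @param lambda exponential placement rate (ignored otherwise).
#' @param seed integer seed.
#' @return list of class `vs_planted_spec`.
#' @export
planted_ranking_spec <- function(N, N_act,
                                 placement = c("top-block", "uniform",
                                               "exponential"),
                                 lambda = 10, seed = 1) {
  placement <- match.arg(placement)
  stopifnot(N_act > 0, N_act < N)
  structure(list(N = as.integer(N), N_act = as.integer(N_act),
                 placement = placement, lambda = lambda,
                 seed = as.integer(seed)),
            class = "vs_planted_spec")
}

#' Generate a planted labeled ranking
#'
#' For `"top-block"` placement the enrichment factor is analytically
#' `min(N_act, n_top)/n_top * N/N_act` and the AUC is 1; for `"uniform"`
#' placement the expected EF is 1 (a random screen).
#'
#' @param spec a [planted_ranking_spec()].
#' @return a [labeled_ranking()].
#' @export
make_planted_ranking <- function(spec) {
  stopifnot(inherits(spec, "vs_planted_spec"))
  restore <- local_seed(spec$seed)
  on.exit(restore())
  pos <- switch(spec$placement,
    "top-block" = seq_len(spec$N_act),
    "uniform" = sample.int(spec$N, spec$N_act),
    "exponential" = sample.int(spec$N, spec$N_act,
                               prob = exp(-spec$lambda *
                                            seq_len(spec$N) / spec$N))
  )
  label <- rep("decoy", spec$N)
  label[pos] <- "active"
  labeled_ranking(sprintf("CMP%05d", seq_len(spec$N)), label)
}

#' Generate planted pharmacophore feature sets
#'
#' Emulates a pharmacophore screen's ground truth without conformer
#' generation: actives carry the hypothesis feature geometry perturbed by
#' isotropic Gaussian noise and placed in a random rigid frame; decoys carry
#' the same feature kinds at scrambled positions (uniform in a sphere of
#' the hypothesis' span).
#'
#' @param n_active,n_decoy set sizes.
#' @param hypothesis a [hypothesis()].
#' @param noise_sd per-coordinate Gaussian noise for actives (Angstrom).
#' @param seed integer seed.
#' @return tibble `(id, label, features)` where `features` is a list of
#'   feature tibbles `(kind, x, y, z)`, one conformer per compound.
#' @export
make_planted_pharmacophore <- function(n_active, n_decoy, hypothesis,
                                       noise_sd = 0.3, seed = 1) {
  stopifnot(inherits(hypothesis, "vs_hypothesis"))
  restore <- local_seed(seed)
  on.exit(restore())
  feat <- hypothesis$features
  centre <- colMeans(feat[, c("x", "y", "z")])
  span <- max(sqrt(rowSums(sweep(as.matrix(feat[, c("x", "y", "z")]), 2,
                                 centre)^2))) + 1
  one_active <- function(k) {
    pos <- as.matrix(feat[, c("x", "y", "z")])
    pos <- pos + matrix(rnorm(length(pos), 0, noise_sd), nrow(pos), 3)
    rot <- random_rotation()
    pos <- sweep(pos, 2, centre) %*% rot
    pos <- sweep(pos, 2, runif(3, -20, 20), `+`)
    tibble(kind = feat$kind, x = pos[, 1], y = pos[, 2], z = pos[, 3])
  }
  one_decoy <- function(k) {
    n <- nrow(feat)
    pos <- matrix(rnorm(3 * n), n, 3)
    pos <- pos / sqrt(rowSums(pos^2)) * (span * runif(n)^(1 / 3))
    tibble(kind = sample(feat$kind), x = pos[, 1], y = pos[, 2],
           z = pos[, 3])
  }
  tibble(
    id = c(sprintf("PACT%03d", seq_len(n_active)),
           sprintf("PDEC%03d", seq_len(n_decoy))),
    label = c(rep("active", n_active), rep("decoy", n_decoy)),
    features = c(lapply(seq_len(n_active), one_active),
                 lapply(seq_len(n_decoy), one_decoy))
  )
}

random_rotation <- function() {
  # QR-based uniform random rotation
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
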