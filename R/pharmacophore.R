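#' Pharmacophore hypotheses, feature perception and matching
#'
#' A pharmacophore hypothesis is a set of typed interaction features --
#' hydrogen-bond donor (D), acceptor (A), hydrophobic group (H), aromatic
#' ring (R), positive (P) and negative (N) ionizable groups -- at 3D
#' positions with tolerance spheres.  A conformer matches when some
#' injective, kind-compatible assignment of hypothesis features to the
#' conformer's perceived features can be rigidly superposed so that every
#' assigned feature falls inside its tolerance sphere.  The assignment
#' search is exhaustive with pairwise-distance pruning; the reported fit is
#' the RMS residual of the superposed feature positions (used only to rank
#' hits).
#'
#' @name vsfuse-pharmacophore
NULL

FEATURE_KINDS <- c("D", "A", "H", "R", "P", "N")

#' Construct a pharmacophore hypothesis
#'
#' @param features tibble with columns `kind` (one of D/A/H/R/P/N), `x`,
#'   `y`, `z` (Angstrom) and `tolerance` (sphere radius, Angstrom; filled
#'   with `default_tolerance` when absent).
#' @param name hypothesis name.
#' @param default_tolerance tolerance used where the column is missing
#'   (default 1.6 Angstrom).
#' @param min_features,max_features allowed feature count (defaults 4 and
#'   10); relax for toy hypotheses.
#' @param min_distance minimum pairwise inter-feature distance (default
#'   2.97 Angstrom); violations are fatal.
#' @return object of class `vs_hypothesis`.
#' @export
hypothesis <- function(features, name = "hypothesis",
                       default_tolerance = 1.6,
                       min_features = 4, max_features = 10,
                       min_distance = 2.97) {
  features <- as_tibble(features)
  if (!all(c("kind", "x", "y", "z") %in% names(features)))
    abort("features need kind, x, y, z columns")
  if (!all(features$kind %in% FEATURE_KINDS))
    abort(paste0("unknown feature kind(s): ",
                 paste(setdiff(features$kind, FEATURE_KINDS),
                       collapse = ", ")))
  if (!"tolerance" %in% names(features))
    features$tolerance <- default_tolerance
  if (any(features$tolerance <= 0)) abort("tolerances must be positive")
  n <- nrow(features)
  if (n < min_features || n > max_features)
    abort(paste0("hypothesis must have between ", min_features, " and ",
                 max_features, " features (got ", n, ")"))
  if (n >= 2) {
    d <- as.matrix(stats::dist(features[, c("x", "y", "z")]))
    if (min(d[upper.tri(d)]) < min_distance)
      abort(paste0("inter-feature distance below the ", min_distance,
                   " Angstrom minimum"))
  }
  structure(list(features = features, name = name,
                 min_distance = min_distance),
            class = "vs_hypothesis")
}

#' @export
print.vs_hypothesis <- function(x, ...) {
  cat("# Pharmacophore hypothesis '", x$name, "': ",
      paste(sort(x$features$kind), collapse = ""), "\n", sep = "")
  print(x$features)
  invisible(x)
}

#' Read/write a hypothesis as JSON
#'
#' Format: `{"name": ..., "features": [{"kind", "x", "y", "z",
#' "tolerance"}, ...]}`.
#'
#' @param x a `vs_hypothesis`.
#' @param path file path.
#' @param ... validation arguments passed on to [hypothesis()].
#' @return `write_hypothesis()` returns `path` invisibly;
#'   `read_hypothesis()` the parsed hypothesis.
#' @export
write_hypothesis <- function(x, path) {
  jsonlite::write_json(list(name = x$name, features = x$features), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hypothesis
#' @export
read_hypothesis <- function(path, ...) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  hypothesis(as_tibble(obj$features), name = obj$name %||% "hypothesis", ...)
}

#' Build a hypothesis from a reference conformation
#'
#' Takes the perceived features of one reference conformer, keeps a
#' user-selected subset, prunes features that sit closer than the minimum
#' inter-feature distance (earlier features win), and applies a uniform
#' tolerance.
#'
#' @param features perceived feature tibble (from [perceive_features()]).
#' @param select integer indices of features to keep (default all).
#' @param tolerance sphere radius in Angstrom (default 1.6).
#' @param name hypothesis name.
#' @inheritParams hypothesis
#' @return a `vs_hypothesis`.
#' @export
hypothesis_from_reference <- function(features, select = NULL,
                                      tolerance = 1.6,
                                      name = "reference",
                                      min_features = 4, max_features = 10,
                                      min_distance = 2.97) {
  if (!is.null(select)) features <- features[select, , drop = FALSE]
  keep <- rep(TRUE, nrow(features))
  pos <- as.matrix(features[, c("x", "y", "z")])
  for (i in seq_len(nrow(features))) {
    if (!keep[i]) next
    for (j in seq_len(i - 1)) {
      if (keep[j] &&
          sqrt(sum((pos[i, ] - pos[j, ])^2)) < min_distance) {
        keep[i] <- FALSE
        break
      }
    }
  }
  features <- features[keep, , drop = FALSE]
  features$tolerance <- tolerance
  hypothesis(features[, c("kind", "x", "y", "z", "tolerance")], name = name,
             min_features = min_features, max_features = max_features,
             min_distance = min_distance)
}

# --- feature perception --------------------------------------------------

is_amide_n <- function(graph, i) {
  b <- graph$bonds
  for (e in seq_len(nrow(b))) {
    other <- if (b$i[e] == i) b$j[e] else if (b$j[e] == i) b$i[e] else next
    if (graph$atoms$element[other] != "C") next
    # carbon double-bonded to oxygen?
    cb <- b[(b$i == other | b$j == other) & b$token == "=", , drop = FALSE]
    for (e2 in seq_len(nrow(cb))) {
      o <- if (cb$i[e2] == other) cb$j[e2] else cb$i[e2]
      if (graph$atoms$element[o] == "O") return(TRUE)
    }
  }
  FALSE
}

carboxyl_groups <- function(graph) {
  at <- graph$atoms
  b <- graph$bonds
  groups <- list()
  for (c_idx in which(at$element == "C")) {
    nb <- b[b$i == c_idx | b$j == c_idx, , drop = FALSE]
    o_idx <- integer(0); o_tok <- character(0)
    for (e in seq_len(nrow(nb))) {
      other <- if (nb$i[e] == c_idx) nb$j[e] else nb$i[e]
      if (at$element[other] == "O" && at$degree[other] == 1) {
        o_idx <- c(o_idx, other); o_tok <- c(o_tok, nb$token[e])
      }
    }
    if (length(o_idx) != 2) next
    acid <- ("=" %in% o_tok && any(at$nh[o_idx] > 0 | at$charge[o_idx] < 0))
    carboxylate <- all(at$sybyl[o_idx] == "O.co2")
    if (acid || carboxylate)
      groups[[length(groups) + 1]] <- c(c_idx, o_idx)
  }
  groups
}

#' Perceive pharmacophore features of a conformer
#'
#' Rule-based detection on the molecular graph, with positions taken from
#' the supplied conformer coordinates:
#' * **D** -- N or O bearing at least one hydrogen (not negatively
#'   charged), at the heavy atom;
#' * **A** -- O not positively charged, or N with an available lone pair
#'   (not an aromatic NH, not an amide N, not positively charged /
#'   quaternary), at the heavy atom;
#' * **R** -- each aromatic ring, at its centroid;
#' * **H** -- each connected group of two or more carbons having no
#'   non-carbon heavy neighbour, at its centroid;
#' * **P** -- formally positive atoms and neutral non-amide, non-aromatic
#'   amine nitrogens, at the atom;
#' * **N** -- carboxylic acid / carboxylate groups (at the group centroid)
#'   and any remaining formally negative atom.
#'
#' @param graph molecular graph.
#' @param coords `n_atoms` x 3 coordinate matrix (Angstrom); defaults to
#'   the coordinates stored in the graph.  Missing coordinates are fatal.
#' @return tibble `(kind, x, y, z, atoms)` where `atoms` lists the
#'   contributing atom indices.
#' @export
perceive_features <- function(graph, coords = NULL) {
  at <- graph$atoms
  if (is.null(coords)) coords <- as.matrix(at[, c("x", "y", "z")])
  if (nrow(coords) != nrow(at) || anyNA(coords))
    abort("conformer coordinates missing or inconsistent with the graph")
  feats <- list()
  add <- function(kind, idx) {
    p <- colMeans(coords[idx, , drop = FALSE])
    feats[[length(feats) + 1]] <<- tibble(kind = kind, x = p[1], y = p[2],
                                          z = p[3], atoms = list(idx))
  }
  # donors / acceptors / ionizable singles
  carbox <- carboxyl_groups(graph)
  carbox_atoms <- unlist(carbox)
  for (i in seq_len(nrow(at))) {
    el <- at$element[i]
    if (el %in% c("N", "O") && at$nh[i] > 0 && at$charge[i] >= 0)
      add("D", i)
    if (el == "O" && at$charge[i] <= 0)
      add("A", i)
    if (el == "N" && at$charge[i] <= 0 && at$valence[i] <= 3 &&
        !(at$arom[i] && at$nh[i] > 0) && !is_amide_n(graph, i))
      add("A", i)
    nbrs <- bond_neighbors(graph, i)
    if (at$charge[i] > 0 ||
        (el == "N" && at$charge[i] == 0 && !at$arom[i] &&
         at$valence[i] == 3 && !is_amide_n(graph, i) &&
         !(i %in% carbox_atoms) &&
         length(nbrs) > 0 &&
         all(at$element[nbrs] == "C") && !any(at$arom[nbrs])))
      add("P", i)
    if (at$charge[i] < 0 && !(i %in% carbox_atoms))
      add("N", i)
  }
  # negative ionizable groups
  for (g in carbox) add("N", g)
  # aromatic rings
  for (ring in aromatic_rings(graph)) add("R", ring)
  # hydrophobic carbon groups
  hydro <- which(at$element == "C" &
                   vapply(seq_len(nrow(at)), function(i)
                     all(at$element[bond_neighbors(graph, i)] == "C"),
                     logical(1)) & !at$arom)
  if (length(hydro) > 1) {
    sub <- subgraph_components(graph, hydro)
    for (comp in sub) if (length(comp) >= 2) add("H", comp)
  }
  if (length(feats) == 0)
    return(tibble(kind = character(0), x = numeric(0), y = numeric(0),
                  z = numeric(0), atoms = list()))
  bind_rows(feats)
}

bond_neighbors <- function(graph, i) {
  b <- graph$bonds
  c(b$j[b$i == i], b$i[b$j == i])
}

subgraph_components <- function(graph, vertices) {
  sub_b <- graph$bonds[graph$bonds$i %in% vertices &
                         graph$bonds$j %in% vertices, , drop = FALSE]
  # simple union-find over vertex labels
  parent <- setNames(vertices, as.character(vertices))
  findp <- function(v) {
    while (parent[[as.character(v)]] != v) v <- parent[[as.character(v)]]
    v
  }
  for (e in seq_len(nrow(sub_b))) {
    a <- findp(sub_b$i[e]); b <- findp(sub_b$j[e])
    if (a != b) parent[[as.character(a)]] <- b
  }
  roots <- vapply(vertices, findp, numeric(1))
  split(vertices, roots)
}

# --- conformers ----------------------------------------------------------

#' Generate a conformer ensemble
#'
#' Embeds up to `max_conformers` seeded distance-geometry conformers per
#' molecule, minimises them with the MMFF94 force field and keeps those
#' within `energy_window` kcal/mol of each molecule's minimum after RMS
#' deduplication.  This is the package's stand-in for systematic
#' low-energy conformational sampling; generation is fully deterministic
#' given `seed`.  The work is done by the RDKit helper script shipped at
#' `system.file("python", "gen_conformers.py", package = "vsfuse")`.
#'
#' @param mols molecule tibble.
#' @param max_conformers cap per molecule (default 255).
#' @param energy_window kcal/mol above the per-molecule minimum (default
#'   20).
#' @param seed integer seed for the distance-geometry embedding.
#' @return tibble `(id, conformer, energy, coords)`; `energy` is relative
#'   (kcal/mol), `coords` a heavy-atom coordinate matrix aligned with the
#'   molecule's graph atoms.
#' @export
generate_conformers <- function(mols, max_conformers = 255,
                                energy_window = 20, seed = 1) {
  stopifnot(nrow(mols) > 0)
  dir <- tempfile("confgen")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  smi <- file.path(dir, "in.smi")
  writeLines(paste(mols$smiles, mols$id), smi)
  confs <- file.path(dir, "confs.sdf")
  script <- system.file("python", "gen_conformers.py", package = "vsfuse")
  out <- system2("python", c(script, smi, confs,
                             "--max-conformers", format(max_conformers),
                             "--energy-window", format(energy_window),
                             "--seed", format(as.integer(seed))),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status") %||% 0L
  if (status == 3L)
    abort(paste0("3D embedding failed: ",
                 paste(grep("embedding failed", out, value = TRUE),
                       collapse = "; ")))
  if (status != 0L || !file.exists(confs) || file.size(confs) == 0)
    abort(paste0("conformer generation failed: ",
                 paste(tail(out, 3), collapse = "; ")))
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(confs))
  ids <- ChemmineR::sdfid(sdfset)
  missing <- setdiff(mols$id, unique(ids))
  if (length(missing))
    abort(paste0("3D embedding failed for: ",
                 paste(head(missing, 5), collapse = ", ")))
  rows <- list()
  for (mid in mols$id) {
    idx <- which(ids == mid)
    g <- mols$graph[[match(mid, mols$id)]]
    for (ci in seq_along(idx)) {
      k <- idx[ci]
      ab <- ChemmineR::atomblock(sdfset[[k]])
      elem <- sub("_.*$", "", rownames(ab))
      heavy <- which(toupper(elem) != "H")
      if (!identical(toupper(elem[heavy]), toupper(g$atoms$element)))
        abort(paste0("conformer atom order inconsistent with graph for ",
                     mid))
      db <- ChemmineR::datablock(sdfset[[k]])
      energy <- suppressWarnings(as.numeric(
        db[grep("^energy_rel", names(db))][1]))
      rows[[length(rows) + 1]] <- tibble(
        id = mid, conformer = ci,
        energy = if (length(energy)) energy else NA_real_,
        coords = list(unname(as.matrix(ab[heavy, 1:3, drop = FALSE]))))
    }
  }
  bind_rows(rows)
}

# --- matching ------------------------------------------------------------

# least-squares rigid superposition (Kabsch); returns the transform mapping
# P onto Q and the per-point residual distances
kabsch_residuals <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  P_fit <- Q0 * 0
  P_fit <- P0 %*% t(R)
  resid <- sqrt(rowSums((P_fit - Q0)^2))
  list(residuals = resid, rotation = R, shift = cq - cp)
}

#' Match a conformer's features against a hypothesis
#'
#' Exhaustive backtracking over injective, kind-compatible assignments of
#' hypothesis features to perceived features, pruned by pairwise distances
#' (a partial assignment survives only while
#' `|d_ij(features) - d_ij(hypothesis)| <= tol_i + tol_j` for all assigned
#' pairs).  Each surviving complete assignment is rigidly superposed by
#' least squares; the conformer is a hit when every assigned feature lies
#' within its tolerance sphere.  The best (lowest RMS residual) valid
#' assignment is reported.
#'
#' @param hyp a [hypothesis()].
#' @param features perceived feature tibble for one conformer.
#' @param prune use pairwise-distance pruning (disable only to cross-check
#'   against the brute-force search; results are identical).
#' @return list with `hit` (logical), `assignment` (feature row per
#'   hypothesis feature, or `NULL`), `fit` (RMS residual, `NA` if no
#'   match).
#' @export
match_hypothesis <- function(hyp, features, prune = TRUE) {
  stopifnot(inherits(hyp, "vs_hypothesis"))
  hf <- hyp$features
  nh <- nrow(hf)
  fpos <- as.matrix(features[, c("x", "y", "z")])
  hpos <- as.matrix(hf[, c("x", "y", "z")])
  hd <- as.matrix(stats::dist(hpos))
  cand <- lapply(hf$kind, function(k) which(features$kind == k))
  if (any(lengths(cand) == 0))
    return(list(hit = FALSE, assignment = NULL, fit = NA_real_))
  # search order: most constrained hypothesis feature first
  ord <- order(lengths(cand))
  best <- list(hit = FALSE, assignment = NULL, fit = NA_real_)
  assign_vec <- integer(nh)
  recurse <- function(step) {
    if (step > nh) {
      fit <- assignment_fit(hf, assign_vec, fpos, hpos)
      if (!is.na(fit) && (!best$hit || fit < best$fit))
        best <<- list(hit = TRUE, assignment = assign_vec, fit = fit)
      return(invisible())
    }
    i <- ord[step]
    for (f in cand[[i]]) {
      if (f %in% assign_vec[ord[seq_len(step - 1)]]) next
      ok <- TRUE
      if (prune && step > 1) {
        for (pstep in seq_len(step - 1)) {
          j <- ord[pstep]
          dij <- sqrt(sum((fpos[f, ] - fpos[assign_vec[j], ])^2))
          if (abs(dij - hd[i, j]) > hf$tolerance[i] + hf$tolerance[j]) {
            ok <- FALSE
            break
          }
        }
      }
      if (!ok) next
      assign_vec[i] <<- f
      recurse(step + 1)
      assign_vec[i] <<- 0L
    }
  }
  recurse(1)
  best
}

assignment_fit <- function(hf, assign_vec, fpos, hpos) {
  P <- fpos[assign_vec, , drop = FALSE]
  k <- kabsch_residuals(P, hpos)
  if (all(k$residuals <= hf$tolerance)) sqrt(mean(k$residuals^2))
  else NA_real_
}

#' Screen feature sets against a hypothesis
#'
#' @param hyp a [hypothesis()].
#' @param feature_sets tibble with columns `id` and `features` (list of
#'   per-conformer feature tibbles); multiple rows per id are treated as
#'   conformers of one compound.
#' @return tibble `(id, hit, fit)`: a compound hits when any conformer
#'   matches; `fit` is the best RMS residual.
#' @export
screen_features <- function(hyp, feature_sets) {
  res <- feature_sets |>
    group_by(.data$id) |>
    summarise(matches = list(lapply(.data$features, match_hypothesis,
                                    hyp = hyp)), .groups = "drop")
  res$hit <- map_lgl(res$matches, function(ms) any(map_lgl(ms, `[[`, "hit")))
  res$fit <- map_dbl(res$matches, function(ms) {
    fits <- map_dbl(ms, `[[`, "fit")
    if (all(is.na(fits))) NA_real_ else min(fits, na.rm = TRUE)
  })
  res[, c("id", "hit", "fit")]
}

#' Screen a labeled set and compute validation metrics
#'
#' Every compound is matched (hit when any conformer matches); sensitivity,
#' specificity and hit rate follow from the hit list, and a ROC over fit
#' values (hits ranked best-fit first, misses ranked last) gives the AUC.
#'
#' @param hyp a [hypothesis()].
#' @param feature_sets tibble `(id, label, features)` as produced by
#'   [make_planted_pharmacophore()] or assembled from
#'   [generate_conformers()] + [perceive_features()].
#' @return object of class `vs_pharm_screen`: list with `hits`, `se`,
#'   `sp`, `hit_rate`, `roc` (a `vs_roc`).
#' @export
screen_and_validate <- function(hyp, feature_sets) {
  if (!all(c("id", "label", "features") %in% names(feature_sets)))
    abort("feature_sets needs id, label, features columns")
  labels <- dplyr::distinct(feature_sets[, c("id", "label")])
  if (!all(c("active", "decoy") %in% labels$label))
    abort("validation needs both actives and decoys")
  hits <- screen_features(hyp, feature_sets)
  hits <- left_join(hits, labels, by = "id")
  tp <- sum(hits$hit & hits$label == "active")
  fn <- sum(!hits$hit & hits$label == "active")
  fp <- sum(hits$hit & hits$label == "decoy")
  tn <- sum(!hits$hit & hits$label == "decoy")
  ord <- hits[order(!hits$hit, hits$fit, hits$id), , drop = FALSE]
  roc <- roc_auc(labeled_ranking(ord$id, ord$label))
  structure(list(hits = hits, se = sensitivity(tp, fn),
                 sp = specificity(tn, fp),
                 hit_rate = mean(hits$hit), roc = roc),
            class = "vs_pharm_screen")
}

#' @export
print.vs_pharm_screen <- function(x, ...) {
  cat(sprintf(
    "# Pharmacophore screen: hit rate %.3f | Se %.3f | Sp %.3f | AUC %.3f\n",
    x$hit_rate, x$se, x$sp, x$roc$auc))
  invisible(x)
}

#' Screen a molecule library against a hypothesis
#'
#' Convenience wrapper: generates conformers, perceives features and runs
#' [screen_features()].
#'
#' @param hyp a [hypothesis()].
#' @param mols molecule tibble.
#' @inheritParams generate_conformers
#' @return hit tibble as from [screen_features()].
#' @export
screen_library <- function(hyp, mols, max_conformers = 255,
                           energy_window = 20, seed = 1) {
  confs <- generate_conformers(mols, max_conformers, energy_window, seed)
  confs$features <- pmap(list(confs$id, confs$coords), function(mid, xyz) {
    perceive_features(mols$graph[[match(mid, mols$id)]], xyz)
  })
  screen_features(hyp, confs[, c("id", "features")])
}
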