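#' Active clustering, representative selection and decoy generation
#'
#' Validation sets are prepared the way retrospective screening studies do
#' it: cluster the known actives on fingerprint Tanimoto distance, keep a
#' few diverse, potent representatives per cluster, and pick decoys that
#' match the actives' physicochemical profile while being topologically
#' dissimilar to all of them.
#'
#' @name vsfuse-prep
NULL

#' Hierarchical clustering of actives
#'
#' Agglomerative average-linkage clustering on the pairwise Tanimoto
#' distance (1 - similarity) under the chosen fingerprint, cut at a merge
#' height threshold.  The distance matrix is order-free, so cluster content
#' does not depend on input order (exact merge-height ties follow the
#' deterministic policy of [stats::hclust()]).
#'
#' @param actives molecule tibble (at least two compounds, unique ids).
#' @param kind fingerprint kind for the distance (default `"molprint2d"`).
#' @param threshold merge-distance cut in `[0, 1]`.
#' @return tibble `(id, cluster)` with the dendrogram in attribute
#'   `hclust`.
#' @export
cluster_actives <- function(actives, kind = "molprint2d", threshold = 0.6) {
  if (nrow(actives) < 2) abort("clustering needs at least two actives")
  if (anyDuplicated(actives$id)) abort("duplicate ids in actives")
  fps <- fingerprint_table(actives, kinds = kind)
  sim <- tanimoto_matrix(setNames(fps$bits, fps$id),
                         setNames(fps$bits, fps$id))
  d <- as.dist(1 - sim)
  hc <- hclust(d, method = "average")
  cl <- cutree(hc, h = threshold)
  out <- tibble(id = actives$id, cluster = unname(cl[actives$id]))
  attr(out, "hclust") <- hc
  attr(out, "threshold") <- threshold
  attr(out, "kind") <- kind
  out
}

#' Select diverse, potent cluster representatives
#'
#' Per cluster, up to `max_per_cluster` compounds are kept: the most potent
#' first, then greedily the compound most dissimilar (MaxMin on Tanimoto
#' similarity) to those already selected, breaking ties toward higher
#' potency then id.
#'
#' @param actives molecule tibble.
#' @param assignment cluster tibble from [cluster_actives()].
#' @param activities named numeric vector id -> potency (larger = more
#'   potent, e.g. pIC50); every clustered id must be present.
#' @param max_per_cluster cap per cluster (default 3).
#' @param kind fingerprint for the dissimilarity (defaults to the one used
#'   for clustering).
#' @return character vector of selected ids.
#' @export
select_representatives <- function(actives, assignment, activities,
                                   max_per_cluster = 3, kind = NULL) {
  missing <- setdiff(assignment$id, names(activities))
  if (length(missing))
    abort(paste0("missing activity for: ", paste(head(missing, 5),
                                                 collapse = ", ")))
  kind <- kind %||% attr(assignment, "kind") %||% "molprint2d"
  fps <- fingerprint_table(actives, kinds = kind)
  sim <- tanimoto_matrix(setNames(fps$bits, fps$id),
                         setNames(fps$bits, fps$id))
  selected <- character(0)
  for (cl in sort(unique(assignment$cluster))) {
    ids <- assignment$id[assignment$cluster == cl]
    pot <- activities[ids]
    take <- ids[order(-pot, ids)][1]          # most potent first
    while (length(take) < min(max_per_cluster, length(ids))) {
      rest <- setdiff(ids, take)
      # MaxMin: farthest (lowest max similarity) from current selection
      far <- vapply(rest, function(i)
        max(sim[i, take]), numeric(1))
      cand <- rest[order(far, -activities[rest], rest)][1]
      take <- c(take, cand)
    }
    selected <- c(selected, take)
  }
  selected
}

#' Decoy-matching specification
#'
#' Tolerances for property matching and the topological dissimilarity
#' ceiling, in the style of DUD-E-like decoy pipelines.  An eligible decoy
#' must sit within all property tolerances of at least one active and have
#' fingerprint Tanimoto similarity of at most `max_tanimoto` to **every**
#' active.
#'
#' @param mw_tol molecular-weight tolerance (Da).
#' @param clogp_tol clogP tolerance.
#' @param hbd_tol,hba_tol,rotb_tol count tolerances.
#' @param max_tanimoto similarity ceiling to actives (0 < ceiling < 1).
#' @param min_ratio,max_ratio decoys accepted per active.
#' @param kind fingerprint for the similarity ceiling.
#' @return list of class `vs_decoy_spec`.
#' @export
decoy_spec <- function(mw_tol = 25, clogp_tol = 1.0, hbd_tol = 1,
                       hba_tol = 1, rotb_tol = 1, max_tanimoto = 0.35,
                       min_ratio = 4, max_ratio = 36, kind = "radial") {
  stopifnot(mw_tol >= 0, clogp_tol >= 0, hbd_tol >= 0, hba_tol >= 0,
            rotb_tol >= 0, max_tanimoto > 0, max_tanimoto < 1,
            min_ratio <= max_ratio)
  structure(list(mw_tol = mw_tol, clogp_tol = clogp_tol, hbd_tol = hbd_tol,
                 hba_tol = hba_tol, rotb_tol = rotb_tol,
                 max_tanimoto = max_tanimoto, min_ratio = min_ratio,
                 max_ratio = max_ratio, kind = kind),
            class = "vs_decoy_spec")
}

decoy_eligibility <- function(actives, pool, spec) {
  # property window: |delta| <= tol against at least one active
  prop_ok <- matrix(FALSE, nrow(pool), nrow(actives))
  for (a in seq_len(nrow(actives))) {
    prop_ok[, a] <-
      abs(pool$mw - actives$mw[a]) <= spec$mw_tol &
      abs(pool$clogp - actives$clogp[a]) <= spec$clogp_tol &
      abs(pool$hbd - actives$hbd[a]) <= spec$hbd_tol &
      abs(pool$hba - actives$hba[a]) <= spec$hba_tol &
      abs(pool$rotb - actives$rotb[a]) <= spec$rotb_tol
  }
  afp <- fingerprint_table(actives, kinds = spec$kind)
  pfp <- fingerprint_table(pool, kinds = spec$kind)
  sim <- tanimoto_matrix(setNames(pfp$bits, pfp$id),
                         setNames(afp$bits, afp$id))
  sim_ok <- apply(sim, 1, max) <= spec$max_tanimoto
  list(prop_ok = prop_ok, sim_ok = sim_ok, max_sim = apply(sim, 1, max))
}

#' Generate a property-matched decoy set
#'
#' Scans a candidate pool for compounds that mimic the actives physically
#' (molecular weight, clogP, H-bond donors/acceptors, rotatable bonds
#' within the spec tolerances of at least one active) while staying
#' topologically dissimilar to every active (fingerprint Tanimoto at or
#' below the ceiling).  Eligible decoys are assigned to their
#' property-matched actives up to `max_ratio` each; actives left below
#' `min_ratio` are reported with a warning.
#'
#' @param actives molecule tibble with properties, fingerprintable.
#' @param pool candidate molecule tibble with properties.
#' @param spec a [decoy_spec()].
#' @return list with `decoys` (molecule tibble, disjoint from the actives)
#'   and `report` (tibble per active: eligible and assigned counts,
#'   shortfall flag).
#' @export
generate_decoys <- function(actives, pool, spec = decoy_spec()) {
  if (nrow(pool) == 0) abort("empty decoy candidate pool")
  if (!has_properties(actives) || !has_properties(pool))
    abort("actives and pool must have properties; run compute_properties()")
  pool <- pool[!(pool$id %in% actives$id) &
                 !(pool$smiles %in% actives$smiles), , drop = FALSE]
  elig <- decoy_eligibility(actives, pool, spec)
  ok <- elig$sim_ok & rowSums(elig$prop_ok) > 0

  assigned <- rep(0L, nrow(actives))
  take <- logical(nrow(pool))
  # round-robin over actives so the per-active quota fills evenly
  cand_idx <- which(ok)
  for (idx in cand_idx) {
    targets <- which(elig$prop_ok[idx, ] & assigned < spec$max_ratio)
    if (length(targets) == 0) next
    tgt <- targets[which.min(assigned[targets])]
    assigned[tgt] <- assigned[tgt] + 1L
    take[idx] <- TRUE
  }
  report <- tibble(
    id = actives$id,
    eligible = colSums(elig$prop_ok & matrix(elig$sim_ok, nrow(pool),
                                             nrow(actives))),
    assigned = assigned,
    shortfall = assigned < spec$min_ratio
  )
  if (any(report$shortfall))
    warn(paste0(sum(report$shortfall), " active(s) below the minimum ",
                "decoy/ligand ratio of ", spec$min_ratio))
  list(decoys = pool[take, , drop = FALSE], report = report)
}
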