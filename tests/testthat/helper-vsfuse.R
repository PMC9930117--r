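# Shared fixtures and independent oracles for the test suite.  Expensive
# objects are built once per test run and memoised in this environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small molecule panel used across tests
panel_mols <- function() fixture("panel", function() {
  suppressWarnings(parse_molecules(
    c("CCO", "c1ccccc1", "CC(=O)[O-]", "C", "CCCCCC", "CC", "CCCCCCC",
      "c1ccncc1", "c1ccc2ccccc2c1", "CC(=O)Oc1ccccc1C(O)=O", "C1CCCCC1"),
    c("ethanol", "benzene", "acetate", "methane", "hexane", "ethane",
      "heptane", "pyridine", "naphthalene", "aspirin", "cyclohexane")))
})

panel_graph <- function(id) {
  m <- panel_mols()
  m$graph[[match(id, m$id)]]
}

# small synthetic benchmark reused by fusion/prep tests
small_bench <- function() fixture("small_bench", function() {
  suppressWarnings(make_benchmark(
    benchmark_spec(n_actives = 6, n_decoys = 40, seed = 42)))
})

# ---- independent oracles -------------------------------------------------

# AUC by brute-force pair counting (Mann-Whitney; ties over ranks cannot
# occur in a materialised ranking)
oracle_auc <- function(ranking) {
  act <- ranking$rank[ranking$label == "active"]
  dec <- ranking$rank[ranking$label == "decoy"]
  mean(outer(act, dec, function(a, d) (a < d) + 0.5 * (a == d)))
}

# BEDROC from the published formula, written directly
oracle_bedroc <- function(ranking, alpha) {
  N <- nrow(ranking)
  n <- sum(ranking$label == "active")
  ra <- n / N
  s <- sum(exp(-alpha * ranking$rank[ranking$label == "active"] / N))
  rie <- s / (ra * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  rie_min <- (1 - exp(alpha * ra)) / (ra * (1 - exp(alpha)))
  rie_max <- (1 - exp(-alpha * ra)) / (ra * (1 - exp(-alpha)))
  (rie - rie_min) / (rie_max - rie_min)
}

# dendritic fragment count for a linear alkane with n carbons, by direct
# combinatorial enumeration of path compositions (end/mid atom types)
oracle_dendritic_alkane <- function(n_carbons, max_bonds = 5) {
  stopifnot(n_carbons >= 3)
  type <- ifelse(seq_len(n_carbons) %in% c(1, n_carbons), "e", "m")
  pats <- character(0)
  for (L in seq_len(min(max_bonds, n_carbons - 1))) {
    for (s in seq_len(n_carbons - L)) {
      t <- type[s:(s + L)]
      f <- paste(t, collapse = "")
      r <- paste(rev(t), collapse = "")
      pats <- c(pats, min(f, r))
    }
  }
  length(unique(type)) + length(unique(pats))
}

# brute-force pharmacophore assignment search: all injective
# kind-compatible assignments, no pruning, full superposition check
oracle_match <- function(hyp, features) {
  hf <- hyp$features
  nh <- nrow(hf)
  cand <- lapply(hf$kind, function(k) which(features$kind == k))
  if (any(lengths(cand) == 0))
    return(list(hit = FALSE, fit = NA_real_))
  grid <- expand.grid(cand, KEEP.OUT.ATTRS = FALSE)
  best <- list(hit = FALSE, fit = NA_real_)
  fpos <- as.matrix(features[, c("x", "y", "z")])
  hpos <- as.matrix(hf[, c("x", "y", "z")])
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    if (anyDuplicated(a)) next
    k <- vsfuse:::kabsch_residuals(fpos[a, , drop = FALSE], hpos)
    if (all(k$residuals <= hf$tolerance)) {
      fit <- sqrt(mean(k$residuals^2))
      if (!best$hit || fit < best$fit) best <- list(hit = TRUE, fit = fit)
    }
  }
  best
}

# labeled ranking with a given number of hits in the leading block and the
# remaining actives at the very end
block_ranking <- function(N, N_act, hits_on_top) {
  lab <- rep("decoy", N)
  lab[seq_len(hits_on_top)] <- "active"
  rest <- N_act - hits_on_top
  if (rest > 0) lab[seq(N - rest + 1, N)] <- "active"
  labeled_ranking(sprintf("C%04d", seq_len(N)), lab)
}

random_ranking <- function(N, N_act) {
  pos <- sample.int(N, N_act)
  lab <- rep("decoy", N)
  lab[pos] <- "active"
  labeled_ranking(sprintf("C%04d", seq_len(N)), lab)
}
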