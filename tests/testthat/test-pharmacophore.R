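# a well-spread 4-feature toy hypothesis used throughout
toy_hypothesis <- function(tolerance = 1.0) {
  hypothesis(tibble::tibble(
    kind = c("D", "A", "R", "H"),
    x = c(0, 4, 0, 4), y = c(0, 0, 4, 4), z = c(0, 1, 2, 0),
    tolerance = tolerance), name = "toy")
}

test_that("hypothesis construction enforces the feature contract", {
  expect_s3_class(toy_hypothesis(), "vs_hypothesis")
  f <- toy_hypothesis()$features
  expect_error(hypothesis(f[1:2, ]), "between 4 and 10")
  expect_error(hypothesis(dplyr::mutate(f, kind = c("D", "A", "Z", "H"))),
               "unknown feature kind")
  expect_error(hypothesis(dplyr::mutate(f, tolerance = -1)), "positive")
  close_f <- dplyr::mutate(f, x = c(0, 1, 0, 4))  # features 1 & 2 too close
  expect_error(hypothesis(close_f), "2.97")
  # relaxed limits admit toy three-feature hypotheses
  expect_s3_class(hypothesis(f[c(1, 2, 3), ], min_features = 3),
                  "vs_hypothesis")
})

test_that("hypotheses round-trip through JSON", {
  h <- toy_hypothesis()
  tf <- tempfile(fileext = ".json")
  write_hypothesis(h, tf)
  back <- read_hypothesis(tf)
  expect_equal(back$name, h$name)
  expect_equal(as.data.frame(back$features), as.data.frame(h$features))
})

test_that("feature perception matches chemistry on reference molecules", {
  mols <- suppressWarnings(parse_molecules(
    c("c1ccccc1", "CCO", "CC(=O)[O-]", "C[NH3+]", "CCCCCC"),
    c("benzene", "ethanol", "acetate", "mam", "hexane")))
  confs <- generate_conformers(mols, max_conformers = 4, seed = 2)
  feat <- function(id) {
    perceive_features(mols$graph[[match(id, mols$id)]],
                      confs$coords[confs$id == id][[1]])
  }
  fb <- feat("benzene")
  expect_equal(fb$kind, "R")
  ring_atoms <- fb$atoms[[1]]
  centroid <- colMeans(confs$coords[confs$id == "benzene"][[1]][ring_atoms, ])
  expect_equal(c(fb$x, fb$y, fb$z), unname(centroid), tolerance = 1e-9)

  fe <- feat("ethanol")
  expect_equal(sort(fe$kind), c("A", "D"))
  expect_equal(fe$x[fe$kind == "D"], fe$x[fe$kind == "A"])

  fa <- feat("acetate")
  expect_equal(sum(fa$kind == "N"), 1)

  fm <- feat("mam")
  expect_true("P" %in% fm$kind)

  fh <- feat("hexane")
  expect_equal(fh$kind, "H")

  expect_error(perceive_features(mols$graph[[1]],
                                 matrix(NA_real_, 6, 3)),
               "coordinates")
})

test_that("conformer ensembles are capped, windowed and deterministic", {
  mols <- suppressWarnings(parse_molecules(
    c("c1ccccc1", "CCCC"), c("benzene", "butane")))
  confs <- generate_conformers(mols, max_conformers = 50,
                               energy_window = 20, seed = 4)
  # rigid benzene keeps one conformer
  expect_equal(sum(confs$id == "benzene"), 1)
  # butane keeps at least anti and gauche
  expect_gte(sum(confs$id == "butane"), 2)
  expect_true(all(confs$energy <= 20))
  expect_equal(min(confs$energy[confs$id == "butane"]), 0)
  confs2 <- generate_conformers(mols, max_conformers = 50,
                                energy_window = 20, seed = 4)
  expect_identical(confs$coords, confs2$coords)
  expect_error(generate_conformers(
    suppressWarnings(parse_molecules("C", "m"))[0, ]), "nrow")
})

test_that("matching is exact on planted geometries", {
  hyp <- toy_hypothesis()
  feats <- hyp$features[, c("kind", "x", "y", "z")]
  self <- match_hypothesis(hyp, feats)
  expect_true(self$hit)
  expect_equal(self$fit, 0, tolerance = 1e-9)
  # missing kind is infeasible
  expect_false(match_hypothesis(hyp, feats[feats$kind != "A", ])$hit)
  # 0.3 A noise within 1.0 A spheres hits; 5 A noise misses
  set.seed(6)
  jitter <- function(sd) dplyr::mutate(feats, x = x + rnorm(4, 0, sd),
                                       y = y + rnorm(4, 0, sd),
                                       z = z + rnorm(4, 0, sd))
  expect_true(match_hypothesis(hyp, jitter(0.3))$hit)
  expect_false(match_hypothesis(hyp, jitter(5))$hit)
})

test_that("matching is invariant under rigid motion of the conformer", {
  hyp <- toy_hypothesis()
  feats <- hyp$features[, c("kind", "x", "y", "z")]
  set.seed(9)
  for (k in 1:10) {
    rot <- vsfuse:::random_rotation()
    pos <- as.matrix(feats[, c("x", "y", "z")]) %*% rot
    pos <- sweep(pos, 2, runif(3, -30, 30), `+`)
    moved <- dplyr::mutate(feats, x = pos[, 1], y = pos[, 2], z = pos[, 3])
    m <- match_hypothesis(hyp, moved)
    expect_true(m$hit)
    expect_equal(m$fit, 0, tolerance = 1e-6)
  }
})

test_that("pruned search agrees with the brute-force assignment oracle", {
  set.seed(13)
  for (k in 1:30) {
    # random hypothesis (4 features) and random conformer features
    hf <- tibble::tibble(
      kind = sample(c("D", "A", "R", "H"), 4, replace = TRUE),
      x = runif(4, 0, 10), y = runif(4, 0, 10), z = runif(4, 0, 10),
      tolerance = runif(4, 0.8, 2))
    d <- as.matrix(stats::dist(hf[, c("x", "y", "z")]))
    if (nrow(hf) > 1 && min(d[upper.tri(d)]) < 2.97) next
    hyp <- hypothesis(hf, min_features = 3)
    nf <- sample(4:8, 1)
    feats <- tibble::tibble(
      kind = sample(c("D", "A", "R", "H"), nf, replace = TRUE),
      x = runif(nf, 0, 10), y = runif(nf, 0, 10), z = runif(nf, 0, 10))
    pruned <- match_hypothesis(hyp, feats, prune = TRUE)
    plain <- match_hypothesis(hyp, feats, prune = FALSE)
    oracle <- oracle_match(hyp, feats)
    expect_equal(pruned$hit, oracle$hit)
    expect_equal(plain$hit, oracle$hit)
    if (oracle$hit) {
      expect_equal(pruned$fit, oracle$fit, tolerance = 1e-9)
      expect_equal(plain$fit, oracle$fit, tolerance = 1e-9)
    }
  }
})

test_that("tightening tolerances never converts a miss into a hit", {
  hyp_loose <- toy_hypothesis(tolerance = 1.5)
  hyp_tight <- toy_hypothesis(tolerance = 0.5)
  set.seed(21)
  feats <- hyp_loose$features[, c("kind", "x", "y", "z")]
  for (k in 1:20) {
    noisy <- dplyr::mutate(feats, x = x + rnorm(4, 0, 0.6),
                           y = y + rnorm(4, 0, 0.6),
                           z = z + rnorm(4, 0, 0.6))
    if (match_hypothesis(hyp_tight, noisy)$hit)
      expect_true(match_hypothesis(hyp_loose, noisy)$hit)
  }
})

test_that("screening a labeled planted set recovers the ground truth", {
  hyp <- toy_hypothesis()
  sets <- make_planted_pharmacophore(15, 30, hyp, noise_sd = 0.2, seed = 8)
  sc <- screen_and_validate(hyp, sets)
  expect_gte(sc$se, 0.9)
  expect_gte(sc$sp, 0.9)
  expect_gte(sc$roc$auc, 0.9)
  # zero noise: every active self-matches
  sc0 <- screen_and_validate(hyp,
                             make_planted_pharmacophore(10, 10, hyp,
                                                        noise_sd = 0,
                                                        seed = 9))
  expect_equal(sc0$se, 1)
  # huge noise: sensitivity collapses, specificity stays high
  scn <- screen_and_validate(hyp,
                             make_planted_pharmacophore(10, 10, hyp,
                                                        noise_sd = 8,
                                                        seed = 10))
  expect_lte(scn$se, 0.2)
  gl <- glance(sc)
  expect_named(gl, c("hit_rate", "se", "sp", "auc"))
})

test_that("hypotheses built from a reference conformation self-screen", {
  mols <- suppressWarnings(parse_molecules(
    c("OC(=O)c1ccc(Nc2ccccc2)cc1", "CCCCCCCC", "c1ccc2ccccc2c1"),
    c("act", "dec1", "dec2")))
  confs <- generate_conformers(mols, max_conformers = 10, seed = 3)
  f <- perceive_features(mols$graph[[1]],
                         confs$coords[confs$id == "act"][[1]])
  sel <- c(which(f$kind == "A")[2], which(f$kind == "R"))
  hyp <- hypothesis_from_reference(f, select = sel, tolerance = 1.6,
                                   min_features = 3)
  confs$features <- purrr::pmap(list(confs$id, confs$coords),
                                function(mid, xyz)
    perceive_features(mols$graph[[match(mid, mols$id)]], xyz))
  hits <- screen_features(hyp, confs[, c("id", "features")])
  expect_true(hits$hit[hits$id == "act"])
  expect_equal(hits$fit[hits$id == "act"], 0, tolerance = 1e-6)
  expect_false(any(hits$hit[hits$id != "act"]))
})
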