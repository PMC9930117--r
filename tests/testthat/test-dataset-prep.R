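test_that("average-linkage clustering cuts match a hand-built distance matrix", {
  mols <- suppressWarnings(parse_molecules(
    c("CCO", "OCC", "c1ccc2ccccc2c1"), c("a", "b", "c")))
  # a and b are the same molecule (distance 0); c is unrelated
  cl <- suppressWarnings(cluster_actives(mols, kind = "radial",
                                         threshold = 0.5))
  expect_equal(cl$cluster[cl$id == "a"], cl$cluster[cl$id == "b"])
  expect_false(cl$cluster[cl$id == "a"] == cl$cluster[cl$id == "c"])
  expect_equal(length(unique(cl$cluster)), 2)
  # extreme cuts (distinct compounds only, so no zero-distance pairs)
  mols2 <- panel_mols()[c(1, 2, 9), ]
  cl0 <- suppressWarnings(cluster_actives(mols2, "radial", threshold = 0))
  expect_equal(length(unique(cl0$cluster)), 3)
  cl1 <- suppressWarnings(cluster_actives(mols2, "radial", threshold = 1))
  expect_equal(length(unique(cl1$cluster)), 1)
  expect_error(cluster_actives(mols2[1, ]), "at least two")
  dup <- mols2
  dup$id <- c("x", "x", "y")
  expect_error(suppressWarnings(cluster_actives(dup)), "duplicate")
})

test_that("clustering assignments are invariant to input order", {
  act <- small_bench()$actives
  set.seed(8)
  perm <- sample.int(nrow(act))
  c1 <- suppressWarnings(cluster_actives(act, threshold = 0.6))
  c2 <- suppressWarnings(cluster_actives(act[perm, ], threshold = 0.6))
  # same partition regardless of labels chosen for the clusters
  part1 <- split(c1$id, c1$cluster)
  part2 <- split(c2$id, c2$cluster)
  norm <- function(p) sort(vapply(p, function(x)
    paste(sort(x), collapse = "|"), character(1)))
  expect_equal(norm(part1), norm(part2))
})

test_that("representative selection caps clusters and keeps the most potent", {
  act <- small_bench()$actives
  cl <- suppressWarnings(cluster_actives(act, threshold = 0.9))
  pot <- setNames(act$potency, act$id)
  sel <- suppressWarnings(select_representatives(act, cl, pot,
                                                 max_per_cluster = 3))
  tab <- table(cl$cluster[match(sel, cl$id)])
  expect_true(all(tab <= 3))
  for (c0 in unique(cl$cluster)) {
    ids <- cl$id[cl$cluster == c0]
    expect_true(ids[which.max(pot[ids])] %in% sel)
    # clusters at or below the cap are taken whole
    if (length(ids) <= 3) expect_true(all(ids %in% sel))
  }
  expect_error(select_representatives(act, cl, pot[-1]), "missing activity")
})

test_that("decoy generation enforces property windows and the similarity ceiling", {
  bench <- small_bench()
  act <- bench$actives
  pool <- bench$decoys
  spec <- decoy_spec()
  out <- suppressWarnings(generate_decoys(act, pool, spec))
  expect_true(nrow(out$decoys) > 0)
  # decoys are disjoint from the actives
  expect_length(intersect(out$decoys$id, act$id), 0)
  expect_length(intersect(out$decoys$smiles, act$smiles), 0)
  # exhaustive post-hoc verification of every emitted decoy
  afp <- purrr::map(act$graph, fp_radial)
  dfp <- purrr::map(out$decoys$graph, fp_radial)
  expect_lte(max(tanimoto_matrix(dfp, afp)), spec$max_tanimoto)
  for (k in seq_len(nrow(out$decoys))) {
    d <- out$decoys[k, ]
    ok <- any(abs(d$mw - act$mw) <= spec$mw_tol &
                abs(d$clogp - act$clogp) <= spec$clogp_tol &
                abs(d$hbd - act$hbd) <= spec$hbd_tol &
                abs(d$hba - act$hba) <= spec$hba_tol &
                abs(d$rotb - act$rotb) <= spec$rotb_tol)
    expect_true(ok, label = d$id)
  }
  expect_true(all(out$report$assigned <= spec$max_ratio))
})

test_that("ineligible pool compounds are rejected for the documented reason", {
  bench <- small_bench()
  act <- bench$actives
  # a same-scaffold analogue of an active fails the similarity ceiling even
  # though its properties match
  analogue <- suppressWarnings(compute_properties(suppressWarnings(
    parse_molecules(vsfuse:::fill_template(bench$spec$scaffold,
                                           c("C", "", "")), "ANAL1"))))
  pool <- dplyr::bind_rows(bench$decoys[1:5, ], analogue)
  out <- suppressWarnings(generate_decoys(act, pool, decoy_spec()))
  expect_false("ANAL1" %in% out$decoys$id)
  # a property-mismatched compound (tiny molecular weight) is rejected too
  tiny <- suppressWarnings(compute_properties(suppressWarnings(
    parse_molecules("CCO", "TINY"))))
  out2 <- suppressWarnings(generate_decoys(act,
                                           dplyr::bind_rows(bench$decoys[1:5, ],
                                                            tiny),
                                           decoy_spec()))
  expect_false("TINY" %in% out2$decoys$id)
  expect_error(generate_decoys(act, act[0, ], decoy_spec()), "empty")
})

test_that("a pool built to contain exactly four eligible decoys per active yields ratio four", {
  act <- suppressWarnings(compute_properties(suppressWarnings(
    parse_molecules("OC(=O)c1ccc(Nc2ccccc2)cc1", "A1"))))
  # four property-twins from unrelated scaffolds, verified eligible by
  # exhaustive check inside generate_decoys
  pool <- suppressWarnings(compute_properties(suppressWarnings(
    parse_molecules(c("OC(=O)C1CCN(CC1)C(=O)Cc1ccccc1",
                      "OC(=O)CN1CCC(Cc2ccccc2)CC1",
                      "O=C(NCc1cccnc1)C1CCC(O)CC1",
                      "OC(=O)CC1CCN(C(=O)C2CCCCC2)CC1"),
                    paste0("P", 1:4)))))
  spec <- decoy_spec(mw_tol = 60, clogp_tol = 2.5, hbd_tol = 2,
                     hba_tol = 2, rotb_tol = 2)
  out <- suppressWarnings(generate_decoys(act, pool, spec))
  expect_equal(out$report$assigned, 4)
  expect_false(any(out$report$shortfall))
})
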