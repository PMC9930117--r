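test_that("enrichment factor reproduces the worked validation-set values", {
  # 1198-compound set with 28 actives: the printed single-decimal EF values
  # are fixed by the formula once the retrieved-active counts are known
  cases <- list(
    list(hits = 12, x = 0.01, ef = 42.8),
    list(hits = 21, x = 0.05, ef = 15.0),
    list(hits = 22, x = 0.10, ef = 7.8),
    list(hits = 6,  x = 0.01, ef = 21.4),
    list(hits = 10, x = 0.05, ef = 7.1),
    list(hits = 28, x = 0.10, ef = 10.0),
    list(hits = 13, x = 0.10, ef = 4.6)
  )
  for (cs in cases) {
    r <- block_ranking(1198, 28, cs$hits)
    expect_equal(round(enrichment_factor(r, cs$x), 1), cs$ef,
                 ignore_attr = TRUE,
                 label = sprintf("%d hits at %g", cs$hits, cs$x))
  }
  # top-count rounding is half away from zero with a floor of one
  expect_equal(vsfuse:::round_half_up(c(11.98, 59.9, 119.8, 0.5, -0.5)),
               c(12, 60, 120, 1, -1))
})

test_that("EF is bounded and errors without actives", {
  r <- block_ranking(200, 20, 20)
  ef <- enrichment_factor(r, c(0.01, 0.1, 1))
  expect_true(all(ef <= 200 / 20 + 1e-12))
  expect_equal(unname(ef[3]), 1)  # whole database: hit rate equals base rate
  all_dec <- labeled_ranking(letters[1:5], rep("decoy", 5))
  expect_error(enrichment_factor(all_dec, 0.1), "no actives")
})

test_that("EF of uniform-random rankings averages one", {
  set.seed(2024)
  efs <- replicate(250, {
    enrichment_factor(random_ranking(300, 30), 0.10)
  })
  expect_equal(mean(efs), 1.0, tolerance = 0.1)
})

test_that("sensitivity and specificity follow the confusion-matrix ratios", {
  expect_equal(sensitivity(28, 0), 1)
  expect_equal(sensitivity(0, 28), 0)
  expect_equal(sensitivity(12, 16), 12 / 28, tolerance = 1e-12)
  expect_equal(specificity(1170, 0), 1)
  expect_equal(specificity(0, 1170), 0)
  expect_equal(specificity(1080, 90), 1080 / 1170)
  expect_error(sensitivity(0, 0), "undefined")
  expect_error(specificity(0, 0), "undefined")
})

test_that("ROC AUC equals the Mann-Whitney pair-counting oracle", {
  # six-compound toy A,D,A,D,D,A: actives at ranks 1,3,6 win 5 of the 9
  # active-decoy pairs, so the Mann-Whitney AUC is 5/9
  toy <- labeled_ranking(letters[1:6],
                         c("active", "decoy", "active", "decoy", "decoy",
                           "active"))
  expect_equal(roc_auc(toy)$auc, 5 / 9)
  expect_equal(roc_auc(toy)$auc, oracle_auc(toy))
  # oracle equivalence on random rankings up to N = 50
  set.seed(31)
  for (k in 1:40) {
    N <- sample(5:50, 1)
    r <- random_ranking(N, sample(seq_len(N - 1), 1))
    expect_equal(roc_auc(r)$auc, oracle_auc(r), tolerance = 1e-12)
  }
  # perfect ranking and degenerate input
  expect_equal(roc_auc(block_ranking(100, 10, 10))$auc, 1)
  expect_error(roc_auc(labeled_ranking("a", "active")), "both")
})

test_that("random-label rankings have AUC near one half", {
  set.seed(99)
  aucs <- replicate(20, roc_auc(random_ranking(2000, 200))$auc)
  # the per-seed spread of a random AUC at this size is about 0.02, so the
  # mean sits within 0.03 of one half and no single seed strays far
  expect_equal(mean(aucs), 0.5, tolerance = 0.03)
  expect_true(all(abs(aucs - 0.5) < 0.1))
})

test_that("BEDROC matches a direct exponential-sum evaluation", {
  r20 <- labeled_ranking(sprintf("x%02d", 1:20), {
    l <- rep("decoy", 20); l[c(1, 5, 17)] <- "active"; l
  })
  expect_equal(bedroc(r20, 20), oracle_bedroc(r20, 20), tolerance = 1e-12)
  set.seed(17)
  for (k in 1:25) {
    r <- random_ranking(sample(20:200, 1), sample(3:10, 1))
    a <- sample(c(2, 8, 20, 50), 1)
    expect_equal(bedroc(r, a), oracle_bedroc(r, a), tolerance = 1e-12)
  }
  expect_error(bedroc(r20, -1), "positive")
})

test_that("BEDROC approaches one for perfect early recognition", {
  r <- block_ranking(10000, 50, 50)
  expect_equal(bedroc(r, 20), 1, tolerance = 0.01)
})

test_that("the alpha=20 weight concentrates 80% of the score in the top 8%", {
  expect_equal(round(bedroc_weight_fraction(20, 0.08), 2), 0.80)
  expect_equal(bedroc_weight_fraction(20, 1), 1)
})

test_that("BEDROC agrees with AUC-like behaviour in the small-alpha limit", {
  set.seed(4)
  for (k in 1:10) {
    r <- random_ranking(400, 40)
    expect_equal(bedroc(r, 1e-3), roc_auc(r)$auc, tolerance = 0.02)
  }
})

test_that("promoting an active never decreases EF, AUC or BEDROC", {
  set.seed(12)
  for (k in 1:20) {
    r <- random_ranking(120, 12)
    act_pos <- which(r$label == "active")
    a <- act_pos[act_pos > 1][1]
    if (is.na(a)) next
    # swap the active up one position
    lab <- r$label
    lab[c(a - 1, a)] <- lab[c(a, a - 1)]
    r2 <- labeled_ranking(r$id, lab)
    expect_gte(enrichment_factor(r2, 0.1), enrichment_factor(r, 0.1))
    expect_gte(roc_auc(r2)$auc, roc_auc(r)$auc)
    expect_gte(bedroc(r2, 20), bedroc(r, 20))
  }
})

test_that("screen_metrics aggregates consistently and tidies", {
  r <- block_ranking(1198, 28, 12)
  m <- screen_metrics(r)
  expect_equal(m$ef$ef[1], 42.8, tolerance = 0.05)
  expect_equal(m$auc, roc_auc(r)$auc)
  expect_equal(m$bedroc, bedroc(r, 20))
  expect_equal(m$se, 12 / 28, tolerance = 1e-12)
  td <- tidy(m)
  expect_true(all(c("ef_0.01", "auc", "bedroc") %in% td$metric))
  gl <- glance(m)
  expect_equal(gl$n, 1198)
  expect_equal(gl$n_act, 28)
})

test_that("label_ranking joins labels onto a screening ranking", {
  rk <- tibble::tibble(library_id = c("b", "a", "c"), score = c(3, 2, 1),
                       rank = 1:3)
  lab <- c(a = "decoy", b = "active", c = "decoy")
  lr <- label_ranking(rk, lab)
  expect_equal(lr$id, c("b", "a", "c"))
  expect_equal(lr$label, c("active", "decoy", "decoy"))
  expect_error(label_ranking(rk, lab[1:2]), "missing")
})
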