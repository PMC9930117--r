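test_that("similarity_search builds a complete score table", {
  mols <- panel_mols()
  queries <- mols[mols$id == "benzene", ]
  library <- mols[mols$id %in% c("benzene", "cyclohexane", "ethanol"), ]
  st <- suppressWarnings(similarity_search(queries, library,
                                           measures = c("maccs", "radial")))
  expect_equal(nrow(st), 1 * 2 * 3)
  expect_true(all(st$sim >= 0 & st$sim <= 1))
  # self-similarity is exactly 1
  expect_equal(st$sim[st$library_id == "benzene"], c(1, 1))
  # benzene outranks cyclohexane for a benzene query on MACCS
  m <- st[st$measure == "maccs", ]
  expect_gt(m$sim[m$library_id == "benzene"],
            m$sim[m$library_id == "cyclohexane"])
  expect_error(similarity_search(queries[0, ], library), "non-empty")
})

test_that("MAX and SUM fusion rules follow their definitions", {
  expect_equal(fuse_max(c(0.3, 0.83871, 0.5)), 0.83871)
  expect_equal(fuse_max(c(0, 0, 0)), 0)
  expect_equal(fuse_sum(c(0.2, 0.3)), 0.5)
  expect_equal(fuse_sum(c(0, 0)), 0)
  expect_error(fuse_max(numeric(0)), "empty")
  expect_error(fuse_sum(numeric(0)), "empty")
  # max >= mean for every score list; max equals one of the inputs
  set.seed(11)
  for (k in 1:50) {
    s <- runif(sample(1:6, 1))
    expect_gte(fuse_max(s), fuse_sum(s) / length(s))
    expect_true(fuse_max(s) %in% s)
    expect_true(all(fuse_max(s) >= s))
  }
})

test_that("sum and mean fusion produce identical orderings", {
  set.seed(5)
  scores <- matrix(runif(50 * 4), 50, 4,
                   dimnames = list(sprintf("c%02d", 1:50), NULL))
  by_sum <- order(-apply(scores, 1, sum), rownames(scores))
  by_mean <- order(-apply(scores, 1, mean), rownames(scores))
  expect_identical(by_sum, by_mean)
})

test_that("methods A, B and C emit the contracted ranking counts", {
  bench <- small_bench()
  scores <- suppressWarnings(similarity_search(
    bench$actives, bench$library, measures = c("radial", "molprint2d")))
  a <- run_method_a(scores = scores)
  b <- run_method_b(scores = scores)
  c_ <- run_method_c(scores = scores)
  expect_equal(n_rankings(a), 6 * 2)      # |actives| x |measures|
  expect_equal(n_rankings(b), 2 * 6)      # 2 rules x |actives|
  expect_equal(n_rankings(c_), 2 * 2)     # 2 rules x |measures|
  # every ranking covers the whole library with ranks 1..N
  one <- a[a$query == a$query[1] & a$measure == a$measure[1], ]
  expect_equal(sort(one$rank), seq_len(nrow(bench$library)))
  # each ranking's top compound carries that ranking's maximal score
  top <- dplyr::filter(dplyr::group_by(a, query, measure), rank == 1)
  mx <- dplyr::summarise(dplyr::group_by(a, query, measure),
                         m = max(score), .groups = "drop")
  expect_equal(top$score, mx$m)
})

test_that("degenerate fusion inputs warn and reduce to the raw ranking", {
  bench <- small_bench()
  scores <- suppressWarnings(similarity_search(bench$actives, bench$library,
                                               measures = "radial"))
  expect_warning(b <- run_method_b(scores = scores), "degenerate")
  a <- run_method_a(scores = scores)
  q <- bench$actives$id[1]
  expect_equal(
    b[b$query == q & b$rule == "max", c("library_id", "rank")],
    a[a$query == q, c("library_id", "rank")])
  one <- bench$actives[1, ]
  expect_warning(
    run_method_c(scores = suppressWarnings(
      similarity_search(one, bench$library, measures = "radial"))),
    "degenerate")
})

test_that("group-fusion MAX gives in-library query actives a score of 1", {
  bench <- small_bench()
  rk <- suppressWarnings(run_method_c(bench$actives, bench$library,
                                      measures = c("radial", "maccs")))
  act_scores <- rk$score[rk$rule == "max" &
                           rk$library_id %in% bench$actives$id]
  expect_true(all(act_scores == 1))
})

test_that("rankings are stable under library permutation (tie policy)", {
  bench <- small_bench()
  lib <- bench$library
  set.seed(3)
  perm <- sample.int(nrow(lib))
  fps <- suppressWarnings(fingerprint_table(lib, "radial"))
  r1 <- run_method_c(scores = suppressWarnings(similarity_search(
    bench$actives, lib, "radial", library_fps = fps)))
  r2 <- run_method_c(scores = suppressWarnings(similarity_search(
    bench$actives, lib[perm, ], "radial", library_fps = fps[perm, ])))
  o1 <- r1[order(r1$rule, r1$measure, r1$rank), c("library_id", "score", "rank")]
  o2 <- r2[order(r2$rule, r2$measure, r2$rank), c("library_id", "score", "rank")]
  expect_equal(as.data.frame(o1), as.data.frame(o2))
})

test_that("rankings serialise to the documented CSV layout", {
  bench <- small_bench()
  rk <- suppressWarnings(run_method_c(bench$actives, bench$library,
                                      measures = "radial"))
  tf <- tempfile(fileext = ".csv")
  write_rankings(rk, tf)
  back <- read.csv(tf)
  expect_named(back, c("library_id", "score", "rank", "rule", "method",
                       "query", "measure"))
  expect_equal(nrow(back), nrow(rk))
})
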