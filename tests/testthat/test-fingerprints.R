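test_that("MACCS keys reproduce an independent reference implementation", {
  # expected key sets computed with the RDKit MACCS implementation and
  # frozen here; both engines evaluate the same public key definitions
  expected <- list(
    benzene = c(162, 163, 165),
    ethanol = c(82, 109, 114, 139, 153, 155, 157, 160, 164),
    pyridine = c(65, 98, 121, 137, 161, 162, 163, 165),
    naphthalene = c(101, 105, 125, 145, 162, 163, 165),
    aspirin = c(89, 113, 123, 126, 127, 136, 139, 140, 143, 144, 146,
                150, 152, 154, 157, 159, 160, 162, 163, 164, 165)
  )
  mols <- panel_mols()
  keys <- fp_maccs(mols[mols$id %in% names(expected), ])
  for (nm in names(expected))
    expect_equal(as.numeric(keys[[nm]]), expected[[nm]], label = nm)
  # aromatic-ring key on benzene, ring-count key on naphthalene
  expect_true(162 %in% keys$benzene)
  expect_true(125 %in% keys$naphthalene)
  expect_false(125 %in% keys$benzene)
})

test_that("MACCS is invariant across SMILES spellings and serialises", {
  a <- suppressWarnings(parse_molecules(
    c("OCC", "C(O)C"), c("s1", "s2")))
  keys <- fp_maccs(a)
  expect_equal(as.numeric(keys$s1), as.numeric(keys$s2))
  s <- maccs_string(keys$s1)
  expect_equal(nchar(s), 166)
  expect_equal(which(strsplit(s, "")[[1]] == "1"), as.integer(keys$s1))
})

test_that("radial fingerprint matches hand-enumerated environments", {
  # single heavy atom: only the radius-0 environment exists
  expect_length(fp_radial(panel_graph("methane"), iterations = 2), 1)
  # ethane: both carbons equivalent, one bit per informative radius
  expect_length(fp_radial(panel_graph("ethane"), iterations = 2), 2)
  # benzene: all atoms equivalent at every radius
  expect_length(fp_radial(panel_graph("benzene"), iterations = 2), 3)
  # deeper iteration never removes bits
  g <- panel_graph("aspirin")
  expect_true(all(fp_radial(g, 1) %in% fp_radial(g, 2)))
})

test_that("dendritic fragments match the combinatorial path oracle", {
  expect_length(fp_dendritic(panel_graph("ethane")), 2)  # atom + 1 bond
  expect_length(fp_dendritic(panel_graph("hexane")),
                oracle_dendritic_alkane(6))
  expect_length(fp_dendritic(panel_graph("heptane")),
                oracle_dendritic_alkane(7))
  # fragment vocabulary saturates once every composition of at most five
  # bonds exists: octane and nonane give identical bit sets
  oct <- suppressWarnings(parse_molecules(c("CCCCCCCC", "CCCCCCCCC"),
                                          c("octane", "nonane")))
  expect_identical(as.numeric(fp_dendritic(oct$graph[[1]])),
                   as.numeric(fp_dendritic(oct$graph[[2]])))
  expect_equal(oracle_dendritic_alkane(8), oracle_dendritic_alkane(9))
  # a branched molecule contributes single-branch tree fragments that a
  # path-only enumeration cannot produce
  iso <- suppressWarnings(parse_molecules("CC(C)(C)C", "neopentane"))
  expect_gt(length(fp_dendritic(iso$graph[[1]])), 2 + 2)
})

test_that("MOLPRINT2D encodes typed two-bond environments", {
  expect_length(fp_molprint2d(panel_graph("methane")), 1)
  # ethanol: three distinct atom environments
  expect_length(fp_molprint2d(panel_graph("ethanol")), 3)
  # benzene: one environment shared by all six atoms
  expect_length(fp_molprint2d(panel_graph("benzene")), 1)
})

test_that("all sparse fingerprints are invariant under atom renumbering", {
  mols <- panel_mols()
  set.seed(101)
  for (id in c("ethanol", "aspirin", "naphthalene", "acetate")) {
    g <- panel_graph(id)
    for (k in seq_len(34)) {
      pg <- permute_molecule_graph(g)
      expect_identical(as.numeric(fp_radial(pg)),
                       as.numeric(fp_radial(g)), label = id)
      expect_identical(as.numeric(fp_dendritic(pg)),
                       as.numeric(fp_dendritic(g)), label = id)
      expect_identical(as.numeric(fp_molprint2d(pg)),
                       as.numeric(fp_molprint2d(g)), label = id)
    }
  }
})

test_that("hashed bits stay inside the 32-bit space and hash is pinned", {
  g <- panel_graph("aspirin")
  for (fp in list(fp_radial(g), fp_dendritic(g), fp_molprint2d(g))) {
    expect_true(all(fp >= 0 & fp < 2^32))
    expect_true(all(fp == floor(fp)))
  }
  # FNV-1a reference values (offset basis for "", published test vector)
  expect_equal(fnv1a32(""), 2166136261)
  expect_equal(fnv1a32("a"), 3826002220)
})

test_that("Tanimoto similarity follows the set formula and conventions", {
  a <- structure(c(1, 2, 3), kind = "radial")
  b <- structure(c(2, 3, 9), kind = "radial")
  expect_equal(tanimoto(a, b), 2 / 4)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(a, structure(c(7, 8), kind = "radial")), 0)
  expect_equal(tanimoto(structure(numeric(0), kind = "radial"),
                        structure(numeric(0), kind = "radial")), 0)
  expect_error(tanimoto(a, structure(1:3, kind = "maccs")),
               "kind mismatch")
  # symmetry and range over random sets
  set.seed(7)
  for (k in 1:25) {
    x <- structure(sample(100, 12), kind = "radial")
    y <- structure(sample(100, 20), kind = "radial")
    expect_equal(tanimoto(x, y), tanimoto(y, x))
    expect_gte(tanimoto(x, y), 0)
    expect_lte(tanimoto(x, y), 1)
  }
})

test_that("fingerprint tables serialise to text and back", {
  mols <- panel_mols()[1:4, ]
  fps <- suppressWarnings(fingerprint_table(mols))
  tf <- tempfile(fileext = ".tsv")
  write_fingerprints(fps, tf)
  back <- read_fingerprints(tf)
  expect_equal(back$id, fps$id)
  expect_equal(back$kind, fps$kind)
  for (k in seq_len(nrow(fps)))
    expect_equal(as.numeric(back$bits[[k]]), as.numeric(fps$bits[[k]]))
})

test_that("similar molecules score higher than unrelated scaffolds", {
  mols <- small_bench()
  afp <- purrr::map(mols$actives$graph, fp_radial)
  dfp <- purrr::map(mols$decoys$graph, fp_radial)
  within <- tanimoto_matrix(afp, afp)
  across <- tanimoto_matrix(afp, dfp)
  expect_gt(min(within), max(across))
})
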