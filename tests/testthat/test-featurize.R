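test_that("fingerprints have the contracted shapes and binary entries", {
  smi <- unname(fixture_smiles())
  e4 <- ecfp(smi, 4)
  e6 <- ecfp(smi, 6)
  mk <- maccs(smi)
  expect_equal(dim(e4), c(length(smi), 1024L))
  expect_equal(dim(e6), c(length(smi), 1024L))
  expect_equal(dim(mk), c(length(smi), 167L))
  expect_true(all(e4 %in% 0:1) && all(e6 %in% 0:1) && all(mk %in% 0:1))
  expect_equal(ncol(featurize(smi[1:2], "ecfp4")), 1028L)
  expect_equal(ncol(featurize(smi[1:2], "maccs")), 171L)
})

test_that("features are invariant to SMILES spelling and deterministic", {
  pairs <- list(c("CCO", "C(C)O"), c("Cc1ccccc1", "c1ccccc1C"))
  for (p in pairs) {
    expect_identical(ecfp(p[1], 4), ecfp(p[2], 4))
    expect_identical(maccs(p[1]), maccs(p[2]))
    expect_equal(physchem(p[1]), physchem(p[2]))
  }
  expect_identical(featurize("CCO", "ecfp6"), featurize("CCO", "ecfp6"))
})

test_that("fast fingerprint decoding matches the reference bit-by-bit", {
  # independent route: ChemmineOB's per-bit decoder on the same OpenBabel
  # fingerprint, including a molecule whose bit pattern hits the high word bit
  for (s in c("CC(=O)OCCc1ccccc1", "CCO", "O=Cc1ccco1",
              "CC(=O)O[C@@H]1C[C@@H](C)CC[C@H]1C(C)C")) {
    slow <- as.integer(ChemmineOB::fingerprint_OB(
      ChemmineOB::forEachMol("SMILES", s, identity), "ECFP4"))
    fast <- odortools:::ob_fingerprints(s, "ECFP4")[1, ]
    expect_identical(fast, slow)
  }
})

test_that("ECFP6 environments extend ECFP4 on the unfolded bit sets", {
  # radius-3 neighborhoods include all radius-2 neighborhoods, so before
  # folding the ECFP6 bit set must contain the ECFP4 bit set
  for (s in c("CCO", "CCCC", "CC=O", "CCOC", "c1ccccc1")) {
    b4 <- odortools:::ob_fingerprints(s, "ECFP4")[1, ]
    b6 <- odortools:::ob_fingerprints(s, "ECFP6")[1, ]
    expect_true(all(b6[b4 == 1] == 1))
  }
})

test_that("physchem descriptors match independent oracles", {
  pc <- physchem(c("CCO", "O", "c1ccccc1"))
  # atomic-mass summation: C2H6O = 2*12.011 + 6*1.008 + 15.999
  expect_equal(unname(pc[1, "MW"]), 2 * 12.011 + 6 * 1.008 + 15.999,
               tolerance = 1e-3)
  expect_lt(pc[2, "logP"], pc[1, "logP"])   # water below ethanol
  expect_equal(unname(pc[3, "TPSA"]), 0)    # benzene: no polar atoms
  expect_true(all(is.finite(pc)))
})

test_that("molecular graphs mirror the parsed molecule", {
  g <- to_graph("CCO")
  expect_equal(nrow(g$atoms), 3L)
  expect_equal(nrow(g$bonds), 2L)
  b <- to_graph("c1ccccc1")
  expect_equal(nrow(b$atoms), 6L)
  expect_equal(nrow(b$bonds), 6L)   # ring closure
  expect_true(all(b$atoms$aromatic))
  m <- to_graph("C")
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(nrow(m$bonds), 0L)
  expect_equal(m$atoms$element, "C")
  # degree sums to twice the edge count
  expect_equal(sum(g$atoms$degree), 2L * nrow(g$bonds))
})

test_that("disconnected duplicates only saturate presence bits", {
  one <- ecfp("CCO", 4)
  two <- ecfp("CCO.CCO", 4)
  expect_true(all(two[one == 1] == 1))
})
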