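test_that("canonicalization maps SMILES spellings to one idempotent form", {
  expect_identical(canonicalize_smiles("C(C)O"), canonicalize_smiles("CCO"))
  can <- canonicalize_smiles("CC(=O)OCCc1ccccc1")
  expect_identical(canonicalize_smiles(can), can)
  # vectorized batch agrees with scalar calls
  batch <- canonicalize_smiles(c("c1ccccc1", "OCC", "CC(C)CCOC(C)=O"))
  expect_identical(batch, vapply(c("c1ccccc1", "OCC", "CC(C)CCOC(C)=O"),
                                 canonicalize_smiles, "", USE.NAMES = FALSE))
})

test_that("unparseable SMILES are rejected with the offending string", {
  expect_error(canonicalize_smiles("xyz!!"), "xyz!!")
  res <- suppressWarnings(canonicalize_smiles(c("CCO", "xyz!!"), strict = FALSE))
  expect_identical(res[1], "CCO")
  expect_true(is.na(res[2]))
})

test_that("name resolution is case-insensitive and misses are NA", {
  lk <- default_name_lookup()
  expect_identical(resolve_names("menthyl acetate", lk),
                   resolve_names("MENTHYL ACETATE", lk))
  expect_false(is.na(resolve_names("menthyl acetate", lk)))
  expect_true(is.na(resolve_names("unknownium", lk)))
  # every packaged SMILES parses
  expect_false(anyNA(canonicalize_smiles(unname(lk), strict = FALSE)))
})

test_that("registry resolves, canonicalizes, excludes and dedupes", {
  reg <- build_registry(fixture_compound_table())
  # unknownium is excluded, the two ethanol spellings merge: 7 rows -> 5
  expect_equal(nrow(reg$records), 5L)
  expect_equal(nrow(reg$excluded), 1L)
  expect_match(reg$excluded$reason[1], "lookup")
  eth <- reg$records[reg$records$smiles == "CCO", ]
  expect_equal(sort(eth$threshold_obs[[1]]), c(990, 1010))
  expect_setequal(eth$descriptors[[1]], c("alcoholic", "sweet"))
  # lexicographically first name kept, other stored as alias
  expect_equal(eth$name, "dup-ethanol-a")
  expect_equal(eth$aliases[[1]], "dup-ethanol-b")
  # deterministic order
  expect_identical(reg$records$smiles, sort(reg$records$smiles))
})

test_that("registry is idempotent and never grows", {
  reg <- build_registry(fixture_compound_table())
  again <- dedupe_records(reg$records)
  expect_identical(again$smiles, reg$records$smiles)
  expect_identical(again$threshold_obs, reg$records$threshold_obs)
  expect_lte(nrow(reg$records), nrow(fixture_compound_table()))
  expect_false(anyDuplicated(reg$records$smiles) > 0)
})

test_that("dedupe pools thresholds and counts distinct molecules", {
  recs <- data.frame(smiles = c("CCO", "CCO", "CCCCCC=O", "Cc1ccccc1", "CCO"),
                     name = c("a", "b", "c", "d", "e"),
                     concentration_mg_L = NA_real_, stringsAsFactors = FALSE)
  recs$descriptors <- list("x", "y", "z", "w", "x")
  recs$threshold_obs <- list(0.1, 0.3, 1, 2, numeric(0))
  out <- dedupe_records(recs)
  expect_equal(nrow(out), 3L)
  expect_equal(sort(out$threshold_obs[[which(out$smiles == "CCO")]]),
               c(0.1, 0.3))
})
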