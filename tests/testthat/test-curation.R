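test_that("descriptor consolidation collapses synonyms and normalizes case", {
  expect_identical(consolidate_descriptors(c("fruit", "fruity")), "fruity")
  expect_identical(consolidate_descriptors(c("Rose ", "rose")), "rose")
  expect_identical(consolidate_descriptors(character(0)), character(0))
  # empty descriptor set stays unlabeled, never becomes Odorless
  expect_true(is.na(assign_category(character(0))))
})

test_that("category assignment follows the fixed priority scheme", {
  expect_equal(assign_category(c("apple", "grassy")), "Fruity")
  expect_equal(assign_category("buttery"), "Sweet/Vanilla/Caramel")
  expect_equal(assign_category("sweaty"), "Off-flavor")
  expect_equal(assign_category("solvent"), "Off-flavor")
  expect_equal(assign_category("odorless"), "Odorless")
  # order of the descriptor set never matters
  sets <- list(c("apple", "grassy", "rose"), c("rose", "apple", "grassy"),
               c("grassy", "rose", "apple"))
  cats <- vapply(sets, assign_category, "")
  expect_length(unique(cats), 1L)
  # all-unmapped set is unlabeled
  expect_true(is.na(assign_category(c("zorp", "flibber"))))
})

test_that("contribution labels are a pure function of the final category", {
  expect_equal(assign_contribution("Citrus"), "positive")
  expect_equal(assign_contribution("Fruity"), "positive")
  expect_equal(assign_contribution("Odorless"), "negative")
  expect_equal(assign_contribution("Off-flavor"), "negative")
  expect_error(assign_contribution("NoSuchCategory"), "polarity")
})

test_that("threshold collapse filters non-positive values and transforms", {
  ct <- collapse_threshold(c(0.001, 0.01, 0.1))
  expect_equal(ct$t_mg_L, 0.01)
  expect_equal(ct$y, 2.0)
  expect_equal(collapse_threshold(1.0)$y, 0.0)
  expect_equal(collapse_threshold(c(-0.5, 0.02))$t_mg_L, 0.02)
  expect_null(collapse_threshold(c(-1, 0)))
  expect_equal(collapse_threshold(c(1, 2, 30), policy = "mean")$t_mg_L, 11)
  # duplicating the median value leaves the median unchanged
  expect_equal(collapse_threshold(c(0.1, 0.2, 0.3, 0.2))$t_mg_L,
               collapse_threshold(c(0.1, 0.2, 0.3))$t_mg_L)
})

test_that("curation of a registry is invariant to row permutation", {
  reg <- build_registry(fixture_compound_table())
  cur1 <- curate_corpus(reg$records)
  perm <- reg$records[rev(seq_len(nrow(reg$records))), ]
  cur2 <- curate_corpus(perm)
  cur2 <- cur2[match(cur1$smiles, cur2$smiles), ]
  expect_equal(cur1$contribution, cur2$contribution)
  expect_equal(cur1$y_neglog10_mg_L, cur2$y_neglog10_mg_L)
})

test_that("the packaged curation config is complete and validates", {
  cfg <- curation_config()
  expect_s3_class(cfg, "curation_config")
  final <- unique(c(setdiff(unlist(cfg$category_map), names(cfg$merge_map)),
                    unlist(cfg$merge_map)))
  expect_true(all(final %in% cfg$priority))
  expect_true(all(vapply(cfg$priority, function(k)
    !is.null(cfg$polarity[[k]]), TRUE)))
})
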