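test_that("molecule generation is deterministic, valid and scaffold-grouped", {
  spec <- synth_spec(n_molecules = 120, seed = 5)
  smi <- gen_molecules(spec)
  expect_length(smi, 120L)
  expect_false(anyDuplicated(smi) > 0)
  # all parse and are already canonical
  expect_identical(canonicalize_smiles(as.character(smi)), as.character(smi))
  expect_identical(as.character(gen_molecules(synth_spec(120, seed = 5))),
                   as.character(smi))
  # murcko keys come from the ring-template library plus "" for acyclics
  keys <- unique(murcko_scaffold(as.character(smi)))
  ring_keys <- murcko_scaffold(canonicalize_smiles(
    vapply(odortools:::synth_ring_templates(),
           function(t) gsub("\\(\\{B\\}\\)", "", t), "")))
  expect_true(all(keys %in% c("", ring_keys)))
  expect_gt(length(keys), 3L)
  # oversampling the enumerable space fails loudly
  expect_error(gen_molecules(synth_spec(n_molecules = 10000, seed = 1)),
               "enumerable space")
})

test_that("label generation hits the target prevalence", {
  spec <- synth_spec(n_molecules = 400, prevalence = 0.93, seed = 7)
  smi <- gen_molecules(spec)
  lab <- gen_labels(smi, spec)
  expect_equal(mean(lab == "positive"), 0.93, tolerance = 0.02)
  # zero flip noise: labels are a pure function of structure
  expect_identical(gen_labels(smi, spec), lab)
  # full flip noise destroys the structure signal
  spec_noise <- synth_spec(n_molecules = 400, prevalence = 0.93,
                           flip_noise = 0.5, seed = 7)
  lab_noise <- gen_labels(smi, spec_noise)
  expect_gt(mean(lab != lab_noise), 0.3)
})

test_that("threshold generation follows the linear physchem rule", {
  spec0 <- synth_spec(n_molecules = 100, seed = 9, noise_sd = 0)
  smi <- gen_molecules(spec0)
  y0 <- gen_thresholds(smi, spec0)
  pc <- physchem(as.character(smi))
  expect_equal(y0, drop(cbind(1, pc) %*% spec0$beta), tolerance = 1e-12)
  # noise adds variance around the same mean structure
  spec1 <- synth_spec(n_molecules = 100, seed = 9, noise_sd = 0.4)
  y1 <- gen_thresholds(smi, spec1)
  expect_equal(sd(y1 - y0), 0.4, tolerance = 0.15)
})

test_that("threshold distribution is near-normal over mixed scaffolds", {
  spec <- synth_spec(n_molecules = 600, seed = 17)
  y <- gen_thresholds(gen_molecules(spec), spec)
  skew <- mean((y - mean(y))^3) / sd(y)^3
  expect_lt(abs(skew), 0.5)
})

test_that("simulated panels recover the step-function limit", {
  # infinite slope: every panelist flips exactly at the true threshold
  s <- gen_panel(0.5, slope = Inf, seed = 3,
                 concentrations = c(0, 0.01, 0.1, 1, 10))
  expect_equal(group_threshold(s), 1)   # smallest tested conc >= 0.5
  # all-identical sensitivities give a degenerate bootstrap CI
  b <- bootstrap_threshold_ci(s, B = 500, seed = 1)
  expect_equal(b$ci_low, b$ci_high)
  # profiles are monotone by construction
  s2 <- gen_panel(1, slope = 2, seed = 11)
  expect_true(all(apply(s2$detection, 1, function(r) !is.unsorted(r))))
})

test_that("generated corpora flow through registry and curation unchanged", {
  corpus <- gen_corpus(synth_spec(n_molecules = 50, seed = 19))
  reg <- build_registry(corpus)
  expect_equal(nrow(reg$records), 50L)
  expect_equal(nrow(reg$excluded), 0L)
  cur <- curate_corpus(reg$records)
  expect_false(anyNA(cur$contribution))
  expect_false(anyNA(cur$y_neglog10_mg_L))
})
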