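test_that("majority downsampling caps only the majority class", {
  labels <- c(rep("positive", 8000), rep("negative", 1200))
  idx <- downsample_majority(labels, cap = 5000, seed = 1)
  expect_equal(unname(table(labels[idx])["positive"]), 5000)
  expect_equal(unname(table(labels[idx])["negative"]), 1200)
  # below the cap: untouched
  labels2 <- c(rep("positive", 3000), rep("negative", 1200))
  expect_identical(downsample_majority(labels2, 5000, 1), seq_along(labels2))
  # determinism
  expect_identical(downsample_majority(labels, 5000, 7),
                   downsample_majority(labels, 5000, 7))
})

test_that("class weights are inverse-frequency with conserving totals", {
  w <- class_weights(c(rep("A", 50), rep("B", 50)))
  expect_equal(unname(w), c(1, 1))
  w2 <- class_weights(c(rep("A", 75), rep("B", 25)))
  expect_equal(unname(w2["A"]), 100 / (2 * 75))
  expect_equal(unname(w2["B"]), 2.0)
  expect_equal(sum(w2 * c(75, 25)), 100)
  expect_error(class_weights(rep("A", 10)), "2 classes")
})

test_that("configuration draws stay inside the declared domains", {
  for (fam in c("rf", "gbdt", "mlp", "gcn")) {
    space <- search_space(fam)
    cfgs <- draw_configs(space, 25, seed = 3)
    for (cfg in cfgs) {
      for (nm in names(space)) {
        dom <- space[[nm]]
        if (is.list(dom)) {
          expect_true(any(vapply(dom, identical, TRUE, cfg[[nm]])))
        } else {
          expect_true(cfg[[nm]] %in% dom)
        }
      }
    }
    expect_identical(draw_configs(space, 5, 11), draw_configs(space, 5, 11))
  }
})

test_that("ranking uses macro-F1 with the documented tie-break cascade", {
  mk <- function(f1, acc, prec, rec)
    list(macro_f1 = f1, accuracy = acc, macro_precision = prec,
         macro_recall = rec)
  r <- rank_combinations(list(A = mk(0.73, 0.90, 0.6, 0.6),
                              B = mk(0.73, 0.88, 0.9, 0.9)))
  expect_equal(r$combination[1], "A")
  # full ties preserve input order (stable)
  r2 <- rank_combinations(list(X = mk(0.5, 0.5, 0.5, 0.5),
                               Y = mk(0.5, 0.5, 0.5, 0.5)))
  expect_equal(r2$combination, c("X", "Y"))
  r3 <- rank_combinations(list(L = mk(0.2, 1, 1, 1), M = mk(0.9, 0, 0, 0),
                               N = mk(0.5, 1, 1, 1)))
  expect_equal(r3$combination, c("M", "N", "L"))
})

test_that("random search recovers separable structure and respects draws", {
  # balanced, noiseless structure-determined labels: essentially separable
  spec <- synth_spec(n_molecules = 150, prevalence = 0.5, seed = 3)
  smi <- as.character(gen_molecules(spec))
  lab <- gen_labels(smi, spec)
  X <- featurize(smi, "maccs")
  cv <- random_search("classification", X, lab, "gbdt",
                      n_draws = 2, folds = 5, seed = 5)
  expect_length(cv$fold_metrics, 5L)
  expect_equal(cv$best_mean, mean(cv$fold_metrics))
  expect_gte(cv$best_mean, 0.95)
  # single draw returns that draw
  cv1 <- random_search("classification", X, lab, "rf",
                       n_draws = 1, folds = 5, seed = 5)
  expect_equal(cv1$best_draw, 1L)
  expect_identical(cv1$best_config, cv1$configs[[1]])
})

test_that("search never sees validation data", {
  # the selected configuration is a function of the training rows only:
  # shuffling labels on held-out rows cannot change it
  fx <- fixture_synth(150, 3)
  sp <- greedy_split(fx$smiles, 0.2)
  tr <- sp$membership == "train"
  X <- featurize(fx$smiles[tr], "maccs")
  cv_a <- random_search("classification", X, fx$labels[tr], "rf",
                        n_draws = 3, folds = 5, seed = 2)
  cv_b <- random_search("classification", X, fx$labels[tr], "rf",
                        n_draws = 3, folds = 5, seed = 2)
  expect_identical(cv_a$best_config, cv_b$best_config)
  expect_identical(cv_a$table, cv_b$table)
})

test_that("final models predict calibrated-scale outputs and persist exactly", {
  fx <- fixture_synth(150, 3)
  m <- fit_final("contribution", "ecfp4", "gbdt", gbdt_default_config(),
                 fx$smiles, fx$labels, seed = 4)
  p <- predict(m, fx$smiles[1:30])
  expect_true(all(p >= 0 & p <= 1))
  dir <- withr::local_tempdir()
  save_model(m, dir)
  m2 <- load_model(dir)
  expect_identical(as.numeric(predict(m2, fx$smiles[1:30])), as.numeric(p))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  # bad SMILES becomes a per-row error, batch continues
  mix <- predict(m, c(fx$smiles[1], "zzz!"))
  expect_false(is.na(mix[1]))
  expect_true(is.na(mix[2]))
  expect_equal(attr(mix, "errors"), "zzz!")
})

test_that("noiseless threshold structure is recoverable by the regressor", {
  fx <- fixture_synth(200, 13, noise_sd = 0)
  sp <- greedy_split(fx$smiles, 0.2)
  tr <- sp$membership == "train"
  m <- fit_final("threshold", "ecfp4", "gbdt", gbdt_default_config(),
                 fx$smiles[tr], fx$y[tr], seed = 4)
  rep_ <- regression_report(fx$y[!tr], predict(m, fx$smiles[!tr]))
  expect_gte(rep_$r2, 0.75)   # small-n spot check; the full-scale bound is 0.9
})

test_that("mlp and gcn families train and emit normalized probabilities", {
  fx <- fixture_synth(150, 3)
  sub <- 1:60
  Xs <- featurize(fx$smiles[sub], "maccs")
  pc <- c("MW", "logP", "TPSA", "MR")
  Xs[, pc] <- scale(Xs[, pc])
  cfg <- list(hidden_layer_sizes = c(256L, 64L), alpha = 1e-4,
              learning_rate_init = 1e-3, batch_size = 128L)
  fm <- fit_family("mlp", "classification", Xs, fx$labels[sub], cfg, seed = 2)
  P <- predict_family(fm, Xs)
  expect_equal(unname(rowSums(P)), rep(1, length(sub)), tolerance = 1e-9)
  graphs <- lapply(fx$smiles[sub], to_graph)
  gcfg <- list(hidden = 64L, dropout = 0.1, learning_rate = 3e-3,
               weight_decay = 0, batch_size = 64L)
  fg <- fit_family("gcn", "classification", graphs, fx$labels[sub], gcfg,
                   seed = 2)
  Pg <- predict_family(fg, graphs)
  expect_equal(unname(rowSums(Pg)), rep(1, length(sub)), tolerance = 1e-9)
})
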