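# End-to-end orchestration: curate -> scaffold split -> randomized search per
# fingerprint-model combination -> final refit -> validation evaluation ->
# ranked model table -> persisted best artifact. Every output directory
# carries a manifest (config hash, seeds, package version); deterministic
# stages rerun to identical outputs under the same config and seed.

#' Assemble and validate a pipeline run configuration
#'
#' @param task `"contribution"`, `"category"` or `"threshold"`.
#' @param schemes Fingerprint schemes to try (`"ecfp4"`, `"ecfp6"`,
#'   `"maccs"`, `"graph"`).
#' @param families Model families to try (`"rf"`, `"gbdt"`, `"mlp"`,
#'   `"gcn"`); `"graph"` pairs only with `"gcn"` and vice versa.
#' @param split_fraction Validation fraction for the scaffold split.
#' @param n_draws Randomized-search draws per scheme-family pair.
#' @param folds CV folds.
#' @param downsample_cap Majority-class cap for classification training sets.
#' @param curation Path to a curation YAML, or `NULL` for the default.
#' @param threshold_policy `"median"` or `"mean"` duplicate-threshold
#'   collapse.
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(task = "contribution",
                       schemes = c("ecfp4", "maccs"),
                       families = c("rf", "gbdt"),
                       split_fraction = 0.2, n_draws = 30L, folds = 5L,
                       downsample_cap = 5000L, curation = NULL,
                       threshold_policy = "median", seed = 1L,
                       out_dir = tempfile("odortools_run_")) {
  task <- match.arg(task, c("contribution", "category", "threshold"))
  schemes <- match.arg(schemes, c("ecfp4", "ecfp6", "maccs", "graph"),
                       several.ok = TRUE)
  families <- match.arg(families, c("rf", "gbdt", "mlp", "gcn"),
                        several.ok = TRUE)
  stopifnot(split_fraction > 0, split_fraction < 1, n_draws >= 1, folds >= 2)
  threshold_policy <- match.arg(threshold_policy, c("median", "mean"))
  if (!is.null(curation) && !file.exists(curation))
    stop("curation config not found: ", curation)
  out <- list(task = task, schemes = schemes, families = families,
              split_fraction = split_fraction, n_draws = as.integer(n_draws),
              folds = as.integer(folds),
              downsample_cap = downsample_cap, curation = curation,
              threshold_policy = threshold_policy, seed = as.integer(seed),
              out_dir = out_dir)
  class(out) <- "run_config"
  out
}

config_hash <- function(config) {
  flat <- jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                           auto_unbox = TRUE)
  tmp <- tempfile(); on.exit(unlink(tmp))
  writeLines(as.character(flat), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(dir, config, stage, extra = list()) {
  jsonlite::write_json(
    c(list(stage = stage, config_hash = config_hash(config),
           seed = config$seed,
           version = as.character(utils::packageVersion("odortools")),
           config = unclass(config)), extra),
    file.path(dir, paste0(stage, "_manifest.json")),
    auto_unbox = TRUE, digits = NA, na = "null")
}

# scheme-family pairs actually run: graph<->gcn are exclusive partners
combo_grid <- function(schemes, families) {
  g <- expand.grid(scheme = schemes, family = families,
                   stringsAsFactors = FALSE)
  g[(g$scheme == "graph") == (g$family == "gcn"), , drop = FALSE]
}

#' Run the full modeling pipeline
#'
#' Ingests a compound table (data.frame or CSV path), curates it, performs
#' the scaffold-aware greedy split, then for every scheme-family combination
#' runs the randomized hyperparameter search with k-fold CV on the training
#' set, refits on the full training set, and evaluates on the held-out
#' validation set. Combinations are ranked (macro-F1 with
#' accuracy/macro-precision/macro-recall tie-breaks for classification;
#' validation R-squared with RMSE tie-break for regression) and the winning
#' artifact is persisted. All stage outputs (curated corpus, split, CV
#' tables, validation reports, ranked table) are written under
#' `config$out_dir` with manifests.
#'
#' @param compounds data.frame (see [read_compound_table()]) or CSV path.
#' @param config A [run_config()].
#' @return Invisible list: `ranked` (data.frame), `best_model`
#'   (`aroma_model`), `reports` (per-combination validation `eval_report`s),
#'   `split`, `corpus`, `out_dir`.
#' @export
run_pipeline <- function(compounds, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(compounds)) compounds <- read_compound_table(compounds)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  cur_cfg <- if (is.null(config$curation)) curation_config()
             else curation_config(config$curation)
  reg <- build_registry(compounds)
  corpus <- curate_corpus(reg$records, cur_cfg, config$threshold_policy)
  if (config$task == "threshold") {
    corpus <- corpus[!is.na(corpus$y_neglog10_mg_L), , drop = FALSE]
    y_all <- corpus$y_neglog10_mg_L
  } else if (config$task == "contribution") {
    corpus <- corpus[!is.na(corpus$contribution), , drop = FALSE]
    y_all <- factor(corpus$contribution, levels = c("negative", "positive"))
  } else {
    corpus <- corpus[!is.na(corpus$category), , drop = FALSE]
    y_all <- factor(corpus$category)
  }
  if (nrow(corpus) < 10L)
    stop("pipeline aborted at curation: only ", nrow(corpus),
         " usable records for task ", config$task)
  utils::write.csv(corpus, file.path(config$out_dir, "curated_corpus.csv"),
                   row.names = FALSE)
  write_manifest(config$out_dir, config, "curate",
                 list(n_records = nrow(corpus),
                      n_excluded = nrow(reg$excluded)))

  split <- greedy_split(corpus$smiles, config$split_fraction)
  utils::write.csv(split, file.path(config$out_dir, "split.csv"),
                   row.names = FALSE)
  tr <- split$membership == "train"
  smi_tr <- corpus$smiles[tr];  y_tr <- y_all[tr]
  smi_va <- corpus$smiles[!tr]; y_va <- y_all[!tr]

  cls <- config$task != "threshold"
  keep <- seq_along(smi_tr)
  if (cls && is.finite(config$downsample_cap))
    keep <- downsample_majority(y_tr, config$downsample_cap, config$seed)
  smi_fit <- smi_tr[keep]; y_fit <- y_tr[keep]

  grid <- combo_grid(config$schemes, config$families)
  if (nrow(grid) == 0L) stop("no runnable scheme-family combinations")
  mltask <- if (cls) "classification" else "regression"
  feats <- new.env(parent = emptyenv())
  get_features <- function(smiles, scheme) {
    key <- paste(scheme, length(smiles), substr(paste(smiles, collapse = ""), 1, 40))
    if (!is.null(feats[[key]])) return(feats[[key]])
    val <- if (scheme == "graph") lapply(smiles, to_graph)
           else featurize(smiles, scheme)
    feats[[key]] <- val
    val
  }

  reports <- list(); cv_tables <- list(); models <- list()
  for (i in seq_len(nrow(grid))) {
    scheme <- grid$scheme[i]; family <- grid$family[i]
    combo <- paste(scheme, family, sep = "-")
    Xtr <- get_features(smi_fit, scheme)
    cv <- random_search(mltask, Xtr, y_fit, family,
                        n_draws = config$n_draws, folds = config$folds,
                        seed = config$seed)
    cv_tables[[combo]] <- cv$table
    model <- fit_final(config$task, scheme, family, cv$best_config,
                       smi_fit, y_fit, downsample_cap = Inf,
                       seed = config$seed)
    pred <- predict(model, smi_va)
    reports[[combo]] <- if (cls) {
      if (config$task == "category") classification_report(y_va, pred)
      else classification_report(y_va, pred)
    } else regression_report(y_va, pred)
    models[[combo]] <- model
  }

  if (cls) {
    ranked <- rank_combinations(reports)
    ranked <- cbind(combination = ranked$combination,
                    ranked[setdiff(names(ranked), "combination")])
  } else {
    ranked <- do.call(rbind, lapply(names(reports), function(nm)
      data.frame(combination = nm, r2 = reports[[nm]]$r2,
                 rmse = reports[[nm]]$rmse, stringsAsFactors = FALSE)))
    ranked$input_rank <- seq_len(nrow(ranked))
    ranked <- ranked[order(-ranked$r2, ranked$rmse, ranked$input_rank), ,
                     drop = FALSE]
    rownames(ranked) <- NULL
  }
  utils::write.csv(ranked, file.path(config$out_dir, "ranked_models.csv"),
                   row.names = FALSE)
  for (nm in names(cv_tables))
    utils::write.csv(cv_tables[[nm]],
                     file.path(config$out_dir, paste0("cv_", nm, ".csv")),
                     row.names = FALSE)
  for (nm in names(reports))
    write_eval_report(reports[[nm]],
                      file.path(config$out_dir, paste0("eval_", nm, ".json")))

  best_name <- ranked$combination[1]
  best_model <- models[[best_name]]
  save_model(best_model, file.path(config$out_dir, "best_model"))
  write_manifest(config$out_dir, config, "train",
                 list(best = best_name, ranked = ranked))
  invisible(list(ranked = ranked, best_model = best_model, reports = reports,
                 split = split, corpus = corpus, out_dir = config$out_dir))
}

#' Batch prediction over a compound table
#'
#' Loads persisted artifacts, resolves names to SMILES where needed, and
#' produces a candidate report row per input. Unresolved or unparseable rows
#' are reported in the returned attribute `skipped`, never fatal.
#'
#' @param contribution_dir,threshold_dir Artifact directories from
#'   [save_model()].
#' @param compounds data.frame or CSV path with `name` and/or `smiles`
#'   (optionally `concentration_mg_L`).
#' @param lookup Name lookup table for rows without SMILES.
#' @param conformal_q Optional conformal half-width for threshold intervals.
#' @param out Optional CSV path for the ranked report.
#' @return A `candidate_ranking` data.frame (see [rank_candidates()]).
#' @export
predict_batch <- function(contribution_dir, threshold_dir, compounds,
                          lookup = default_name_lookup(), conformal_q = NULL,
                          out = NULL) {
  if (is.character(compounds)) compounds <- read_compound_table(compounds)
  cm <- load_model(contribution_dir)
  tm <- load_model(threshold_dir)
  if (cm$version != tm$version)
    warning("artifact versions differ: ", cm$version, " vs ", tm$version)
  smi <- if (!is.null(compounds$smiles)) as.character(compounds$smiles)
         else rep("", nrow(compounds))
  smi[is.na(smi)] <- ""
  need <- !nzchar(trimws(smi))
  if (any(need) && !is.null(compounds$name))
    smi[need] <- resolve_names(as.character(compounds$name)[need], lookup)
  ok <- !is.na(smi) & nzchar(smi)
  df <- compounds[ok, , drop = FALSE]
  df$smiles <- smi[ok]
  ranked <- rank_candidates(df, cm, tm, conformal_q = conformal_q)
  skipped <- c(attr(ranked, "skipped"),
               if (any(!ok)) paste0("row ", which(!ok), ": unresolved"))
  attr(ranked, "skipped") <- skipped
  if (!is.null(out)) {
    utils::write.csv(ranked, out, row.names = FALSE)
    jsonlite::write_json(
      list(contribution_model = cm$version, threshold_model = tm$version,
           conformal_q = conformal_q, n = nrow(ranked),
           skipped = skipped),
      paste0(out, ".manifest.json"), auto_unbox = TRUE, na = "null")
  }
  ranked
}
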