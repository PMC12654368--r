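# Odor activity values and candidate ranking: converts model outputs plus
# measured concentrations into OAV = concentration / threshold and a ranked
# list of candidate aroma contributors, flagging compounds absent from the
# training corpus as novel.

#' Back-transform a predicted threshold with its conformal interval
#'
#' The regression target is `y = -log10(t [mg/L])`, so `t = 10^(-y)`. A
#' conformal half-width `q` on the log scale gives the multiplicative
#' interval `[10^-(y+q), 10^-(y-q)]` mg/L, asymmetric on the linear scale.
#'
#' @param y Predicted `-log10(mg/L)` value(s).
#' @param q Conformal half-width (log10 units), `>= 0`; optional.
#' @return data.frame with `t_mg_L` and, when `q` is given, `t_lo`, `t_hi`.
#' @export
delog_threshold <- function(y, q = NULL) {
  stopifnot(all(is.finite(y)))
  out <- data.frame(t_mg_L = 10^(-y))
  if (!is.null(q)) {
    stopifnot(q >= 0)
    out$t_lo <- 10^(-(y + q))
    out$t_hi <- 10^(-(y - q))
  }
  out
}

#' Odor activity value
#'
#' `OAV = concentration / threshold`, dimensionless (both in mg/L).
#' `OAV > 1` indicates the compound exceeds its detection threshold and is
#' likely perceptually relevant.
#'
#' @param concentration Concentration in mg/L, `> 0`.
#' @param threshold Odor threshold in mg/L, `> 0`.
#' @return Numeric ratio.
#' @export
oav <- function(concentration, threshold) {
  if (any(!is.finite(concentration) | concentration <= 0))
    stop("concentration must be > 0")
  if (any(!is.finite(threshold) | threshold <= 0))
    stop("threshold must be > 0")
  concentration / threshold
}

#' Rank candidate aroma compounds
#'
#' Applies the contribution and threshold models to a compound table,
#' computes OAVs where measured concentrations are available, flags
#' compounds whose canonical SMILES is absent from the training corpus as
#' novel, and returns a deterministic ranking: novel compounds first, then
#' by OAV descending when concentrations exist, otherwise by predicted
#' threshold ascending (most potent first). Positive and negative predicted
#' contributors are reported in separate sections of the `section` column
#' (probability cutoff 0.5). Rows whose SMILES fails to parse are dropped
#' with a log entry in `attr(, "skipped")`.
#'
#' @param df data.frame with `smiles` (and optionally `name`,
#'   `concentration_mg_L`).
#' @param contribution_model `aroma_model` for the contribution task.
#' @param threshold_model `aroma_model` for the threshold task.
#' @param corpus_smiles Canonical SMILES of the training corpus (novelty
#'   reference); defaults to the union of both models' training sets.
#' @param conformal_q Optional conformal half-width for threshold intervals.
#' @return data.frame of class `candidate_ranking`, best candidates first.
#' @export
rank_candidates <- function(df, contribution_model, threshold_model,
                            corpus_smiles = NULL, conformal_q = NULL) {
  stopifnot(inherits(contribution_model, "aroma_model"),
            inherits(threshold_model, "aroma_model"))
  if (is.null(corpus_smiles))
    corpus_smiles <- union(contribution_model$train_smiles,
                           threshold_model$train_smiles)
  can <- canonicalize_smiles(as.character(df$smiles), strict = FALSE)
  skipped <- df$smiles[is.na(can)]
  keep <- which(!is.na(can))
  can <- can[keep]
  p_pos <- predict(contribution_model, can)
  y_hat <- predict(threshold_model, can)
  thr <- delog_threshold(y_hat, conformal_q)
  conc <- if (!is.null(df$concentration_mg_L))
    as.numeric(df$concentration_mg_L)[keep] else rep(NA_real_, length(keep))
  oav_val <- ifelse(!is.na(conc) & conc > 0, conc / thr$t_mg_L, NA_real_)
  out <- data.frame(
    smiles = can,
    name = if (!is.null(df$name)) as.character(df$name)[keep] else "",
    contribution_probability = as.numeric(p_pos),
    contribution = ifelse(p_pos >= 0.5, "positive", "negative"),
    y_pred = as.numeric(y_hat),
    threshold_mg_L = thr$t_mg_L,
    concentration_mg_L = conc,
    oav = oav_val,
    novel = !(can %in% corpus_smiles),
    stringsAsFactors = FALSE)
  if (!is.null(conformal_q)) {
    out$threshold_lo_mg_L <- thr$t_lo
    out$threshold_hi_mg_L <- thr$t_hi
  }
  ord <- order(-out$novel,
               -ifelse(is.na(out$oav), -Inf, out$oav),
               out$threshold_mg_L,
               out$smiles)
  out <- out[ord, , drop = FALSE]
  out$section <- out$contribution
  rownames(out) <- NULL
  if (length(skipped)) attr(out, "skipped") <- as.character(skipped)
  class(out) <- c("candidate_ranking", "data.frame")
  out
}
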