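# Metric suite for the contribution classifier and threshold regressor:
# macro/weighted F1, accuracy, ROC-AUC, average precision, Brier score,
# calibration curve, normalized confusion matrix; R^2, RMSE, tertile-
# stratified RMSE; residual-based conformal prediction bands.

# "higher" (conservative) empirical quantile: smallest order statistic whose
# ECDF reaches p. Used for conformal q and tertile boundaries.
quantile_higher <- function(x, p) {
  s <- sort(x)
  s[pmin(length(s), pmax(1L, ceiling(length(s) * p)))]
}

per_class_prf <- function(cm) {
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(precision = prec, recall = rec, f1 = f1, support = rowSums(cm))
}

#' Classification metric report
#'
#' Computes the full classification metric bundle. For binary problems,
#' `p` is the predicted probability of the positive class and the report
#' additionally carries ROC-AUC, average precision (step integration of the
#' precision-recall curve), Brier score and a 10-bin equal-width calibration
#' curve. For multi-class problems `p` is a probability matrix (columns =
#' classes) and the probability-based metrics are `NA`. Macro metrics are
#' unweighted class means; weighted-F1 is support-weighted. If `y_true`
#' contains a single class, AUC and AP are undefined and reported as `NA`.
#'
#' @param y_true True labels (factor, character, or 0/1).
#' @param p Probability vector (binary, positive class) or matrix (one column
#'   per class, named).
#' @param cutoff Decision cutoff for the binary positive call (default 0.5).
#' @param positive Positive class label; defaults to `"positive"` when
#'   present, otherwise the second factor level (or `1`).
#' @return A list of class `eval_report`.
#' @export
classification_report <- function(y_true, p, cutoff = 0.5, positive = NULL) {
  if (is.matrix(p) && ncol(p) > 2L) return(multiclass_report(y_true, p))
  if (is.matrix(p)) {
    if (is.null(positive)) positive <- colnames(p)[ncol(p)]
    p <- p[, positive]
  }
  y <- as.character(y_true)
  labs <- sort(unique(y))
  if (is.null(positive)) {
    positive <- if ("positive" %in% labs) "positive"
                else if (all(labs %in% c("0", "1"))) "1"
                else labs[length(labs)]
  }
  negative <- setdiff(labs, positive)
  negative <- if (length(negative)) negative[1] else paste0("not_", positive)
  pred <- ifelse(p >= cutoff, positive, negative)
  lev <- c(negative, positive)
  cm <- table(factor(y, levels = lev), factor(pred, levels = lev))
  cm <- unclass(cm)
  prf <- per_class_prf(cm)
  n <- length(y)
  single <- length(labs) < 2L
  ypos <- as.integer(y == positive)

  auc <- ap <- NA_real_
  if (!single) {
    npos <- sum(ypos); nneg <- n - npos
    r <- rank(p, ties.method = "average")
    auc <- (sum(r[ypos == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
    ord <- order(p, decreasing = TRUE)
    yp <- ypos[ord]; ps <- p[ord]
    tp <- cumsum(yp); fp <- cumsum(1 - yp)
    keep <- c(ps[-1] != ps[-n], TRUE)       # last index of each score level
    prec <- (tp / (tp + fp))[keep]
    recl <- (tp / npos)[keep]
    ap <- sum(diff(c(0, recl)) * prec)
  }
  brier <- mean((p - ypos)^2)
  bins <- cut(p, breaks = seq(0, 1, by = 0.1), include.lowest = TRUE)
  cal <- do.call(rbind, lapply(levels(bins), function(b) {
    idx <- which(bins == b)
    if (!length(idx)) return(NULL)
    data.frame(bin = b, mean_predicted = mean(p[idx]),
               observed_positive = mean(ypos[idx]), n = length(idx))
  }))
  out <- list(
    task = "classification",
    classes = lev, positive = positive, cutoff = cutoff,
    confusion = cm,
    confusion_normalized = sweep(cm, 1, pmax(rowSums(cm), 1), "/"),
    per_class = prf,
    accuracy = sum(diag(cm)) / n,
    macro_f1 = mean(prf$f1),
    weighted_f1 = sum(prf$f1 * prf$support) / n,
    macro_precision = mean(prf$precision),
    macro_recall = mean(prf$recall),
    auc = auc, average_precision = ap, brier = brier,
    calibration = cal)
  class(out) <- "eval_report"
  out
}

multiclass_report <- function(y_true, p) {
  y <- as.character(y_true)
  lev <- colnames(p)
  stopifnot(!is.null(lev))
  pred <- lev[max.col(p, ties.method = "first")]
  cm <- unclass(table(factor(y, levels = lev), factor(pred, levels = lev)))
  prf <- per_class_prf(cm)
  n <- length(y)
  out <- list(
    task = "classification", classes = lev, positive = NA_character_,
    cutoff = NA_real_, confusion = cm,
    confusion_normalized = sweep(cm, 1, pmax(rowSums(cm), 1), "/"),
    per_class = prf,
    accuracy = sum(diag(cm)) / n,
    macro_f1 = mean(prf$f1),
    weighted_f1 = sum(prf$f1 * prf$support) / n,
    macro_precision = mean(prf$precision),
    macro_recall = mean(prf$recall),
    auc = NA_real_, average_precision = NA_real_, brier = NA_real_,
    calibration = NULL)
  class(out) <- "eval_report"
  out
}

#' Regression metric report
#'
#' `R^2 = 1 - SS_res/SS_tot` and `RMSE = sqrt(mean((y - yhat)^2))`, plus the
#' tertile-stratified RMSE from [tertile_rmse()]. A constant `y_true` makes
#' R^2 undefined; it is reported as `NA` with `r2_defined = FALSE`.
#'
#' @param y_true,y_hat Finite numeric vectors of equal length.
#' @return A list of class `eval_report`.
#' @export
regression_report <- function(y_true, y_hat) {
  stopifnot(length(y_true) == length(y_hat),
            all(is.finite(y_true)), all(is.finite(y_hat)))
  ss_res <- sum((y_true - y_hat)^2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  out <- list(
    task = "regression",
    r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    r2_defined = ss_tot > 0,
    rmse = sqrt(mean((y_true - y_hat)^2)),
    tertile_rmse = tertile_rmse(y_true, y_hat))
  class(out) <- "eval_report"
  out
}

#' Tertile-stratified RMSE
#'
#' Partitions observations by the true value into Low (`y <= q1`),
#' Mid (`q1 < y <= q2`) and High (`y > q2`), where q1 and q2 are the 1/3 and
#' 2/3 quantiles of `y_true` (conservative "higher" interpolation; the upper
#' boundary is inclusive). RMSE is computed within each stratum; an empty
#' stratum (possible with heavy ties at the quantiles) is `NA`.
#'
#' @param y_true,y_hat Numeric vectors, `length >= 3`.
#' @return Named numeric vector `c(low =, mid =, high =)`.
#' @export
tertile_rmse <- function(y_true, y_hat) {
  stopifnot(length(y_true) >= 3L, length(y_true) == length(y_hat))
  q1 <- quantile_higher(y_true, 1 / 3)
  q2 <- quantile_higher(y_true, 2 / 3)
  stratum <- ifelse(y_true <= q1, "low", ifelse(y_true <= q2, "mid", "high"))
  one <- function(s) {
    idx <- stratum == s
    if (!any(idx)) return(NA_real_)
    sqrt(mean((y_true[idx] - y_hat[idx])^2))
  }
  c(low = one("low"), mid = one("mid"), high = one("high"))
}

#' Residual-based conformal prediction band
#'
#' The band half-width `q` is the empirical `level` quantile (conservative
#' "higher" interpolation) of the absolute calibration residuals, in
#' `-log10(mg/L)` units. By construction the coverage of the calibration
#' residuals themselves is at least `level - 1/n`. Proper usage computes `q`
#' on a calibration split disjoint from the evaluation split; computing
#' coverage on the residuals that set `q` (in-sample emulation) is supported
#' but should be flagged by the caller.
#'
#' @param residuals Numeric vector of calibration residuals (`y - yhat`).
#' @param level Nominal coverage, default 0.95.
#' @return A list of class `conformal_band` with `q`, `level`, `n`.
#' @export
conformal_band <- function(residuals, level = 0.95) {
  stopifnot(all(is.finite(residuals)), level > 0, level < 1)
  n <- length(residuals)
  if (n < 20L)
    warning("conformal_band: only ", n,
            " residuals; the quantile estimate is unstable")
  out <- list(q = quantile_higher(abs(residuals), level), level = level, n = n)
  class(out) <- "conformal_band"
  out
}

#' Empirical coverage of a conformal band
#'
#' Fraction of points with `|y - yhat| <= q`. Non-decreasing in `q`.
#'
#' @param y_true,y_hat Numeric vectors.
#' @param q Band half-width (from [conformal_band()], or a bare number).
#' @return Scalar coverage in `[0, 1]`.
#' @export
conformal_coverage <- function(y_true, y_hat, q) {
  if (inherits(q, "conformal_band")) q <- q$q
  mean(abs(y_true - y_hat) <= q)
}

#' @export
print.eval_report <- function(x, ...) {
  if (x$task == "classification") {
    cat(sprintf(
      "classification: macro-F1 %.3f | weighted-F1 %.3f | acc %.3f | AUC %s | AP %s | Brier %s\n",
      x$macro_f1, x$weighted_f1, x$accuracy,
      ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc)),
      ifelse(is.na(x$average_precision), "NA", sprintf("%.3f", x$average_precision)),
      ifelse(is.na(x$brier), "NA", sprintf("%.3f", x$brier))))
  } else {
    cat(sprintf("regression: R2 %s | RMSE %.3f | tertile RMSE %s\n",
                ifelse(is.na(x$r2), "NA", sprintf("%.3f", x$r2)), x$rmse,
                paste(sprintf("%.2f", x$tertile_rmse), collapse = "/")))
  }
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes the report as JSON; for classification the normalized confusion
#' matrix and calibration curve are additionally emitted as CSV files next to
#' it for plotting.
#'
#' @param report An `eval_report`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_eval_report <- function(report, path) {
  ser <- report
  class(ser) <- NULL
  if (!is.null(ser$confusion)) {
    ser$confusion <- as.data.frame.matrix(ser$confusion)
    ser$confusion_normalized <- as.data.frame.matrix(ser$confusion_normalized)
  }
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, na = "null")
  if (report$task == "classification") {
    utils::write.csv(as.data.frame.matrix(report$confusion_normalized),
                     sub("\\.json$", "_confusion.csv", path))
    if (!is.null(report$calibration))
      utils::write.csv(report$calibration,
                       sub("\\.json$", "_calibration.csv", path),
                       row.names = FALSE)
  }
  invisible(path)
}
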