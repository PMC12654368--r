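# Group odor detection thresholds from ascending-series panel data (modified
# ASTM E679 design: single-bottle yes/no detection, group threshold at the
# lowest concentration where at least half the panel detects), with panelist
# bootstrap confidence intervals, descriptor tallies and intensity summaries.

#' Construct a sensory panel session
#'
#' A session holds an ascending concentration series (including the blank at
#' 0), a panelist-by-concentration binary detection matrix, and optional
#' per-concentration descriptor tallies and 0-5 intensity ratings. When only
#' marginal detection counts are available (as in published tables), pass
#' `counts` and the per-panelist matrix is reconstructed under the monotone
#' assumption (see [reconstruct_monotone()]); the estimate metadata records
#' that reconstruction was used.
#'
#' @param concentrations Strictly increasing concentrations in mg/L; the
#'   first entry is usually the blank (0).
#' @param detection Binary matrix, panelists x concentrations.
#' @param counts Alternative to `detection`: detection counts per
#'   concentration (requires `n_panelists`).
#' @param n_panelists Panel size when reconstructing from `counts`.
#' @param descriptors Optional list (one per concentration) of named counts,
#'   e.g. `list(...,"1" = c(floral = 10, sweet = 3))`.
#' @param intensity Optional list (one per concentration) of 0-5 ratings.
#' @return A list of class `panel_session`.
#' @export
panel_session <- function(concentrations, detection = NULL, counts = NULL,
                          n_panelists = NULL, descriptors = NULL,
                          intensity = NULL) {
  stopifnot(!is.unsorted(concentrations, strictly = TRUE))
  reconstructed <- FALSE
  if (is.null(detection)) {
    if (is.null(counts) || is.null(n_panelists))
      stop("supply either a detection matrix or counts + n_panelists")
    detection <- reconstruct_monotone(counts, n_panelists)
    reconstructed <- TRUE
  }
  detection <- as.matrix(detection)
  if (ncol(detection) != length(concentrations))
    stop("detection matrix must have one column per concentration")
  if (!all(detection %in% c(0, 1))) stop("detection entries must be 0/1")
  out <- list(concentrations = as.numeric(concentrations),
              detection = detection,
              descriptors = descriptors, intensity = intensity,
              n_panelists = nrow(detection),
              reconstructed = reconstructed)
  class(out) <- "panel_session"
  out
}

#' @export
print.panel_session <- function(x, ...) {
  cat("panel_session:", x$n_panelists, "panelists x",
      length(x$concentrations), "concentrations",
      if (x$reconstructed) "(monotone-reconstructed)" else "", "\n")
  cat("  detection counts:", paste(colSums(x$detection), collapse = ", "), "\n")
  invisible(x)
}

#' Reconstruct monotone per-panelist detection profiles from marginal counts
#'
#' Published threshold tables usually report only the number of detecting
#' panelists per concentration. Under the ascending-series assumption that a
#' panelist who detects at some concentration also detects at every higher
#' one, the per-panelist matrix is uniquely determined up to panelist order:
#' sorting panelists by sensitivity, panelist `i` detects at concentration
#' `j` iff `i <= counts[j]`. Column sums reproduce the input counts exactly.
#' Decreasing counts contradict the monotone assumption and are rejected
#' (supply the raw matrix instead).
#'
#' @param counts Non-decreasing integer detection counts per concentration.
#' @param n Panel size.
#' @return Binary matrix `n` x `length(counts)`.
#' @export
reconstruct_monotone <- function(counts, n) {
  counts <- as.integer(counts)
  if (any(counts < 0) || any(counts > n))
    stop("counts must lie in [0, n]")
  if (is.unsorted(counts))
    stop("counts decrease across ascending concentrations; monotone ",
         "reconstruction is invalid - supply the raw detection matrix")
  outer(seq_len(n), counts, function(i, k) as.integer(i <= k))
}

detection_rule_k <- function(n, rule_fraction) as.integer(ceiling(rule_fraction * n))

# first concentration index (excluding the blank at 0) meeting the rule;
# returns m + 1 when censored (never met)
threshold_index <- function(counts, concentrations, k) {
  eligible <- which(concentrations > 0 & counts >= k)
  if (length(eligible)) eligible[1] else length(concentrations) + 1L
}

#' Group odor detection threshold
#'
#' The lowest tested nonzero concentration at which at least
#' `rule_fraction` of the panel reported detection (with 20 assessors and the
#' default 50% rule: at least 10 "yes" answers). If the rule is never met the
#' threshold is right-censored and `Inf` is returned with attribute
#' `censored = "> max tested"`.
#'
#' @param session A [panel_session()].
#' @param rule_fraction Detection fraction defining the group threshold
#'   (default 0.5).
#' @return Concentration in mg/L (scalar), or `Inf` when censored.
#' @export
group_threshold <- function(session, rule_fraction = 0.5) {
  stopifnot(inherits(session, "panel_session"))
  if (nrow(session$detection) == 0L) stop("empty detection matrix")
  k <- detection_rule_k(session$n_panelists, rule_fraction)
  idx <- threshold_index(colSums(session$detection), session$concentrations, k)
  if (idx > length(session$concentrations)) {
    out <- Inf
    attr(out, "censored") <- paste0("> ", max(session$concentrations), " mg/L")
    out
  } else {
    session$concentrations[idx]
  }
}

#' Bootstrap confidence interval for the group threshold
#'
#' Resamples the panelists with replacement `B` times, recomputes the group
#' threshold per replicate under the same detection rule, and reads the CI
#' off the ordered replicate thresholds: each bound is the smallest replicate
#' value whose empirical CDF reaches the requested tail probability
#' (lower-value assignment at probability ties, over the discrete
#' concentration grid). Censored replicates sort above the highest tested
#' concentration; a bound landing on the censored category is reported as
#' `Inf` (printed "> max"). The point estimate is the bootstrap median.
#'
#' @param session A [panel_session()].
#' @param B Number of bootstrap replicates (default 10000).
#' @param seed RNG seed.
#' @param level CI level (default 0.95).
#' @param rule_fraction Detection rule, see [group_threshold()].
#' @return A list of class `group_threshold_estimate`: `point` (plug-in
#'   group threshold on the full panel), `bootstrap_median`, `ci_low`,
#'   `ci_high`, `level`, `B`, `seed`, `rule_fraction`, `reconstructed`.
#' @export
bootstrap_threshold_ci <- function(session, B = 10000L, seed = 1,
                                   level = 0.95, rule_fraction = 0.5) {
  stopifnot(inherits(session, "panel_session"))
  set.seed(seed)
  D <- session$detection
  n <- nrow(D); m <- ncol(D)
  k <- detection_rule_k(n, rule_fraction)
  conc <- session$concentrations
  # count matrix per replicate via one multiplication: S[b, i] = times panelist
  # i was drawn in replicate b, so (S %*% D)[b, j] = detection count
  draws <- matrix(sample.int(n, n * B, replace = TRUE), B, n)
  S <- matrix(0L, B, n)
  for (i in seq_len(n)) S[, i] <- rowSums(draws == i)
  counts <- S %*% D
  idx <- rep(m + 1L, B)
  for (j in rev(which(conc > 0))) idx[counts[, j] >= k] <- j
  grid <- c(conc, Inf)
  thr <- grid[idx]
  s <- sort(thr)
  qlo <- s[max(1L, ceiling(B * (1 - level) / 2))]
  qhi <- s[max(1L, ceiling(B * (1 + level) / 2))]
  med <- s[max(1L, ceiling(B * 0.5))]
  out <- list(point = group_threshold(session, rule_fraction),
              bootstrap_median = med, ci_low = qlo, ci_high = qhi,
              level = level, B = B, seed = seed,
              rule_fraction = rule_fraction,
              reconstructed = session$reconstructed,
              replicate_table = table(thr))
  class(out) <- "group_threshold_estimate"
  out
}

#' @export
print.group_threshold_estimate <- function(x, ...) {
  fmt <- function(v) if (is.infinite(v)) "> max tested" else paste(v, "mg/L")
  cat(sprintf("group threshold: %s (bootstrap median %s; %g%% CI %s - %s; B = %d)\n",
              fmt(x$point), fmt(x$bootstrap_median), 100 * x$level,
              fmt(x$ci_low), fmt(x$ci_high), x$B))
  if (x$reconstructed)
    cat("  note: per-panelist profiles were monotone-reconstructed from marginal counts\n")
  invisible(x)
}

#' Descriptor tally per concentration
#'
#' @param session A [panel_session()] carrying descriptor data.
#' @return Named list (one element per concentration) of term counts, sorted
#'   by decreasing count then term.
#' @export
descriptor_tally <- function(session) {
  stopifnot(inherits(session, "panel_session"))
  if (is.null(session$descriptors)) stop("session carries no descriptors")
  out <- lapply(session$descriptors, function(d) {
    if (is.null(d) || length(d) == 0L) return(c(None = 0))
    v <- if (is.null(names(d))) table(d) else d
    v <- stats::setNames(as.integer(v), names(v))
    v[order(-v, names(v))]
  })
  names(out) <- as.character(session$concentrations)
  out
}

#' Intensity summary per concentration
#'
#' Mean and standard deviation (n-1 denominator) of the 0-5 intensity
#' ratings at each concentration. A single rating has undefined SD; it is
#' reported as 0 by convention and flagged in the `sd_defined` column.
#'
#' @param session A [panel_session()] carrying intensity data.
#' @return data.frame: `concentration_mg_L`, `mean`, `sd`, `n`, `sd_defined`.
#' @export
intensity_summary <- function(session) {
  stopifnot(inherits(session, "panel_session"))
  if (is.null(session$intensity)) stop("session carries no intensity ratings")
  rows <- lapply(seq_along(session$concentrations), function(j) {
    r <- session$intensity[[j]]
    data.frame(concentration_mg_L = session$concentrations[j],
               mean = if (length(r)) mean(r) else NA_real_,
               sd = if (length(r) > 1L) stats::sd(r) else 0,
               n = length(r),
               sd_defined = length(r) > 1L)
  })
  do.call(rbind, rows)
}

#' Read a sensory session from CSV
#'
#' Accepts the long dialect (`panelist_id, concentration_mg_L, detected,
#' descriptors, intensity`) or the marginal-count dialect
#' (`concentration_mg_L, detected_count, n_panelists`).
#'
#' @param path CSV path.
#' @return A [panel_session()].
#' @export
read_panel_session <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("panelist_id", "concentration_mg_L", "detected") %in% names(df))) {
    conc <- sort(unique(df$concentration_mg_L))
    panelists <- sort(unique(df$panelist_id))
    D <- matrix(0L, length(panelists), length(conc))
    D[cbind(match(df$panelist_id, panelists),
            match(df$concentration_mg_L, conc))] <- as.integer(df$detected)
    intensity <- NULL
    if ("intensity" %in% names(df))
      intensity <- lapply(conc, function(cc)
        df$intensity[df$concentration_mg_L == cc & !is.na(df$intensity)])
    descriptors <- NULL
    if ("descriptors" %in% names(df))
      descriptors <- lapply(conc, function(cc) {
        terms <- unlist(lapply(df$descriptors[df$concentration_mg_L == cc],
                               split_semis))
        if (length(terms)) table(terms) else NULL
      })
    panel_session(conc, detection = D, descriptors = descriptors,
                  intensity = intensity)
  } else if (all(c("concentration_mg_L", "detected_count", "n_panelists")
                 %in% names(df))) {
    panel_session(df$concentration_mg_L, counts = df$detected_count,
                  n_panelists = df$n_panelists[1])
  } else stop("unrecognized sensory CSV dialect")
}

#' Built-in worked sensory sessions
#'
#' The packaged ascending-series panel data for 2-phenylethyl acetate
#' (acetic acid, 2-phenylethyl ester) and menthyl acetate: 20 assessors,
#' 10-fold dilution series in water, marginal detection counts with
#' per-concentration descriptor tallies and intensity means. Per-panelist
#' profiles are monotone-reconstructed.
#'
#' @return Named list of two [panel_session()] objects
#'   (`phenylethyl_acetate`, `menthyl_acetate`).
#' @export
worked_sessions <- function() {
  path <- system.file("extdata", "sensory_sessions.csv", package = "odortools")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$compound), function(d) {
    d <- d[order(d$concentration_mg_L), ]
    desc <- lapply(d$descriptors, function(s) {
      if (!nzchar(s)) return(NULL)
      parts <- strsplit(split_semis(s), ":", fixed = TRUE)
      stats::setNames(as.integer(vapply(parts, `[`, "", 2)),
                      trimws(vapply(parts, `[`, "", 1)))
    })
    panel_session(d$concentration_mg_L, counts = d$detected_count,
                  n_panelists = d$n_panelists[1], descriptors = desc)
  })
  out[c("phenylethyl_acetate", "menthyl_acetate")]
}
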