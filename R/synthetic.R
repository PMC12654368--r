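# Seeded synthetic-data generators with known ground truth: template-built
# molecule sets with controllable scaffold structure, contribution labels
# driven by a structure score, thresholds linear in the physicochemical
# block, and ascending-series panel sessions from a cumulative-normal
# psychometric rule. Every generator is a pure function of (spec, seed).

#' Synthetic data specification
#'
#' Collects the knobs of the generators. Defaults emulate the shape of real
#' volatile corpora: a handful of ring scaffolds shared by many compounds, a
#' large acyclic (ester/aldehyde/alcohol) contingent, a heavily imbalanced
#' contribution labeling (93% positive), and thresholds whose `-log10(mg/L)`
#' values are approximately normal over a few orders of magnitude.
#'
#' @param n_molecules Number of molecules to generate.
#' @param prevalence Target positive-class fraction for labels.
#' @param flip_noise Label flip probability (0 = perfectly
#'   structure-determined labels).
#' @param beta Threshold-rule coefficients on `(1, MW, logP, TPSA, MR)`.
#' @param noise_sd Threshold noise SD on the `-log10` scale.
#' @param seed Integer seed; every generator derives its randomness from it.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_molecules = 800L, prevalence = 0.93,
                       flip_noise = 0, beta = c(-2.2, 0.015, 0.45, -0.02, 0.03),
                       noise_sd = 0.4, seed = 1L) {
  stopifnot(prevalence > 0, prevalence < 1, flip_noise >= 0, flip_noise <= 0.5,
            length(beta) == 5L, noise_sd >= 0)
  out <- list(n_molecules = as.integer(n_molecules), prevalence = prevalence,
              flip_noise = flip_noise, beta = beta, noise_sd = noise_sd,
              seed = as.integer(seed))
  class(out) <- "synth_spec"
  out
}

# ring templates carry a {B} branch slot and accept a prefix substituent;
# acyclic templates combine prefix and suffix fragments around a core
synth_ring_templates <- function() c(
  benzene     = "c1ccc({B})cc1",
  furan       = "c1cc({B})oc1",
  thiophene   = "c1cc({B})sc1",
  pyridine    = "c1cc({B})cnc1",
  cyclohexane = "C1CCC({B})CC1",
  cyclopentane = "C1CCC({B})C1",
  lactone     = "C1({B})CCC(=O)O1")

synth_acyclic_cores <- function() c(
  ester    = "CC(=O)OC{B}",
  aldehyde = "CCC(=O){B}",
  alcohol  = "CCO{B}")

synth_substituents <- function() c(
  "", "C", "CC", "CCC", "CCCC", "CCCCC", "CC(C)", "CC(C)C",
  "OC", "OCC", "CO", "COC", "CCO", "C=C", "CC=C", "C(C)C")

fill_template <- function(template, a, b) {
  body <- ifelse(nzchar(b),
                 vapply(b, function(x) sub("{B}", x, template, fixed = TRUE), ""),
                 gsub("\\(\\{B\\}\\)|\\{B\\}", "", template))
  paste0(a, body)
}

#' Generate a synthetic molecule set
#'
#' Enumerates scaffold-template x substituent combinations (ring scaffolds
#' with prefix and branch substitution plus acyclic ester/aldehyde/alcohol
#' cores), canonicalizes, removes duplicates, and draws `n_molecules` with
#' the spec seed. Template substitution guarantees chemical validity and
#' gives every ring template a multi-member Murcko scaffold group, so
#' scaffold-split behavior is exercised by construction.
#'
#' @param spec A [synth_spec()].
#' @return Character vector of canonical SMILES with attribute `template`
#'   naming the generating scaffold template per molecule.
#' @export
gen_molecules <- function(spec = synth_spec()) {
  subs <- synth_substituents()
  combos <- expand.grid(a = subs, b = subs, stringsAsFactors = FALSE)
  all_t <- c(synth_ring_templates(), synth_acyclic_cores())
  raw <- unlist(lapply(names(all_t), function(nm)
    stats::setNames(fill_template(all_t[[nm]], combos$a, combos$b),
                    rep(nm, nrow(combos)))))
  raw <- raw[nzchar(raw)]
  can <- canonicalize_smiles(unname(raw), strict = FALSE)
  ok <- !is.na(can)
  can <- can[ok]; tmpl <- names(raw)[ok]
  first <- !duplicated(can)
  can <- can[first]; tmpl <- tmpl[first]
  if (spec$n_molecules > length(can))
    stop("n_molecules (", spec$n_molecules, ") exceeds the enumerable space (",
         length(can), ")")
  set.seed(spec$seed)
  pick <- sort(sample.int(length(can), spec$n_molecules))
  structure(can[pick], template = tmpl[pick])
}

#' Generate contribution labels with known structure dependence
#'
#' A structure score linear in the physicochemical block
#' (`0.6 logP + 0.02 MW - 0.015 TPSA`) is thresholded at its
#' `1 - prevalence` quantile, so the realized positive fraction matches the
#' target up to ties, and the label is a deterministic function of structure.
#' Independent flips with probability `flip_noise` then degrade the signal
#' (0.5 destroys it entirely).
#'
#' @param smiles Canonical SMILES.
#' @param spec A [synth_spec()].
#' @return Factor with levels `negative`, `positive`.
#' @export
gen_labels <- function(smiles, spec = synth_spec()) {
  pc <- physchem(smiles)
  score <- 0.6 * pc[, "logP"] + 0.02 * pc[, "MW"] - 0.015 * pc[, "TPSA"]
  cut <- stats::quantile(score, 1 - spec$prevalence, type = 1)
  lab <- score >= cut
  if (spec$flip_noise > 0) {
    set.seed(spec$seed + 1L)
    flip <- stats::runif(length(lab)) < spec$flip_noise
    lab <- xor(lab, flip)
  }
  factor(ifelse(lab, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Generate threshold targets linear in the physicochemical block
#'
#' `y = beta . (1, MW, logP, TPSA, MR) + N(0, noise_sd)` on the
#' `-log10(mg/L)` scale. With `noise_sd = 0` the target is an exact function
#' of structure and serves as a parameter-recovery oracle for the
#' regression stack.
#'
#' @param smiles Canonical SMILES.
#' @param spec A [synth_spec()].
#' @return Numeric vector of `y = -log10(threshold mg/L)` values.
#' @export
gen_thresholds <- function(smiles, spec = synth_spec()) {
  pc <- physchem(smiles)
  mu <- drop(cbind(1, pc) %*% spec$beta)
  set.seed(spec$seed + 2L)
  mu + stats::rnorm(length(mu), sd = spec$noise_sd)
}

#' Generate a full synthetic compound table
#'
#' Assembles molecules, labels and thresholds into the CSV dialect consumed
#' by the registry (name, smiles, semicolon-separated descriptors and
#' thresholds), with descriptors drawn from terms that curate to categories
#' of the matching polarity. The generated table passes the registry and
#' curation modules unchanged.
#'
#' @param spec A [synth_spec()].
#' @return data.frame with columns `name`, `smiles`, `descriptors`,
#'   `threshold_mg_L`.
#' @export
gen_corpus <- function(spec = synth_spec()) {
  smi <- gen_molecules(spec)
  lab <- gen_labels(smi, spec)
  y <- gen_thresholds(smi, spec)
  pos_terms <- c("fruity", "apple", "floral", "sweet", "citrus", "rose")
  neg_terms <- c("sweaty", "solvent", "musty", "grassy", "sulfurous", "odorless")
  set.seed(spec$seed + 3L)
  desc <- vapply(seq_along(smi), function(i) {
    pool <- if (lab[i] == "positive") pos_terms else neg_terms
    paste(sample(pool, 2L), collapse = ";")
  }, "")
  data.frame(name = paste0("synthetic_", seq_along(smi)),
             smiles = as.character(smi),
             descriptors = desc,
             threshold_mg_L = sprintf("%.6g", 10^(-y)),
             stringsAsFactors = FALSE)
}

#' Simulate an ascending-series sensory panel
#'
#' Each panelist's log10 detection threshold is drawn from
#' `N(log10(true_threshold), 1/slope)`, so the probability of detecting
#' concentration `c` is the cumulative-normal psychometric function
#' `pnorm(slope * (log10(c) - log10(true_threshold)))` and per-panelist
#' detection profiles are monotone by construction. The group-threshold
#' estimator never sees this model: it applies only the 50%-detection rule.
#'
#' @param true_threshold True group-level threshold, mg/L.
#' @param slope Psychometric slope on the log10 scale (larger = steeper;
#'   `Inf` gives a deterministic step at the true threshold).
#' @param n_panelists Panel size (default 20).
#' @param concentrations Tested series, mg/L, ascending, including the blank
#'   0 (default a 10-fold series 0, 0.1 ... 1000).
#' @param seed RNG seed.
#' @return A [panel_session()].
#' @export
gen_panel <- function(true_threshold, slope = 2, n_panelists = 20L,
                      concentrations = c(0, 0.1, 1, 10, 100, 1000),
                      seed = 1L) {
  stopifnot(true_threshold > 0, slope > 0,
            !is.unsorted(concentrations, strictly = TRUE))
  set.seed(seed)
  z <- stats::rnorm(n_panelists)
  lt <- log10(true_threshold) - (if (is.finite(slope)) z / slope else 0)
  D <- outer(lt, concentrations, function(l, cc)
    as.integer(cc > 0 & log10(pmax(cc, .Machine$double.xmin)) >= l))
  intensity <- lapply(seq_along(concentrations), function(j) {
    cc <- concentrations[j]
    if (cc <= 0) return(rep(0, n_panelists))
    pmin(5, pmax(0, round(1.5 * (log10(cc) - lt) + 1))) * D[, j]
  })
  panel_session(concentrations, detection = D, intensity = intensity)
}
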