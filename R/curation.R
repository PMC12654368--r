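#' Load a descriptor-curation configuration
#'
#' The curation configuration is data, not code: a YAML file holding the
#' descriptor synonym map, the descriptor-to-category map, the sparse-category
#' merge map, the category priority order and the category polarity
#' (contribution) map. The packaged default implements the standard rules
#' (e.g. *fruit*, *fruity*, *apple*, *pear* map to Fruity; Dairy/Buttery is
#' merged into Sweet/Vanilla/Caramel; Rancid/Sweaty/Animalic and
#' Chemical/Solvent/Plastic into Off-flavor; Fruity outranks Green/Herbal;
#' Fruity and Citrus are positive contributors, Off-flavor and Odorless
#' negative) and can be replaced wholesale by the user.
#'
#' @param path YAML file; default is the packaged configuration.
#' @return A list of class `curation_config` with elements `synonym_map`,
#'   `category_map`, `merge_map`, `priority`, `polarity`.
#' @export
curation_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "curation_default.yaml", package = "odortools")
  cfg <- yaml::read_yaml(path)
  need <- c("synonym_map", "category_map", "priority", "polarity")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("curation config missing: ", paste(miss, collapse = ", "))
  if (is.null(cfg$merge_map)) cfg$merge_map <- list()
  final_cats <- unique(vapply(cfg$priority, identity, ""))
  merged_to <- unlist(cfg$merge_map, use.names = FALSE)
  if (!all(merged_to %in% final_cats))
    stop("merge_map targets missing from priority order")
  no_pol <- setdiff(final_cats, names(cfg$polarity))
  if (length(no_pol))
    stop("polarity map is not total over final categories: ",
         paste(no_pol, collapse = ", "))
  class(cfg) <- "curation_config"
  cfg
}

#' Consolidate raw odor descriptors
#'
#' Lowercases, trims and collapses synonymous descriptors onto their canonical
#' form. Descriptors with no synonym entry are kept verbatim (they may still
#' carry a category mapping); nothing is silently dropped here.
#'
#' @param raw Character vector of free-text descriptors.
#' @param config A [curation_config()].
#' @return Character vector: the consolidated descriptor set (unique, sorted).
#' @export
consolidate_descriptors <- function(raw, config = curation_config()) {
  if (length(raw) == 0L) return(character(0))
  x <- tolower(trimws(raw))
  x <- x[nzchar(x)]
  syn <- config$synonym_map
  hit <- x %in% names(syn)
  x[hit] <- unlist(syn[x[hit]], use.names = FALSE)
  sort(unique(x))
}

#' Assign the semantic odor category for a descriptor set
#'
#' Each consolidated descriptor is mapped to a category, sparse categories are
#' merged into their broad group, and when several categories remain the one
#' earliest in the priority order wins. Assignment depends only on the *set*
#' of descriptors, never their sequence. Unmappable descriptors are ignored
#' for the vote; if every descriptor is unmappable the record is unlabeled
#' (`NA`) and should be excluded from training.
#'
#' @param descriptors Consolidated descriptor set, see
#'   [consolidate_descriptors()].
#' @param config A [curation_config()].
#' @return A single category name, or `NA_character_` if unlabeled.
#' @export
assign_category <- function(descriptors, config = curation_config()) {
  if (length(descriptors) == 0L) return(NA_character_)
  cats <- unlist(config$category_map[descriptors], use.names = FALSE)
  if (is.null(cats) || length(cats) == 0L) return(NA_character_)
  merged <- vapply(cats, function(k)
    if (!is.null(config$merge_map[[k]])) config$merge_map[[k]] else k, "")
  ranks <- match(merged, config$priority)
  if (all(is.na(ranks))) return(NA_character_)
  config$priority[[min(ranks, na.rm = TRUE)]]
}

#' Map a final category to its aroma-contribution label
#'
#' Deterministic lookup in the polarity map. Contribution is a function of the
#' final (post-merge) category only.
#'
#' @param category Final category name.
#' @param config A [curation_config()].
#' @return `"positive"` or `"negative"`.
#' @export
assign_contribution <- function(category, config = curation_config()) {
  if (is.na(category)) return(NA_character_)
  pol <- config$polarity[[category]]
  if (is.null(pol))
    stop("category not in polarity map: ", category)
  pol
}

#' Collapse threshold observations to a single modeling target
#'
#' Non-positive and missing observations are removed first; the remainder is
#' collapsed by the chosen policy (median by default, mean as an alternative
#' workflow emulation) and expressed on the modeling scale
#' `y = -log10(t [mg/L])`, so *lower* thresholds (more potent odorants) map to
#' *higher* y.
#'
#' @param obs Numeric vector of threshold observations, mg/L.
#' @param policy `"median"` (default) or `"mean"`.
#' @return A list with `t_mg_L` and `y`, or `NULL` if nothing survives
#'   filtering (caller should exclude the record).
#' @export
collapse_threshold <- function(obs, policy = c("median", "mean")) {
  policy <- match.arg(policy)
  v <- obs[is.finite(obs) & obs > 0]
  if (length(v) == 0L) return(NULL)
  t <- if (policy == "median") stats::median(v) else mean(v)
  list(t_mg_L = t, y = -log10(t))
}

#' Curate a deduplicated compound registry
#'
#' Runs descriptor consolidation, category assignment, contribution labeling
#' and threshold collapsing over registry records, producing the modeling
#' corpus. Records whose descriptors are all unmappable get `NA` labels;
#' records with no usable threshold get `NA` targets. Both stay in the output
#' (flagged), so the caller controls exclusion.
#'
#' @param records Registry records (see [build_registry()]).
#' @param config A [curation_config()].
#' @param threshold_policy Passed to [collapse_threshold()].
#' @return data.frame with columns `smiles`, `name`, `category`,
#'   `contribution`, `t_mg_L`, `y_neglog10_mg_L`, `concentration_mg_L`.
#' @export
curate_corpus <- function(records, config = curation_config(),
                          threshold_policy = "median") {
  n <- nrow(records)
  cat_ <- character(n); contrib <- character(n)
  t_mg <- rep(NA_real_, n); y <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    d <- consolidate_descriptors(records$descriptors[[i]], config)
    cat_[i] <- assign_category(d, config)
    contrib[i] <- if (is.na(cat_[i])) NA_character_
                  else assign_contribution(cat_[i], config)
    ct <- collapse_threshold(records$threshold_obs[[i]], threshold_policy)
    if (!is.null(ct)) { t_mg[i] <- ct$t_mg_L; y[i] <- ct$y }
  }
  data.frame(smiles = records$smiles, name = records$name,
             category = cat_, contribution = contrib,
             t_mg_L = t_mg, y_neglog10_mg_L = y,
             concentration_mg_L = records$concentration_mg_L,
             stringsAsFactors = FALSE)
}
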