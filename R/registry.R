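#' Canonicalize SMILES strings
#'
#' Converts SMILES to the canonical form produced by OpenBabel's `can` writer.
#' Canonicalization is idempotent: applying it to its own output returns the
#' same string. Stereochemistry flags present in the input are retained.
#'
#' @param smiles Character vector of SMILES strings.
#' @param strict If `TRUE` (default), any unparseable SMILES aborts with an
#'   error naming the offending strings. If `FALSE`, failures are returned as
#'   `NA` with a warning.
#' @return Character vector of canonical SMILES, same length as the input
#'   (with `NA` for failures when `strict = FALSE`).
#' @examples
#' canonicalize_smiles(c("C(C)O", "CCO"))  # both give the same string
#' @export
canonicalize_smiles <- function(smiles, strict = TRUE) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  if (any(!nzchar(smiles) | is.na(smiles))) {
    bad <- which(!nzchar(smiles) | is.na(smiles))
    if (strict) stop("empty or missing SMILES at positions: ",
                     paste(bad, collapse = ", "))
  }
  out <- rep(NA_character_, length(smiles))
  valid <- which(!is.na(smiles) & nzchar(smiles))
  if (length(valid)) {
    res <- ob_canonical(smiles[valid])
    out[valid] <- res
  }
  if (anyNA(out)) {
    bad <- smiles[is.na(out)]
    msg <- paste0("unparseable SMILES: ",
                  paste(utils::head(unique(bad), 10L), collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  out
}

# Batch canonicalization through OpenBabel. The batch converter aborts at the
# first bad record, so on shortfall we fall back to per-molecule conversion to
# identify exactly which inputs failed.
ob_canonical <- function(smiles) {
  one <- function(s, tag) {
    txt <- suppressWarnings(
      ChemmineOB::convertFormat("SMI", "CAN", paste(s, tag)))
    parse_can_block(txt, tag)
  }
  tags <- paste0("q", seq_along(smiles))
  block <- paste(paste(smiles, tags), collapse = "\n")
  txt <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", block))
  res <- parse_can_block(txt, tags)
  if (anyNA(res)) {                      # batch aborted: resolve row by row
    for (i in which(is.na(res))) res[i] <- one(smiles[i], tags[i])
  }
  unname(res)
}

parse_can_block <- function(txt, tags) {
  out <- stats::setNames(rep(NA_character_, length(tags)), tags)
  if (is.null(txt) || !nzchar(txt)) return(out)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (p in parts) {
    if (length(p) >= 2L) {
      tag <- trimws(p[2])
      if (tag %in% tags) out[tag] <- p[1]
    }
  }
  out
}

#' Built-in compound name lookup table
#'
#' A small local name-to-SMILES table covering common volatiles (esters,
#' terpenoids, aldehydes and the compounds used in the worked sensory
#' examples). Name resolution is purely local: no network access ever occurs.
#'
#' @return Named character vector mapping lowercase compound names to SMILES.
#' @export
default_name_lookup <- function() {
  path <- system.file("extdata", "name_lookup.csv", package = "odortools")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(tab$smiles, tolower(trimws(tab$name)))
}

#' Resolve compound names to SMILES
#'
#' Case-insensitive exact match against a local lookup table. Misses are data,
#' not errors: they come back as `NA` and the caller decides whether to drop
#' the record.
#'
#' @param names Character vector of compound names.
#' @param lookup Named character vector (lowercase name -> SMILES), e.g. from
#'   [default_name_lookup()].
#' @return Character vector of SMILES with `NA` for unresolved names.
#' @export
resolve_names <- function(names, lookup = default_name_lookup()) {
  key <- tolower(trimws(names))
  out <- unname(lookup[key])
  out[!nzchar(key) | is.na(key)] <- NA_character_
  out
}

#' Read a compound table
#'
#' Reads a delimited compound table with columns `name`, `smiles`,
#' `descriptors` (semicolon-separated), `threshold_mg_L` (semicolon-separated
#' numerics) and optional `concentration_mg_L`. Missing columns are filled
#' with empty values.
#'
#' @param path Path to a CSV/TSV file (delimiter sniffed from the extension).
#' @return A data.frame with one row per input record.
#' @export
read_compound_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", check.names = TRUE)
  for (col in c("name", "smiles", "descriptors", "threshold_mg_L"))
    if (is.null(df[[col]])) df[[col]] <- ""
  if (is.null(df[["concentration_mg_L"]])) df[["concentration_mg_L"]] <- NA_real_
  df
}

split_semis <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Build a compound registry from a raw table
#'
#' Resolves names to SMILES where no SMILES is given, canonicalizes,
#' filters out unresolvable or unparseable records, and deduplicates by
#' canonical SMILES. Excluded records are returned in a manifest with the
#' reason for exclusion, so a run is always auditable.
#'
#' @param df Data.frame as returned by [read_compound_table()], or with at
#'   least a `smiles` and/or `name` column.
#' @param lookup Name lookup table, see [resolve_names()].
#' @return A list of class `compound_registry`:
#'   \describe{
#'     \item{records}{data.frame with `smiles` (canonical), `name`, `aliases`,
#'       list-columns `descriptors` and `threshold_obs`, and
#'       `concentration_mg_L`; one row per unique canonical SMILES, sorted.}
#'     \item{excluded}{data.frame with `input`, `reason`.}
#'   }
#' @export
build_registry <- function(df, lookup = default_name_lookup()) {
  n <- nrow(df)
  name <- if (!is.null(df$name)) as.character(df$name) else rep("", n)
  smi  <- if (!is.null(df$smiles)) as.character(df$smiles) else rep("", n)
  smi[is.na(smi)] <- ""
  need <- !nzchar(trimws(smi))
  if (any(need)) smi[need] <- resolve_names(name[need], lookup)

  excluded <- data.frame(input = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  unresolved <- is.na(smi) | !nzchar(smi)
  if (any(unresolved)) {
    excluded <- rbind(excluded, data.frame(
      input = ifelse(nzchar(name[unresolved]), name[unresolved], "<blank>"),
      reason = "name not in lookup / no SMILES", stringsAsFactors = FALSE))
  }
  keep <- which(!unresolved)
  can <- rep(NA_character_, n)
  if (length(keep)) can[keep] <- canonicalize_smiles(smi[keep], strict = FALSE)
  bad <- keep[is.na(can[keep])]
  if (length(bad)) {
    excluded <- rbind(excluded, data.frame(
      input = smi[bad], reason = "unparseable SMILES", stringsAsFactors = FALSE))
  }
  keep <- keep[!is.na(can[keep])]

  desc <- lapply(seq_len(n), function(i)
    if (!is.null(df$descriptors)) split_semis(as.character(df$descriptors[i]))
    else character(0))
  thr <- lapply(seq_len(n), function(i) {
    if (is.null(df$threshold_mg_L)) return(numeric(0))
    v <- suppressWarnings(as.numeric(split_semis(as.character(df$threshold_mg_L[i]))))
    v[!is.na(v)]
  })
  conc <- if (!is.null(df$concentration_mg_L))
    suppressWarnings(as.numeric(df$concentration_mg_L)) else rep(NA_real_, n)

  recs <- data.frame(smiles = can[keep], name = name[keep],
                     concentration_mg_L = conc[keep], stringsAsFactors = FALSE)
  recs$descriptors <- desc[keep]
  recs$threshold_obs <- thr[keep]
  out <- list(records = dedupe_records(recs), excluded = excluded)
  class(out) <- "compound_registry"
  out
}

#' Deduplicate canonicalized compound records
#'
#' Merges records sharing one canonical SMILES: descriptors are unioned,
#' threshold observations pooled (collapse to a single target happens later,
#' at curation, under the chosen policy), the lexicographically first
#' non-empty name is kept and the rest stored as aliases. Output is sorted by
#' canonical SMILES, so the result is deterministic regardless of row order.
#'
#' @param records Data.frame with canonical `smiles`, `name`, list-columns
#'   `descriptors`, `threshold_obs`, and `concentration_mg_L`.
#' @return Deduplicated data.frame, one row per canonical SMILES.
#' @export
dedupe_records <- function(records) {
  if (nrow(records) == 0L) {
    records$aliases <- list()
    return(records)
  }
  keys <- sort(unique(records$smiles))
  rows <- lapply(keys, function(k) {
    idx <- which(records$smiles == k)
    nms <- sort(unique(records$name[idx][nzchar(records$name[idx])]))
    thr <- unlist(records$threshold_obs[idx], use.names = FALSE)
    conc <- records$concentration_mg_L[idx]
    conc <- conc[!is.na(conc)]
    data.frame(
      smiles = k,
      name = if (length(nms)) nms[1] else "",
      concentration_mg_L = if (length(conc)) conc[1] else NA_real_,
      stringsAsFactors = FALSE,
      descriptors = I(list(sort(unique(unlist(records$descriptors[idx]))))),
      aliases = I(list(if (length(nms) > 1L) nms[-1] else character(0))),
      threshold_obs = I(list(thr[thr > 0 & is.finite(thr)]))
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.compound_registry <- function(x, ...) {
  cat("compound_registry:", nrow(x$records), "unique compounds,",
      nrow(x$excluded), "excluded\n")
  invisible(x)
}

#' Write registry outputs
#'
#' Writes the normalized compound table as CSV and the exclusion manifest as
#' JSON next to it.
#'
#' @param registry A `compound_registry`.
#' @param path Output CSV path; the manifest goes to `<path>.exclusions.json`.
#' @return Invisibly, the CSV path.
#' @export
write_registry <- function(registry, path) {
  recs <- registry$records
  flat <- data.frame(
    smiles = recs$smiles, name = recs$name,
    aliases = vapply(recs$aliases, paste, "", collapse = ";"),
    descriptors = vapply(recs$descriptors, paste, "", collapse = ";"),
    threshold_mg_L = vapply(recs$threshold_obs,
                            function(v) paste(v, collapse = ";"), ""),
    concentration_mg_L = recs$concentration_mg_L,
    stringsAsFactors = FALSE)
  utils::write.csv(flat, path, row.names = FALSE)
  jsonlite::write_json(registry$excluded,
                       paste0(path, ".exclusions.json"), auto_unbox = TRUE)
  invisible(path)
}
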