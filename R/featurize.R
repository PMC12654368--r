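# Molecular featurization: ECFP4/ECFP6/MACCS fingerprints, the 4-descriptor
# physicochemical block, and molecular graphs for the graph-convolution family.
# All features are pure functions of the canonical molecule: any SMILES
# spelling of the same structure yields identical output.

# Decode OpenBabel fingerprint bit-words into a 0/1 vector. Words arrive as R
# integers; the 0x80000000 pattern is R's integer NA and negatives are the
# high-bit words, so both are remapped before base-2 expansion. Verified
# bit-identical to ChemmineOB::fingerprint_OB, which decodes one bit per call
# and is ~200x slower.
decode_fp_words <- function(words) {
  w <- as.double(words)
  w[is.na(w)] <- -2^31
  w[w < 0] <- w[w < 0] + 2^32
  as.integer(outer(2^(0:31), w, function(p, x) floor(x / p) %% 2))
}

ob_fingerprints <- function(smiles, name) {
  if (length(smiles) == 0L) return(matrix(integer(0), 0, 0))
  handle <- get("OBFingerprint_FindFingerprint",
                envir = asNamespace("ChemmineOB"))(name)
  getfp <- get("OBFingerprint_GetFingerprint", envir = asNamespace("ChemmineOB"))
  block <- paste(paste(smiles, paste0("f", seq_along(smiles))), collapse = "\n")
  rows <- ChemmineOB::forEachMol("SMILES", block, function(mol)
    decode_fp_words(getfp(handle, mol, numeric(1))[[2]]))
  if (length(rows) != length(smiles))
    stop("fingerprinting failed: ", length(smiles) - length(rows),
         " SMILES did not parse")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# OR-fold a wide binary matrix to nbits columns (bit i -> i mod nbits).
fold_bits <- function(m, nbits) {
  if (ncol(m) == nbits) return(m)
  stopifnot(ncol(m) %% nbits == 0L)
  out <- matrix(0L, nrow(m), nbits)
  for (k in seq_len(ncol(m) / nbits)) {
    blk <- m[, ((k - 1L) * nbits + 1L):(k * nbits), drop = FALSE]
    out <- pmax(out, blk)
  }
  out
}

#' Extended-connectivity fingerprints
#'
#' Circular (Morgan-type) fingerprints with neighborhood diameter 4 or 6
#' (radius 2 or 3), hashed and folded to a fixed number of presence bits.
#' Hydrogens are implicit and counts are folded to binary bits.
#'
#' @param smiles Character vector of (ideally canonical) SMILES.
#' @param diameter 4 or 6.
#' @param nbits Number of bits after folding (default 1024).
#' @return Integer matrix, `length(smiles)` x `nbits`, entries in \{0,1\}.
#' @export
ecfp <- function(smiles, diameter = 4, nbits = 1024L) {
  stopifnot(diameter %in% c(4, 6))
  raw <- ob_fingerprints(smiles, paste0("ECFP", diameter))
  fold_bits(raw, as.integer(nbits))
}

#' MACCS structural keys
#'
#' The 166 predefined MACCS substructure keys, returned in the conventional
#' 167-bit layout (position 1 is the unused key 0, key *k* sits at position
#' *k* + 1).
#'
#' @param smiles Character vector of SMILES.
#' @return Integer matrix, `length(smiles)` x 167, entries in \{0,1\}.
#' @export
maccs <- function(smiles) {
  raw <- ob_fingerprints(smiles, "MACCS")  # 256-bit vector, keys at 1..166
  out <- cbind(0L, raw[, 1:166, drop = FALSE])
  colnames(out) <- paste0("maccs", 0:166)
  out
}

#' Physicochemical descriptor block
#'
#' Molecular weight (g/mol), Crippen-type additive logP, topological polar
#' surface area (A^2) and molar refractivity, in that order.
#'
#' @param smiles Character vector of SMILES.
#' @return Numeric matrix, `length(smiles)` x 4, columns
#'   `MW`, `logP`, `TPSA`, `MR`.
#' @export
physchem <- function(smiles) {
  if (length(smiles) == 0L)
    return(matrix(numeric(0), 0, 4,
                  dimnames = list(NULL, c("MW", "logP", "TPSA", "MR"))))
  block <- paste(paste(smiles, paste0("p", seq_along(smiles))), collapse = "\n")
  rows <- ChemmineOB::forEachMol("SMILES", block, function(mol) {
    pr <- ChemmineOB::prop_OB(mol)
    c(MW = pr$MW, logP = pr$logP, TPSA = pr$TPSA, MR = pr$MR)
  })
  if (length(rows) != length(smiles))
    stop("physchem: ", length(smiles) - length(rows), " SMILES did not parse")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble a model feature block
#'
#' Concatenates the fingerprint of the requested scheme with the raw
#' physicochemical 4-vector. Standardization of the physchem columns (train
#' statistics only) happens inside the model pipeline, never here, so no
#' validation information can leak into features.
#'
#' @param smiles Character vector of SMILES.
#' @param scheme `"ecfp4"`, `"ecfp6"` or `"maccs"`.
#' @return Numeric matrix with `nbits + 4` columns; attribute `scheme` records
#'   the fingerprint used.
#' @export
featurize <- function(smiles, scheme = c("ecfp4", "ecfp6", "maccs")) {
  scheme <- match.arg(scheme)
  bits <- switch(scheme,
                 ecfp4 = ecfp(smiles, 4),
                 ecfp6 = ecfp(smiles, 6),
                 maccs = maccs(smiles))
  if (is.null(colnames(bits)))
    colnames(bits) <- paste0(scheme, "_", seq_len(ncol(bits)))
  out <- cbind(bits, physchem(smiles))
  attr(out, "scheme") <- scheme
  out
}

#' Molecular graph for the graph-convolution model family
#'
#' Heavy-atom graph: one node per non-hydrogen atom with element, degree and
#' aromaticity features; one undirected edge per bond with its order. The
#' physicochemical 4-vector rides along for concatenation at the readout.
#'
#' @param smiles A single SMILES string.
#' @return A list of class `molecular_graph` with `atoms` (data.frame:
#'   `element`, `degree`, `aromatic`), `bonds` (data.frame: `i`, `j`,
#'   `order`), and `physchem` (named numeric 4-vector).
#' @export
to_graph <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  atom_rx <- "\\[[^]]+\\]|Br|Cl|[BCNOPSFI]|[bcnops]"
  tokens <- regmatches(smiles, gregexpr(atom_rx, smiles))[[1]]
  if (length(tokens) == 1L) {        # single heavy atom: trivial but valid graph
    el <- gsub("[^A-Za-z]", "", tokens[1])
    el <- paste0(toupper(substr(el, 1, 1)), substring(el, 2))
    out <- list(atoms = data.frame(element = el, degree = 0L,
                                   aromatic = FALSE, stringsAsFactors = FALSE),
                bonds = data.frame(i = integer(0), j = integer(0),
                                   order = integer(0)),
                physchem = physchem(smiles)[1, ])
    class(out) <- "molecular_graph"
    return(out)
  }
  sdf <- ChemmineR::smiles2sdf(c(g = smiles))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- gsub("_.*$", "", rownames(ab))
  n <- length(elements)
  if (n == 0L) stop("empty molecule: ", smiles)
  bonds <- if (is.null(bb) || nrow(bb) == 0L)
    data.frame(i = integer(0), j = integer(0), order = integer(0))
  else
    data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  degree <- tabulate(c(bonds$i, bonds$j), nbins = n)
  aromatic <- rep(FALSE, n)
  if (nrow(bonds) > 0L) {
    rng <- tryCatch(ChemmineR::rings(sdf, type = "all", arom = TRUE),
                    error = function(e) NULL)
    if (!is.null(rng) && length(rng$RINGS)) {
      arom_rings <- rng$RINGS[which(rng$AROMATIC)]
      idx <- unique(as.integer(gsub(".*_", "", unlist(arom_rings))))
      aromatic[idx] <- TRUE
    }
  }
  out <- list(atoms = data.frame(element = elements, degree = degree,
                                 aromatic = aromatic, stringsAsFactors = FALSE),
              bonds = bonds,
              physchem = physchem(smiles)[1, ])
  class(out) <- "molecular_graph"
  out
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("molecular_graph:", nrow(x$atoms), "atoms,", nrow(x$bonds), "bonds\n")
  invisible(x)
}

#' Persist a feature matrix with a JSON sidecar
#'
#' Writes the (sparse-ish) binary-plus-physchem matrix as CSV and records the
#' scheme and column meaning in `<path>.meta.json`.
#'
#' @param features Matrix from [featurize()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_features <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  jsonlite::write_json(
    list(scheme = attr(features, "scheme"),
         n_columns = ncol(features),
         physchem_columns = c("MW", "logP", "TPSA", "MR")),
    paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
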