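# Bemis-Murcko scaffolds and the scaffold-aware greedy train/validation split.
# The scaffold of a molecule is its ring systems plus the linkers connecting
# them; terminal side chains are removed by iteratively pruning degree-1 heavy
# atoms. Acyclic molecules (common among volatiles: esters, aldehydes,
# alcohols) have no scaffold and share the empty key "".

prune_terminal <- function(n_atoms, bonds) {
  keep <- rep(TRUE, n_atoms)
  repeat {
    deg <- tabulate(c(bonds$i[keep[bonds$i] & keep[bonds$j]],
                      bonds$j[keep[bonds$i] & keep[bonds$j]]), nbins = n_atoms)
    drop <- keep & (deg <= 1L)
    if (!any(drop)) break
    keep <- keep & !drop
    if (!any(keep)) break
  }
  keep
}

molfile_text <- function(title, elements, coords, bonds) {
  n <- length(elements)
  header <- c(title, "  odortools", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(bonds))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   coords[, 1], coords[, 2], coords[, 3], elements)
  bl <- if (nrow(bonds)) sprintf("%3d%3d%3d  0  0  0  0",
                                 bonds$i, bonds$j, bonds$order) else character(0)
  paste(c(header, counts, atoms, bl, "M  END", "$$$$"), collapse = "\n")
}

#' Bemis-Murcko scaffold keys
#'
#' Computes the canonical SMILES of each molecule's Murcko framework (ring
#' systems plus linkers, terminal side chains iteratively stripped). Acyclic
#' molecules map to the empty key `""`. Results are cached per canonical
#' input within the call, so repeated structures cost one computation.
#'
#' @param smiles Character vector of valid SMILES.
#' @return Character vector of scaffold keys (canonical SMILES or `""`).
#' @examples
#' \dontrun{
#' murcko_scaffold(c("Cc1ccccc1", "CCCCCC=O"))  # "c1ccccc1", ""
#' }
#' @export
murcko_scaffold <- function(smiles) {
  if (length(smiles) == 0L) return(character(0))
  uniq <- unique(smiles)
  keys <- rep("", length(uniq))
  # a SMILES without ring-closure digits is acyclic: scaffold is "" by definition
  ringy <- which(grepl("[0-9]", uniq))
  if (length(ringy) == 0L) return(keys[match(smiles, uniq)])
  sdf <- ChemmineR::smiles2sdf(
    stats::setNames(uniq[ringy], paste0("s", ringy)))
  if (length(sdf) != length(ringy))
    stop("murcko_scaffold: some SMILES did not parse")
  mol_texts <- character(0); mol_idx <- integer(0)
  for (w in seq_along(ringy)) {
    k <- ringy[w]
    mol <- sdf[[w]]
    ab <- ChemmineR::atomblock(mol)
    bb <- ChemmineR::bondblock(mol)
    if (is.null(bb) || nrow(bb) == 0L) next           # single atom: acyclic
    bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
    keep <- prune_terminal(nrow(ab), bonds)
    if (!any(keep)) next                               # fully acyclic
    remap <- cumsum(keep)
    kb <- bonds[keep[bonds$i] & keep[bonds$j], , drop = FALSE]
    kb$i <- remap[kb$i]; kb$j <- remap[kb$j]
    elements <- gsub("_.*$", "", rownames(ab))[keep]
    coords <- ab[keep, 1:3, drop = FALSE]
    mol_texts <- c(mol_texts, molfile_text(paste0("s", k), elements, coords, kb))
    mol_idx <- c(mol_idx, k)
  }
  if (length(mol_texts)) {
    txt <- suppressWarnings(
      ChemmineOB::convertFormat("SDF", "CAN", paste(mol_texts, collapse = "\n")))
    res <- parse_can_block(txt, paste0("s", mol_idx))
    if (anyNA(res)) stop("murcko_scaffold: scaffold re-canonicalization failed")
    keys[mol_idx] <- unname(res)
  }
  keys[match(smiles, uniq)]
}

#' Scaffold-aware greedy train/validation split
#'
#' Groups compounds by Murcko scaffold key and assigns whole groups so that no
#' scaffold ever spans both sets. Groups are visited largest first (ties
#' broken by key, ascending) and assigned to training while the training set
#' stays within `(1 - target_fraction) * N`; the first group that would
#' overflow, and every group after it, goes to validation. Rare scaffolds
#' therefore land in validation, giving the harder, more honest
#' generalization test. The procedure is deterministic: row order never
#' changes the assignment. All acyclic compounds share the `""` scaffold and
#' move as one indivisible group (a known coarseness for volatile datasets).
#'
#' @param smiles Character vector of canonical SMILES (deduplicated).
#' @param target_fraction Validation fraction in (0, 1), default 0.2.
#' @param seed Optional integer; only used when `shuffle = TRUE`.
#' @param shuffle If `TRUE`, groups are visited in seeded random order instead
#'   of by size (an optional shuffled-greedy mode).
#' @param scaffold_keys Optional precomputed scaffold keys aligned with
#'   `smiles` (e.g. from one batched [murcko_scaffold()] call over several
#'   corpora); computed internally when `NULL`.
#' @return data.frame of class `scaffold_split` with columns `smiles`,
#'   `scaffold`, `membership` (`"train"`/`"validation"`), and attributes
#'   `target_fraction` and `achieved_fraction`.
#' @export
greedy_split <- function(smiles, target_fraction = 0.2, seed = NULL,
                         shuffle = FALSE, scaffold_keys = NULL) {
  stopifnot(target_fraction > 0, target_fraction < 1)
  if (anyDuplicated(smiles))
    stop("greedy_split expects deduplicated SMILES")
  keys <- if (is.null(scaffold_keys)) murcko_scaffold(smiles)
          else { stopifnot(length(scaffold_keys) == length(smiles)); scaffold_keys }
  groups <- split(seq_along(smiles), keys)
  if (length(groups) < 2L)
    stop("split impossible: fewer than 2 scaffold groups (all ",
         length(smiles), " compounds share one scaffold)")
  sizes <- vapply(groups, length, 0L)
  ord <- if (shuffle) {
    if (!is.null(seed)) set.seed(seed)
    sample(seq_along(groups))
  } else {
    order(-sizes, names(groups))
  }
  n <- length(smiles)
  cap <- (1 - target_fraction) * n
  membership <- character(n)
  train_size <- 0L
  in_train <- TRUE
  for (g in ord) {
    if (in_train && train_size + sizes[g] > cap) in_train <- FALSE
    membership[groups[[g]]] <- if (in_train) "train" else "validation"
    if (in_train) train_size <- train_size + sizes[g]
  }
  if (!any(membership == "train"))
    stop("split impossible: the largest scaffold group alone exceeds the ",
         "training budget")
  out <- data.frame(smiles = smiles, scaffold = keys,
                    membership = membership, stringsAsFactors = FALSE)
  attr(out, "target_fraction") <- target_fraction
  attr(out, "achieved_fraction") <- mean(membership == "validation")
  class(out) <- c("scaffold_split", "data.frame")
  out
}

#' @export
print.scaffold_split <- function(x, ...) {
  cat("scaffold_split:", sum(x$membership == "train"), "train /",
      sum(x$membership == "validation"), "validation (",
      round(attr(x, "achieved_fraction"), 3), "achieved vs",
      attr(x, "target_fraction"), "target )\n")
  invisible(x)
}
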