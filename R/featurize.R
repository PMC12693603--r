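# Molecular graph featurization: fixed 25-dimensional atom feature vectors and
# 6-dimensional bond feature vectors. The slot layout is frozen; models, the
# interpretability code and the serialized graph dumps all rely on it.

#' Atom feature slot names (frozen layout, length 25)
#'
#' The 25 atom feature slots, in order: a 9-way element one-hot over the
#' supported vocabulary (C, N, O, S, F, Cl, Br, P, Na), atomic number,
#' formal charge, explicit valence, radical electron count, explicit and
#' implicit hydrogen counts, a 3-way hybridization one-hot (sp, sp2, sp3;
#' all-zero for other hybridizations), an aromaticity flag, the heavy-atom
#' degree, and five ring flags (any ring, then 3-, 4-, 5-, 6-membered).
#'
#' @return Character vector of length 25.
#' @export
atom_feature_names <- function() {
  c(paste0("id_", ATOM_VOCAB),
    "atomic_number", "formal_charge", "explicit_valence", "radical_electrons",
    "explicit_h", "implicit_h",
    "hyb_sp", "hyb_sp2", "hyb_sp3",
    "aromatic", "degree",
    "ring_any", "ring_3", "ring_4", "ring_5", "ring_6")
}

#' Bond feature slot names (frozen layout, length 6)
#'
#' Four-way bond-type one-hot (single, double, triple, aromatic), then a
#' conjugation flag and a ring-membership flag.
#'
#' @return Character vector of length 6.
#' @export
bond_feature_names <- function() {
  c("bond_single", "bond_double", "bond_triple", "bond_aromatic",
    "conjugated", "in_ring")
}

#' Supported element vocabulary
#'
#' @return Character vector of the nine supported heavy elements, in the
#'   one-hot slot order.
#' @export
atom_vocabulary <- function() ATOM_VOCAB

.check_supported <- function(mol, on_unsupported = c("error", "zero")) {
  on_unsupported <- match.arg(on_unsupported)
  bad <- setdiff(unique(mol$element), ATOM_VOCAB)
  if (length(bad) && on_unsupported == "error") {
    stop(sprintf("unsupported element(s) %s in molecule '%s'",
                 paste(bad, collapse = ", "), mol$smiles), call. = FALSE)
  }
  invisible(length(bad) == 0)
}

# n x 25 atom feature matrix for a parsed molecule
.atom_feature_matrix <- function(mol) {
  n <- mol$n
  x <- matrix(0, n, 25, dimnames = list(NULL, atom_feature_names()))
  for (i in seq_len(n)) {
    el <- mol$element[i]
    if (el %in% ATOM_VOCAB) x[i, paste0("id_", el)] <- 1
    x[i, "atomic_number"] <- ATOMIC_NUMBERS[[el]] %||% 0
    x[i, "formal_charge"] <- mol$charge[i]
    x[i, "explicit_valence"] <- mol$explicit_valence[i]
    x[i, "radical_electrons"] <- mol$radical_electrons[i]
    x[i, "explicit_h"] <- mol$explicit_h[i]
    x[i, "implicit_h"] <- mol$implicit_h[i]
    if (mol$hybridization[i] %in% c("sp", "sp2", "sp3")) {
      x[i, paste0("hyb_", mol$hybridization[i])] <- 1
    }
    x[i, "aromatic"] <- as.numeric(mol$aromatic_atom[i])
    x[i, "degree"] <- mol$degree[i]
    x[i, "ring_any"] <- as.numeric(mol$in_ring_atom[i])
    x[i, c("ring_3", "ring_4", "ring_5", "ring_6")] <- as.numeric(mol$ring_size_atom[i, ])
  }
  x
}

# nb x 6 bond feature matrix (one row per chemical bond, undirected)
.bond_feature_matrix <- function(mol) {
  nb <- nrow(mol$bonds)
  x <- matrix(0, nb, 6, dimnames = list(NULL, bond_feature_names()))
  if (!nb) return(x)
  for (r in seq_len(nb)) {
    slot <- if (mol$aromatic_bond[r]) "bond_aromatic"
      else switch(as.character(mol$bonds$order[r]),
                  `1` = "bond_single", `2` = "bond_double", `3` = "bond_triple",
                  "bond_single")
    x[r, slot] <- 1
    x[r, "conjugated"] <- as.numeric(mol$conjugated_bond[r])
    x[r, "in_ring"] <- as.numeric(mol$in_ring_bond[r])
  }
  x
}

.as_mol <- function(x) {
  if (inherits(x, "og_mol")) return(x)
  if (is.character(x) && length(x) == 1) return(parse_mols(x)[[1]])
  stop("expected a SMILES string or a parsed molecule", call. = FALSE)
}

#' Featurize one atom
#'
#' Computes the frozen 25-dimensional feature vector for a single atom of a
#' molecule (see [atom_feature_names()] for the slot layout).
#'
#' @param mol A SMILES string or a molecule parsed by the package.
#' @param index Atom index (1-based, heavy atoms in toolkit order).
#' @param on_unsupported `"error"` (default) rejects molecules containing
#'   elements outside [atom_vocabulary()]; `"zero"` leaves the identity
#'   one-hot block all-zero for such atoms and warns.
#' @return Named numeric vector of length 25.
#' @examples
#' featurize_atom("C", 1)[c("id_C", "implicit_h")]
#' @export
featurize_atom <- function(mol, index, on_unsupported = c("error", "zero")) {
  on_unsupported <- match.arg(on_unsupported)
  mol <- .as_mol(mol)
  ok <- .check_supported(mol, on_unsupported)
  if (!ok) warning(sprintf("molecule '%s' has elements outside the vocabulary; identity block zeroed", mol$smiles))
  stopifnot(index >= 1, index <= mol$n)
  .atom_feature_matrix(mol)[index, ]
}

#' Featurize one bond
#'
#' Computes the frozen 6-dimensional feature vector for a single chemical
#' bond (see [bond_feature_names()]).
#'
#' @inheritParams featurize_atom
#' @param index Bond index (1-based, toolkit bond order).
#' @return Named numeric vector of length 6.
#' @examples
#' featurize_bond("CC", 1)
#' @export
featurize_bond <- function(mol, index, on_unsupported = c("error", "zero")) {
  on_unsupported <- match.arg(on_unsupported)
  mol <- .as_mol(mol)
  .check_supported(mol, on_unsupported)
  stopifnot(index >= 1, index <= nrow(mol$bonds))
  .bond_feature_matrix(mol)[index, ]
}

#' Convert a SMILES string to a molecular graph
#'
#' Parses a SMILES string and assembles the graph representation used by the
#' graph neural networks: an `n x 25` node feature matrix, a directed edge
#' list in which every chemical bond appears in both directions, and a
#' `2m x 6` edge feature matrix (both directed copies of a bond carry the
#' same features). Hydrogens are implicit: only heavy atoms become nodes.
#'
#' @param smiles A single SMILES string.
#' @param on_unsupported `"error"` (default) rejects molecules with elements
#'   outside the supported vocabulary; `"skip"` returns `NULL` with a warning.
#' @return An object of class `molecular_graph` with elements
#'   `node_features` (n x 25), `edge_index` (2m x 2 integer matrix, columns
#'   `src`, `dst`), `edge_features` (2m x 6) and `smiles`; or `NULL` when the
#'   molecule is skipped.
#' @examples
#' g <- smiles_to_graph("CCO")
#' dim(g$node_features)  # 3 x 25
#' nrow(g$edge_index)    # 4 directed edges
#' @export
smiles_to_graph <- function(smiles, on_unsupported = c("error", "skip")) {
  on_unsupported <- match.arg(on_unsupported)
  stopifnot(is.character(smiles), length(smiles) == 1, nzchar(smiles))
  mol <- parse_mols(smiles)[[1]]
  bad <- setdiff(unique(mol$element), ATOM_VOCAB)
  if (length(bad)) {
    if (on_unsupported == "error") {
      stop(sprintf("unsupported element(s) %s in molecule '%s'",
                   paste(bad, collapse = ", "), smiles), call. = FALSE)
    }
    warning(sprintf("skipping molecule '%s' (unsupported element(s) %s)",
                    smiles, paste(bad, collapse = ", ")))
    return(NULL)
  }
  .graph_from_mol(mol)
}

.graph_from_mol <- function(mol) {
  nodef <- .atom_feature_matrix(mol)
  bondf <- .bond_feature_matrix(mol)
  nb <- nrow(mol$bonds)
  if (nb) {
    edge_index <- cbind(src = c(mol$bonds$a1, mol$bonds$a2),
                        dst = c(mol$bonds$a2, mol$bonds$a1))
    edge_features <- rbind(bondf, bondf)
  } else {
    edge_index <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("src", "dst")))
    edge_features <- matrix(0, 0, 6, dimnames = list(NULL, bond_feature_names()))
  }
  structure(list(node_features = nodef,
                 edge_index = edge_index,
                 edge_features = edge_features,
                 smiles = mol$smiles),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> %s: %d atoms, %d directed edges\n",
              x$smiles, nrow(x$node_features), nrow(x$edge_index)))
  invisible(x)
}

#' Convert many SMILES to molecular graphs
#'
#' Vectorized companion to [smiles_to_graph()]; parses in one toolkit batch.
#'
#' @param smiles Character vector of SMILES.
#' @param on_unsupported `"error"` or `"skip"` (skipped molecules are dropped
#'   with a warning; the result carries the kept indices as `kept`).
#' @return List of `molecular_graph` objects with attribute `kept`.
#' @export
smiles_to_graphs <- function(smiles, on_unsupported = c("error", "skip")) {
  on_unsupported <- match.arg(on_unsupported)
  mols <- parse_mols(smiles)
  keep <- logical(length(mols))
  for (i in seq_along(mols)) {
    bad <- setdiff(unique(mols[[i]]$element), ATOM_VOCAB)
    if (length(bad)) {
      if (on_unsupported == "error") {
        stop(sprintf("unsupported element(s) %s in molecule %d ('%s')",
                     paste(bad, collapse = ", "), i, smiles[i]), call. = FALSE)
      }
      warning(sprintf("skipping molecule %d ('%s'): unsupported element(s) %s",
                      i, smiles[i], paste(bad, collapse = ", ")))
    } else keep[i] <- TRUE
  }
  out <- lapply(mols[keep], .graph_from_mol)
  attr(out, "kept") <- which(keep)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
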