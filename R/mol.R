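# Internal molecule model.
#
# SMILES parsing is delegated to ChemmineR/OpenBabel, which yields a kekulized
# connection table (atoms + integer bond orders + formal charges). All atom-level
# chemistry needed for featurization -- ring perception, aromaticity,
# hybridization, implicit hydrogens, conjugation -- is perceived here from that
# table. The conventions are documented in the package vignette.

ATOM_VOCAB <- c("C", "N", "O", "S", "F", "Cl", "Br", "P", "Na")

ATOMIC_NUMBERS <- c(C = 6L, N = 7L, O = 8L, S = 16L, F = 9L, Cl = 17L,
                    Br = 35L, P = 15L, Na = 11L, H = 1L)

# allowed valence lists (Daylight organic-subset style), used to derive
# implicit hydrogen counts from the kekulized bond-order sum
.allowed_valence <- list(
  C = 4, N = c(3, 5), O = 2, S = c(2, 4, 6), P = c(3, 5),
  F = 1, Cl = 1, Br = 1, Na = 1, H = 1
)

# MDL ctab charge codes -> formal charge
.mdl_charge <- function(code) {
  map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L,
           `6` = -2L, `7` = -3L)
  out <- map[as.character(code)]
  out[is.na(out)] <- 0L
  unname(out)
}

# Convert SMILES to kekulized V2000 ctabs through OpenBabel, keeping batch
# alignment via molecule titles (OpenBabel silently drops unparseable inputs).
.ctabs_from_smiles <- function(smiles) {
  input <- paste(sprintf("%s m%d", smiles, seq_along(smiles)), collapse = "\n")
  txt <- ChemmineOB::convertFormat("SMI", "SDF", input)
  recs <- strsplit(txt, "\\$\\$\\$\\$\n?")[[1]]
  recs <- recs[nzchar(trimws(recs))]
  out <- vector("list", length(smiles))
  for (rec in recs) {
    lines <- strsplit(rec, "\n", fixed = TRUE)[[1]]
    while (length(lines) && !nzchar(trimws(lines[1])) ) lines <- lines[-1]
    title <- trimws(lines[1])
    idx <- suppressWarnings(as.integer(sub("^m", "", title)))
    if (!is.na(idx) && idx >= 1 && idx <= length(smiles)) out[[idx]] <- lines
  }
  bad <- which(vapply(out, is.null, logical(1)))
  if (length(bad)) {
    stop(sprintf("cannot parse SMILES at position %d: '%s'",
                 bad[1], smiles[bad[1]]), call. = FALSE)
  }
  out
}

# Parse a vector of SMILES into a list of internal molecule objects.
parse_mols <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1, all(nzchar(smiles)))
  ctabs <- .ctabs_from_smiles(smiles)
  lapply(seq_along(smiles), function(i) .mol_from_ctab(ctabs[[i]], smiles[i]))
}

.mol_from_ctab <- function(lines, smiles) {
  counts <- lines[4]
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  if (is.na(n_atoms) || n_atoms < 1) {
    stop(sprintf("cannot parse SMILES: '%s' (empty molecule)", smiles),
         call. = FALSE)
  }
  atom_lines <- lines[4 + seq_len(n_atoms)]
  element <- character(n_atoms)
  charge <- integer(n_atoms)
  for (i in seq_len(n_atoms)) {
    f <- strsplit(trimws(atom_lines[i]), "\\s+")[[1]]
    element[i] <- f[4]
    charge[i] <- .mdl_charge(as.integer(f[6]))
  }
  if (n_bonds > 0) {
    bond_lines <- lines[4 + n_atoms + seq_len(n_bonds)]
    bonds <- data.frame(
      a1 = as.integer(substr(bond_lines, 1, 3)),
      a2 = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9)))
  } else {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  }
  # authoritative charges from M CHG property lines (reset semantics)
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines)) {
    charge <- integer(n_atoms)
    for (cl in chg_lines) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG\\s+\\d+", "", cl)), "\\s+")[[1]])
      if (length(f) >= 2) {
        pairs <- matrix(f, ncol = 2, byrow = TRUE)
        charge[pairs[, 1]] <- pairs[, 2]
      }
    }
  }
  # strip explicit hydrogen atoms, crediting them to their heavy neighbour
  explicit_h <- integer(length(element))
  is_h <- element == "H"
  if (any(is_h)) {
    h_idx <- which(is_h)
    for (r in seq_len(nrow(bonds))) {
      a1 <- bonds$a1[r]; a2 <- bonds$a2[r]
      if (is_h[a1] && !is_h[a2]) explicit_h[a2] <- explicit_h[a2] + 1L
      if (is_h[a2] && !is_h[a1]) explicit_h[a1] <- explicit_h[a1] + 1L
    }
    keep <- which(!is_h)
    remap <- integer(length(element)); remap[keep] <- seq_along(keep)
    bonds <- bonds[!is_h[bonds$a1] & !is_h[bonds$a2], , drop = FALSE]
    bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
    element <- element[keep]; charge <- charge[keep]
    explicit_h <- explicit_h[keep]
  }
  .perceive(list(smiles = smiles, element = element, charge = charge,
                 bonds = bonds, explicit_h = explicit_h))
}

# neighbour list from a bond table
.adjacency <- function(n, bonds) {
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      a1 <- bonds$a1[r]; a2 <- bonds$a2[r]
      adj[[a1]] <- c(adj[[a1]], a2)
      adj[[a2]] <- c(adj[[a2]], a1)
    }
  }
  adj
}

# enumerate simple cycles of length `size` (each reported once, as an ordered
# atom vector starting at its smallest atom index)
.find_cycles <- function(adj, size) {
  n <- length(adj)
  out <- list()
  seen <- character(0)
  path <- integer(size)
  dfs <- function(start, v, depth) {
    path[depth] <<- v
    if (depth == size) {
      if (start %in% adj[[v]]) {
        key <- paste(sort(path), collapse = "-")
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          out[[length(out) + 1L]] <<- path
        }
      }
      return(invisible())
    }
    for (w in adj[[v]]) {
      if (w > start && !(w %in% path[seq_len(depth)])) dfs(start, w, depth + 1L)
    }
  }
  for (s in seq_len(n)) dfs(s, s, 1L)
  out
}

# bond index lookup: key "a-b" with a<b
.bond_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "-")

.perceive <- function(mol) {
  n <- length(mol$element)
  bonds <- mol$bonds
  nb <- nrow(bonds)
  adj <- .adjacency(n, bonds)
  bidx <- stats::setNames(seq_len(nb), .bond_key(bonds$a1, bonds$a2))

  degree <- vapply(adj, length, integer(1))

  # ring membership: a bond is in a ring iff it is not a bridge
  in_ring_bond <- logical(nb)
  if (nb) {
    for (r in seq_len(nb)) {
      # BFS from a1 to a2 avoiding bond r
      src <- bonds$a1[r]; dst <- bonds$a2[r]
      visited <- logical(n); visited[src] <- TRUE
      queue <- src
      while (length(queue) && !visited[dst]) {
        v <- queue[1]; queue <- queue[-1]
        for (w in adj[[v]]) {
          if ((v == src && w == dst) || (v == dst && w == src)) next
          if (!visited[w]) { visited[w] <- TRUE; queue <- c(queue, w) }
        }
      }
      in_ring_bond[r] <- visited[dst]
    }
  }
  in_ring_atom <- logical(n)
  if (nb) {
    for (r in which(in_ring_bond)) {
      in_ring_atom[bonds$a1[r]] <- TRUE
      in_ring_atom[bonds$a2[r]] <- TRUE
    }
  }

  # ring-size flags for 3..6-membered rings, and the 5/6 cycles themselves
  ring_size_atom <- matrix(FALSE, n, 4, dimnames = list(NULL, c("r3", "r4", "r5", "r6")))
  cycles56 <- list()
  for (s in 3:6) {
    cyc <- .find_cycles(adj, s)
    for (cy in cyc) ring_size_atom[cy, s - 2L] <- TRUE
    if (s >= 5) cycles56 <- c(cycles56, cyc)
  }

  # aromaticity: simplified Hueckel rule on 5/6-membered cycles of the
  # kekulized graph (pi count 6 from ring double bonds and lone-pair donors)
  aromatic_atom <- logical(n)
  aromatic_bond <- logical(nb)
  for (cy in cycles56) {
    k <- length(cy)
    ring_b <- integer(k)
    for (j in seq_len(k)) {
      a <- cy[j]; b <- cy[if (j == k) 1L else j + 1L]
      ring_b[j] <- bidx[[.bond_key(a, b)]]
    }
    pi_total <- 0
    ok <- TRUE
    for (j in seq_len(k)) {
      a <- cy[j]
      el <- mol$element[a]
      inc <- ring_b[c(j, if (j == 1L) k else j - 1L)]
      ring_dbl <- any(bonds$order[inc] == 2)
      all_inc <- which(bonds$a1 == a | bonds$a2 == a)
      exo_dbl <- any(bonds$order[setdiff(all_inc, inc)] >= 2)
      pi <- if (el == "C") {
        if (ring_dbl) 1 else if (exo_dbl) 0 else NA
      } else if (el %in% c("N", "P")) {
        if (ring_dbl) 1 else 2
      } else if (el %in% c("O", "S")) {
        if (ring_dbl) NA else 2
      } else NA
      if (is.na(pi)) { ok <- FALSE; break }
      pi_total <- pi_total + pi
    }
    if (ok && pi_total == 6) {
      aromatic_atom[cy] <- TRUE
      aromatic_bond[ring_b] <- TRUE
    }
  }

  # valence bookkeeping and implicit hydrogens
  order_sum <- numeric(n)
  n_multiple <- integer(n)   # double/triple bonds incident (kekulized)
  if (nb) {
    for (r in seq_len(nb)) {
      o <- bonds$order[r]
      for (a in c(bonds$a1[r], bonds$a2[r])) {
        order_sum[a] <- order_sum[a] + o
        if (o >= 2) n_multiple[a] <- n_multiple[a] + 1L
      }
    }
  }
  explicit_valence <- as.integer(order_sum) + mol$explicit_h
  implicit_h <- integer(n)
  for (i in seq_len(n)) {
    el <- mol$element[i]
    allowed <- .allowed_valence[[el]]
    if (is.null(allowed) || el == "Na") { implicit_h[i] <- 0L; next }
    adj_allowed <- if (el == "C") allowed - abs(mol$charge[i]) else allowed + mol$charge[i]
    used <- explicit_valence[i]
    fit <- adj_allowed[adj_allowed >= used]
    implicit_h[i] <- if (length(fit)) as.integer(min(fit) - used) else 0L
  }

  # hybridization (heuristic; `other` covers hypervalent/unbonded metals)
  n_triple <- integer(n)
  n_double <- integer(n)
  if (nb) {
    for (r in seq_len(nb)) {
      for (a in c(bonds$a1[r], bonds$a2[r])) {
        if (bonds$order[r] == 3) n_triple[a] <- n_triple[a] + 1L
        if (bonds$order[r] == 2) n_double[a] <- n_double[a] + 1L
      }
    }
  }
  hyb <- character(n)
  for (i in seq_len(n)) {
    el <- mol$element[i]
    hyb[i] <- if (el == "Na") "other"
      else if (n_triple[i] >= 1L || n_double[i] >= 2L) "sp"
      else if (n_double[i] >= 1L || aromatic_atom[i]) "sp2"
      else "sp3"
  }

  # conjugation: a bond is conjugated when it sits between two pi-capable
  # centres and the local system extends beyond the bond itself
  has_mult <- n_multiple > 0L | aromatic_atom
  has_lp <- mol$element %in% c("N", "O", "S") & mol$charge <= 0
  conjugated_bond <- logical(nb)
  if (nb) {
    for (r in seq_len(nb)) {
      if (aromatic_bond[r]) { conjugated_bond[r] <- TRUE; next }
      a1 <- bonds$a1[r]; a2 <- bonds$a2[r]
      if (bonds$order[r] >= 2) {
        # neighbouring atom (through another bond) must extend the pi system
        others <- c(setdiff(adj[[a1]], a2), setdiff(adj[[a2]], a1))
        conjugated_bond[r] <- any(has_mult[others] | has_lp[others])
      } else {
        cap1 <- has_mult[a1] || has_lp[a1]
        cap2 <- has_mult[a2] || has_lp[a2]
        conjugated_bond[r] <- cap1 && cap2 && (has_mult[a1] || has_mult[a2])
      }
    }
  }

  # lone-pair heteroatoms drawn into a conjugated system become sp2
  if (nb) {
    for (r in which(conjugated_bond)) {
      for (a in c(bonds$a1[r], bonds$a2[r])) {
        if (has_lp[a] && hyb[a] == "sp3") hyb[a] <- "sp2"
      }
    }
  }

  mol$n <- n
  mol$adj <- adj
  mol$degree <- degree
  mol$in_ring_atom <- in_ring_atom
  mol$in_ring_bond <- in_ring_bond
  mol$ring_size_atom <- ring_size_atom
  mol$aromatic_atom <- aromatic_atom
  mol$aromatic_bond <- aromatic_bond
  mol$explicit_valence <- explicit_valence
  mol$implicit_h <- implicit_h
  mol$hybridization <- hyb
  mol$conjugated_bond <- conjugated_bond
  mol$radical_electrons <- integer(n)  # radicals unsupported in this parse
  class(mol) <- "og_mol"
  mol
}
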