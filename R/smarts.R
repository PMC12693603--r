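# A small SMARTS substructure matcher.
#
# Matching with atom indices is required by the fragment-attribution code;
# the toolkit bindings available to R only return match counts, so the
# subset of SMARTS needed for functional-group perception is implemented
# here directly against the internal molecule model.
#
# Supported grammar:
#   * bare atoms C N O S P F Cl Br (aliphatic), c n o s p (aromatic), `*`
#   * bracket atoms [...] with primitives: element symbols (incl. Na),
#     `#n` atomic number, `a`/`A`, `*`, `Xn` (total connections incl. H),
#     `Dn` (heavy degree), `Hn` (total hydrogen count), `R`/`R0`, `rn`
#     (ring size), `+`/`-` charges, and `!` negation; combined with
#     `&`/juxtaposition (AND), `,` (OR) and `;` (low-precedence AND)
#   * bonds `-` `=` `#` `:` `~` and the single-or-aromatic default
#   * branches `(...)` and ring-closure digits 1-9
# Recursive SMARTS, stereo, `@`, maps and wildcard ring bonds are not
# supported; patterns shipped with the package stay inside this subset.

.SMARTS_TWO_LETTER <- c("Cl", "Br", "Na")

# ---- parsing ---------------------------------------------------------------

.parse_atom_primitives <- function(expr) {
  # returns list of OR-alternatives; each alternative = list of primitives
  # low-precedence AND over ';' parts, each part an OR over ',' alternatives
  # of '&'-joined primitive runs. Normalized to a single OR-of-ANDs by
  # distributing the ';' conjunction.
  parts <- strsplit(expr, ";", fixed = TRUE)[[1]]
  per_part <- lapply(parts, function(p) {
    alts <- strsplit(p, ",", fixed = TRUE)[[1]]
    lapply(alts, .parse_primitive_run)
  })
  # cartesian product across parts (each part contributes one alternative)
  combos <- Reduce(function(acc, alts) {
    out <- list()
    for (a in acc) for (b in alts) out[[length(out) + 1L]] <- c(a, b)
    out
  }, per_part[-1], init = per_part[[1]])
  combos
}

.parse_primitive_run <- function(run) {
  prims <- list()
  i <- 1L
  nch <- nchar(run)
  while (i <= nch) {
    neg <- FALSE
    ch <- substr(run, i, i)
    if (ch == "&") { i <- i + 1L; next }
    if (ch == "!") { neg <- TRUE; i <- i + 1L; ch <- substr(run, i, i) }
    two <- substr(run, i, i + 1L)
    take_num <- function(j) {
      num <- ""
      while (j <= nch && grepl("^[0-9]$", substr(run, j, j))) {
        num <- paste0(num, substr(run, j, j)); j <- j + 1L
      }
      list(num = num, j = j)
    }
    if (two %in% .SMARTS_TWO_LETTER) {
      prims[[length(prims) + 1L]] <- list(type = "sym", sym = two, arom = FALSE, neg = neg)
      i <- i + 2L
    } else if (ch == "#") {
      tk <- take_num(i + 1L)
      prims[[length(prims) + 1L]] <- list(type = "elem", z = as.integer(tk$num), neg = neg)
      i <- tk$j
    } else if (ch %in% c("C", "N", "O", "S", "P", "F", "B", "I")) {
      prims[[length(prims) + 1L]] <- list(type = "sym", sym = ch, arom = FALSE, neg = neg)
      i <- i + 1L
    } else if (ch %in% c("c", "n", "o", "s", "p")) {
      prims[[length(prims) + 1L]] <- list(type = "sym", sym = toupper(ch), arom = TRUE, neg = neg)
      i <- i + 1L
    } else if (ch == "a") {
      prims[[length(prims) + 1L]] <- list(type = "arom", val = TRUE, neg = neg); i <- i + 1L
    } else if (ch == "A") {
      prims[[length(prims) + 1L]] <- list(type = "arom", val = FALSE, neg = neg); i <- i + 1L
    } else if (ch == "*") {
      prims[[length(prims) + 1L]] <- list(type = "any", neg = neg); i <- i + 1L
    } else if (ch %in% c("X", "D", "H", "r", "R")) {
      tk <- take_num(i + 1L)
      n <- if (nzchar(tk$num)) as.integer(tk$num) else NA_integer_
      prims[[length(prims) + 1L]] <- list(type = ch, n = n, neg = neg)
      i <- tk$j
    } else if (ch %in% c("+", "-")) {
      tk <- take_num(i + 1L)
      mag <- if (nzchar(tk$num)) as.integer(tk$num) else 1L
      prims[[length(prims) + 1L]] <- list(type = "charge",
                                          q = if (ch == "+") mag else -mag, neg = neg)
      i <- tk$j
    } else {
      stop(sprintf("unsupported SMARTS atom primitive '%s' in '%s'", ch, run),
           call. = FALSE)
    }
  }
  prims
}

#' Parse a SMARTS pattern
#'
#' Parses a pattern from the supported SMARTS subset into a query graph.
#' Mainly useful for pre-compiling patterns that are matched many times.
#'
#' @param smarts A SMARTS string.
#' @return An object of class `smarts_query`.
#' @export
parse_smarts <- function(smarts) {
  stopifnot(is.character(smarts), length(smarts) == 1, nzchar(smarts))
  atoms <- list()
  edges <- data.frame(a = integer(0), b = integer(0), bond = character(0))
  stack <- integer(0)
  prev <- 0L
  pending_bond <- NA_character_
  ring_open <- list()
  i <- 1L
  nch <- nchar(smarts)
  add_atom <- function(expr) {
    atoms[[length(atoms) + 1L]] <<- .parse_atom_primitives(expr)
    idx <- length(atoms)
    if (prev > 0L) {
      edges[nrow(edges) + 1L, ] <<- list(prev, idx,
                                         ifelse(is.na(pending_bond), "default", pending_bond))
    }
    prev <<- idx
    pending_bond <<- NA_character_
  }
  while (i <= nch) {
    ch <- substr(smarts, i, i)
    two <- substr(smarts, i, i + 1L)
    if (ch == "[") {
      j <- i
      depth <- 0L
      repeat {
        cj <- substr(smarts, j, j)
        if (cj == "[") depth <- depth + 1L
        if (cj == "]") { depth <- depth - 1L; if (depth == 0L) break }
        j <- j + 1L
        if (j > nch) stop("unbalanced '[' in SMARTS", call. = FALSE)
      }
      add_atom(substr(smarts, i + 1L, j - 1L))
      i <- j + 1L
    } else if (two %in% c("Cl", "Br")) {
      add_atom(two); i <- i + 2L
    } else if (ch %in% c("C", "N", "O", "S", "P", "F", "I",
                         "c", "n", "o", "s", "p", "*", "a", "A")) {
      add_atom(ch); i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "~")) {
      pending_bond <- switch(ch, "-" = "single", "=" = "double", "#" = "triple",
                             ":" = "aromatic", "~" = "any")
      i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMARTS", call. = FALSE)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("^[1-9]$", ch)) {
      key <- ch
      if (!is.null(ring_open[[key]])) {
        op <- ring_open[[key]]
        bond <- if (!is.na(pending_bond)) pending_bond
          else if (!is.na(op$bond)) op$bond else "default"
        edges[nrow(edges) + 1L, ] <- list(op$atom, prev, bond)
        ring_open[[key]] <- NULL
      } else {
        ring_open[[key]] <- list(atom = prev, bond = pending_bond)
      }
      pending_bond <- NA_character_
      i <- i + 1L
    } else {
      stop(sprintf("unsupported SMARTS token '%s' in '%s'", ch, smarts),
           call. = FALSE)
    }
  }
  if (length(ring_open)) stop("unclosed ring bond in SMARTS", call. = FALSE)
  if (length(stack)) stop("unbalanced '(' in SMARTS", call. = FALSE)
  structure(list(smarts = smarts, atoms = atoms, edges = edges),
            class = "smarts_query")
}

# ---- evaluation ------------------------------------------------------------

.prim_ok <- function(p, mol, i) {
  tot_h <- mol$explicit_h[i] + mol$implicit_h[i]
  val <- switch(p$type,
    sym = mol$element[i] == p$sym &&
      (is.na(p$arom) || mol$aromatic_atom[i] == p$arom),
    elem = !is.null(ATOMIC_NUMBERS[[mol$element[i]]]) &&
      ATOMIC_NUMBERS[[mol$element[i]]] == p$z,
    arom = mol$aromatic_atom[i] == p$val,
    any = TRUE,
    X = (mol$degree[i] + tot_h) == p$n,
    D = mol$degree[i] == (if (is.na(p$n)) 1L else p$n),
    H = tot_h == (if (is.na(p$n)) 1L else p$n),
    R = if (is.na(p$n)) mol$in_ring_atom[i] else
          (if (p$n == 0L) !mol$in_ring_atom[i] else mol$in_ring_atom[i]),
    r = if (is.na(p$n)) mol$in_ring_atom[i] else
          (p$n >= 3L && p$n <= 6L && mol$ring_size_atom[i, p$n - 2L]),
    charge = mol$charge[i] == p$q,
    stop("unknown primitive")
  )
  if (p$neg) !val else val
}

.atom_expr_ok <- function(alts, mol, i) {
  for (alt in alts) {
    if (all(vapply(alt, .prim_ok, logical(1), mol = mol, i = i))) return(TRUE)
  }
  FALSE
}

.bond_ok <- function(spec, mol, bond_row) {
  o <- mol$bonds$order[bond_row]
  arom <- mol$aromatic_bond[bond_row]
  switch(spec,
    default = (o == 1 && !arom) || arom,
    single = o == 1 && !arom,
    double = o == 2 && !arom,
    triple = o == 3,
    aromatic = arom,
    any = TRUE)
}

#' Match a SMARTS pattern against a molecule
#'
#' Backtracking subgraph matching of a (restricted-subset) SMARTS query.
#'
#' @param pattern A SMARTS string or a [parse_smarts()] query.
#' @param mol A SMILES string or parsed molecule.
#' @param unique_sets If `TRUE` (default) matches mapping to the same atom
#'   set are collapsed to one.
#' @return List of integer vectors; each vector maps query atoms to molecule
#'   atom indices (empty list when there is no match).
#' @examples
#' smarts_match("[CX3](=O)[OX2][#6]", "CCOC(C)=O")  # ester in ethyl acetate
#' @export
smarts_match <- function(pattern, mol, unique_sets = TRUE) {
  q <- if (inherits(pattern, "smarts_query")) pattern else parse_smarts(pattern)
  mol <- .as_mol(mol)
  np <- length(q$atoms)
  if (np == 0L) return(list())
  # bond lookup for the molecule
  key <- .bond_key(mol$bonds$a1, mol$bonds$a2)
  bmap <- stats::setNames(seq_len(nrow(mol$bonds)), key)
  # query adjacency: for each query atom, edges touching it
  qadj <- vector("list", np)
  for (r in seq_len(nrow(q$edges))) {
    a <- q$edges$a[r]; b <- q$edges$b[r]
    qadj[[a]] <- c(qadj[[a]], r); qadj[[b]] <- c(qadj[[b]], r)
  }
  # candidate atoms per query atom
  cand <- lapply(seq_len(np), function(k) {
    which(vapply(seq_len(mol$n), function(i) .atom_expr_ok(q$atoms[[k]], mol, i),
                 logical(1)))
  })
  matches <- list()
  assign <- integer(np)
  used <- logical(mol$n)
  bt <- function(k) {
    if (k > np) { matches[[length(matches) + 1L]] <<- assign; return(invisible()) }
    for (i in cand[[k]]) {
      if (used[i]) next
      ok <- TRUE
      for (er in qadj[[k]]) {
        a <- q$edges$a[er]; b <- q$edges$b[er]
        other <- if (a == k) b else a
        if (other < k) {   # bond to an already-assigned query atom
          j <- assign[other]
          br <- unname(bmap[.bond_key(i, j)])
          if (is.na(br) || !.bond_ok(q$edges$bond[er], mol, br)) { ok <- FALSE; break }
        }
      }
      if (ok) {
        assign[k] <<- i; used[i] <<- TRUE
        bt(k + 1L)
        used[i] <<- FALSE
      }
    }
  }
  bt(1L)
  if (unique_sets && length(matches)) {
    keys <- vapply(matches, function(m) paste(sort(m), collapse = "-"), character(1))
    matches <- matches[!duplicated(keys)]
  }
  matches
}

#' Does a molecule contain a SMARTS pattern?
#'
#' @inheritParams smarts_match
#' @return Logical scalar.
#' @export
smarts_has_match <- function(pattern, mol) {
  length(smarts_match(pattern, mol)) > 0
}

#' Functional-group SMARTS library
#'
#' The curated library of functional-group patterns used for fragment
#' annotation, shipped as a plain-text table (`name`, `smarts`, `priority`).
#' Lower priority numbers are more specific groups and win when a fragment
#' overlaps several matches.
#'
#' @return Data frame with columns `name`, `smarts`, `priority`.
#' @export
smarts_library <- function() {
  path <- system.file("extdata", "smarts_library.tsv", package = "odorgraph")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "smarts_library.tsv")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
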