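# Synthetic study data: molecules from a fragment grammar, planted
# structure-odor labels, and a descriptor table with realistic pathologies
# (heterogeneous scales, tiered missingness, outliers). This makes the whole
# pipeline testable without any external dataset: every functional group the
# label rules and the fragment annotation care about is instantiated by the
# grammar, and label signal strength is controlled by per-rule activation and
# background probabilities.

#' Default planted structure-odor rules
#'
#' One rule per odor label: a functional-group SMARTS, the probability that a
#' molecule matching it carries the label (activation), and the probability
#' for non-matching molecules (background). The chemistry follows classical
#' structure-odor associations (esters for fruity, aldehydes for green,
#' alcohols for sweet, ketones for floral, sulfur groups for woody-smoky,
#' aromatic rings for herbal); the probabilities are chosen so realized label
#' frequencies under the default grammar span roughly 13-31%.
#'
#' @return Named list; each element has `smarts`, `activation`, `background`.
#' @export
default_rule_table <- function() {
  list(
    fruity = list(smarts = "[CX3](=O)[OX2][#6]", activation = 0.90, background = 0.05),
    green  = list(smarts = "[CX3H1]=O",          activation = 0.85, background = 0.06),
    sweet  = list(smarts = "[OX2H][CX4]",        activation = 0.85, background = 0.06),
    floral = list(smarts = "[#6][CX3](=O)[#6]",  activation = 0.80, background = 0.05),
    woody  = list(smarts = "[SX2]",              activation = 0.90, background = 0.04),
    herbal = list(smarts = "c1ccccc1",           activation = 0.50, background = 0.04)
  )
}

#' Configuration for synthetic molecule and label generation
#'
#' @param n_molecules Number of molecules to generate (>= 1).
#' @param seed Integer seed; the single source of randomness for generation
#'   and label planting.
#' @param label_names Labels, in column order. Defaults to the six odor
#'   categories the package is organized around.
#' @param rule_table Named list of planted rules (see [default_rule_table()]);
#'   must cover `label_names` and satisfy activation > background.
#' @param target_frequency_range Fraction pair the realized label frequencies
#'   are expected to span under the default grammar (informational; reported
#'   by [plant_labels()]).
#' @return An object of class `generation_config`.
#' @export
generation_config <- function(n_molecules,
                              seed = 1L,
                              label_names = names(default_rule_table()),
                              rule_table = default_rule_table(),
                              target_frequency_range = c(0.129, 0.309)) {
  stopifnot(n_molecules >= 1, length(label_names) >= 2)
  if (!all(label_names %in% names(rule_table))) {
    stop("rule_table must contain a rule for every label", call. = FALSE)
  }
  for (nm in label_names) {
    r <- rule_table[[nm]]
    if (!(r$activation > r$background)) {
      stop(sprintf("rule '%s': activation probability must exceed background", nm),
           call. = FALSE)
    }
  }
  structure(list(n_molecules = as.integer(n_molecules), seed = as.integer(seed),
                 label_names = label_names, rule_table = rule_table[label_names],
                 target_frequency_range = target_frequency_range),
            class = "generation_config")
}

#' Default fragment grammar
#'
#' Scaffolds (SMILES token chains with decorable positions) and decoration
#' branches with sampling weights. Decorations instantiate every functional
#' group used by the planted rules and the SMARTS library; sodium appears only
#' as a rare terminal alkoxide so the 9-way element one-hot is exercised
#' without exotic valences.
#'
#' @return List with `scaffolds`, `decorations`, `decoration_weights`,
#'   `max_decorations`.
#' @export
default_grammar <- function() {
  list(
    scaffolds = list(
      chain3      = list(weight = 0.10),
      chain4      = list(weight = 0.10),
      chain5      = list(weight = 0.09),
      chain6      = list(weight = 0.08),
      chain7      = list(weight = 0.05),
      chain8      = list(weight = 0.03),
      benzene     = list(weight = 0.20),
      cyclohexane = list(weight = 0.12),
      cyclopentane= list(weight = 0.10),
      furan       = list(weight = 0.07),
      thiophene   = list(weight = 0.06)
    ),
    decorations = c(
      methyl        = "(C)",
      ester_acyl    = "(C(=O)OC)",
      ester_oxy     = "(OC(C)=O)",
      aldehyde      = "(C=O)",
      alcohol       = "(O)",
      ketone        = "(C(C)=O)",
      thiol         = "(S)",
      thioether     = "(SC)",
      ether         = "(OC)",
      amine         = "(N)",
      acid          = "(C(=O)O)",
      nitrile       = "(C#N)",
      fluoro        = "(F)",
      chloro        = "(Cl)",
      bromo         = "(Br)",
      phosphine     = "(P)",
      sodium_alkoxide = "(O[Na])"
    ),
    decoration_weights = c(
      methyl = 0.14, ester_acyl = 0.12, ester_oxy = 0.08, aldehyde = 0.13,
      alcohol = 0.16, ketone = 0.10, thiol = 0.05, thioether = 0.03,
      ether = 0.04, amine = 0.03, acid = 0.03, nitrile = 0.02,
      fluoro = 0.02, chloro = 0.02, bromo = 0.01, phosphine = 0.01,
      sodium_alkoxide = 0.01
    ),
    max_decorations = 3L
  )
}

# scaffold -> list(tokens = atom tokens, decorable = indices, aromatic = lgl)
.scaffold_tokens <- function(name) {
  chain <- function(k) list(tokens = rep("C", k), decorable = seq_len(k),
                            aromatic = rep(FALSE, k))
  switch(name,
    chain3 = chain(3), chain4 = chain(4), chain5 = chain(5),
    chain6 = chain(6), chain7 = chain(7), chain8 = chain(8),
    benzene = list(tokens = c("c1", "c", "c", "c", "c", "c1"),
                   decorable = 1:6, aromatic = rep(TRUE, 6)),
    cyclohexane = list(tokens = c("C1", "C", "C", "C", "C", "C1"),
                       decorable = 1:6, aromatic = rep(FALSE, 6)),
    cyclopentane = list(tokens = c("C1", "C", "C", "C", "C1"),
                        decorable = 1:5, aromatic = rep(FALSE, 5)),
    furan = list(tokens = c("c1", "c", "c", "o", "c1"),
                 decorable = c(1:3, 5), aromatic = rep(TRUE, 5)),
    thiophene = list(tokens = c("c1", "c", "c", "s", "c1"),
                     decorable = c(1:3, 5), aromatic = rep(TRUE, 5)),
    stop(sprintf("unknown scaffold '%s'", name), call. = FALSE)
  )
}

#' Generate synthetic molecules
#'
#' Assembles molecules by sampling a scaffold and splicing decoration
#' branches at open positions. Every output is a valid SMILES by
#' construction (the grammar only produces standard valences) and all heavy
#' atoms stay inside the supported nine-element vocabulary.
#'
#' @param config A [generation_config()].
#' @param grammar Fragment grammar (see [default_grammar()]); replace it to
#'   restrict generation, e.g. a single undecorated scaffold.
#' @return Character vector of `n_molecules` SMILES.
#' @export
generate_molecules <- function(config, grammar = default_grammar()) {
  stopifnot(inherits(config, "generation_config"))
  rng <- .local_rng(config$seed)
  scaf_names <- names(grammar$scaffolds)
  scaf_w <- vapply(grammar$scaffolds, function(s) s$weight, numeric(1))
  dec_names <- names(grammar$decorations)
  dec_w <- if (length(dec_names)) grammar$decoration_weights[dec_names] else numeric(0)
  vapply(seq_len(config$n_molecules), function(i) {
    sc <- .scaffold_tokens(sample(scaf_names, 1, prob = scaf_w))
    tokens <- sc$tokens
    if (length(dec_names) && grammar$max_decorations > 0) {
      n_dec <- sample(0:grammar$max_decorations, 1,
                      prob = c(0.15, 0.35, 0.30, 0.20)[seq_len(grammar$max_decorations + 1L)])
      budget <- ifelse(sc$aromatic, 1L, 2L)  # open valences per position
      budget[-sc$decorable] <- 0L
      # chain terminals have three open hydrogens, interiors two
      if (!any(sc$aromatic) && !grepl("1", tokens[1], fixed = TRUE)) {
        budget[c(1, length(tokens))] <- 3L
      }
      for (d in seq_len(n_dec)) {
        open <- which(budget > 0)
        if (!length(open)) break
        pos <- if (length(open) == 1) open else sample(open, 1)
        dec <- sample(dec_names, 1, prob = dec_w)
        tokens[pos] <- paste0(tokens[pos], grammar$decorations[[dec]])
        budget[pos] <- budget[pos] - 1L
      }
    }
    paste(tokens, collapse = "")
  }, character(1))
}

#' Plant multi-label odor annotations on molecules
#'
#' Applies the configured structure-odor rules: a molecule matching rule k's
#' SMARTS receives label k with the rule's activation probability, otherwise
#' with its background probability.
#'
#' @param smiles Character vector of valid SMILES.
#' @param config A [generation_config()] (provides rules, labels and seed).
#' @return Integer 0/1 matrix (`label_matrix`), one column per label, with
#'   attributes `frequencies` (realized per-label positive rates) and
#'   `match_fraction` (per-rule SMARTS match rates).
#' @export
plant_labels <- function(smiles, config) {
  stopifnot(inherits(config, "generation_config"))
  mols <- tryCatch(parse_mols(smiles), error = function(e) {
    stop(sprintf("plant_labels: %s", conditionMessage(e)), call. = FALSE)
  })
  rng <- .local_rng(config$seed + 10007L)
  K <- length(config$label_names)
  n <- length(smiles)
  y <- matrix(0L, n, K, dimnames = list(NULL, config$label_names))
  match_frac <- stats::setNames(numeric(K), config$label_names)
  for (k in seq_len(K)) {
    rule <- config$rule_table[[config$label_names[k]]]
    q <- parse_smarts(rule$smarts)
    hit <- vapply(mols, function(m) length(smarts_match(q, m)) > 0, logical(1))
    match_frac[k] <- mean(hit)
    p <- ifelse(hit, rule$activation, rule$background)
    y[, k] <- as.integer(stats::runif(n) < p)
  }
  structure(y, frequencies = colMeans(y), match_fraction = match_frac,
            class = c("label_matrix", class(y)))
}

#' Realized per-label frequencies of a label matrix
#' @param labels A 0/1 label matrix.
#' @return Named numeric vector of per-label positive rates.
#' @export
label_frequencies <- function(labels) colMeans(unclass(labels))

#' Noise specification for the synthetic descriptor table
#'
#' @param n_descriptors Total number of descriptor columns (>= 10).
#' @param missing_tier_fractions Fractions of columns drawn to have low
#'   (<5%), moderate (5-30%) and high (>30%) missing rates; must sum to <= 1.
#' @param outlier_rate Fraction of (non-structural) cells replaced by extreme
#'   values.
#' @param scale_range Column scale multipliers are drawn log-uniformly from
#'   this range; the default spans eight orders of magnitude, mimicking the
#'   extreme scale heterogeneity of commercial descriptor panels.
#' @return An object of class `descriptor_noise_spec`.
#' @export
descriptor_noise_spec <- function(n_descriptors = 120L,
                                  missing_tier_fractions = c(0.10, 0.08, 0.05),
                                  outlier_rate = 0.01,
                                  scale_range = c(1e-2, 1e6)) {
  stopifnot(n_descriptors >= 10, length(missing_tier_fractions) == 3,
            sum(missing_tier_fractions) <= 1, outlier_rate >= 0,
            length(scale_range) == 2, scale_range[2] > scale_range[1])
  structure(list(n_descriptors = as.integer(n_descriptors),
                 missing_tier_fractions = missing_tier_fractions,
                 outlier_rate = outlier_rate, scale_range = scale_range),
            class = "descriptor_noise_spec")
}

#' Synthesize a descriptor table for a molecule set
#'
#' Emulates a wide molecular-descriptor panel: a block of structural columns
#' that are deterministic functions of the molecule (heavy-atom, ring,
#' heteroatom and aromatic counts, total atomic number, plus one 0/1
#' rule-match indicator per planted rule -- the recoverable signal), padded
#' with correlated and independent noise columns, then degraded with
#' column-wise scale multipliers, tiered missingness and injected outliers.
#' Structural and rule-match columns are never degraded, so they remain
#' deterministic functions of structure and the planted signal stays
#' identifiable.
#'
#' @param smiles Character vector of valid SMILES.
#' @param spec A [descriptor_noise_spec()].
#' @param seed Integer seed for the stochastic noise components.
#' @param rule_table Rules for the match-indicator columns
#'   (default [default_rule_table()]).
#' @return Numeric matrix (molecules x descriptors) with named columns,
#'   possibly containing `NA`.
#' @export
synth_descriptor_table <- function(smiles, spec = descriptor_noise_spec(),
                                   seed = 1L, rule_table = default_rule_table()) {
  stopifnot(inherits(spec, "descriptor_noise_spec"))
  mols <- parse_mols(smiles)
  n <- length(mols)
  rng <- .local_rng(seed + 20011L)

  heavy <- vapply(mols, function(m) m$n, numeric(1))
  ringc <- vapply(mols, function(m) sum(m$in_ring_atom), numeric(1))
  hetero <- vapply(mols, function(m) sum(!m$element %in% c("C", "H")), numeric(1))
  aromc <- vapply(mols, function(m) sum(m$aromatic_atom), numeric(1))
  ztot <- vapply(mols, function(m) sum(ATOMIC_NUMBERS[m$element]), numeric(1))
  struct <- cbind(heavy_atom_count = heavy, ring_atom_count = ringc,
                  heteroatom_count = hetero, aromatic_atom_count = aromc,
                  total_atomic_number = ztot)
  rules <- lapply(rule_table, function(r) parse_smarts(r$smarts))
  match_cols <- vapply(seq_along(rules), function(k) {
    q <- rules[[k]]
    vapply(mols, function(m) as.numeric(length(smarts_match(q, m)) > 0), numeric(1))
  }, numeric(n))
  if (is.null(dim(match_cols))) match_cols <- matrix(match_cols, nrow = n)
  colnames(match_cols) <- paste0("rule_match_", names(rule_table))

  n_struct <- ncol(struct) + ncol(match_cols)
  n_noise <- max(0L, spec$n_descriptors - n_struct)
  noise <- matrix(stats::rnorm(n * n_noise), n, n_noise)
  if (n_noise >= 10) {
    # ~10% of noise columns are near-duplicates of another, exercising the
    # correlation filter downstream
    dup <- sample(seq_len(n_noise), max(1L, round(0.1 * n_noise)))
    src <- sample(setdiff(seq_len(n_noise), dup), length(dup), replace = TRUE)
    noise[, dup] <- noise[, src] + stats::rnorm(n * length(dup), sd = 0.01)
  }
  colnames(noise) <- sprintf("noise_%03d", seq_len(n_noise))
  x <- cbind(struct, match_cols, noise)

  # structural and rule-indicator columns stay clean deterministic
  # functions of structure; only noise columns are degraded
  degradable <- which(grepl("^noise_", colnames(x)))

  # heterogeneous scales
  lr <- log10(spec$scale_range)
  scale_mult <- 10^stats::runif(length(degradable), lr[1], lr[2])
  x[, degradable] <- sweep(x[, degradable, drop = FALSE], 2, scale_mult, `*`)

  # outliers before missingness so NAs stay NA
  if (spec$outlier_rate > 0 && length(degradable)) {
    sub <- x[, degradable, drop = FALSE]
    cells <- which(stats::runif(length(sub)) < spec$outlier_rate)
    if (length(cells)) {
      colsd <- apply(sub, 2, stats::sd)
      col_of <- ((cells - 1L) %/% n) + 1L
      sub[cells] <- sub[cells] +
        sample(c(-1, 1), length(cells), replace = TRUE) *
          (10 + stats::rexp(length(cells), 0.5)) * pmax(colsd[col_of], 1e-8)
      x[, degradable] <- sub
    }
  }

  # tiered missingness over degradable columns
  tf <- spec$missing_tier_fractions
  tier <- sample(c("low", "mid", "high", "none"), length(degradable),
                 replace = TRUE, prob = c(tf, 1 - sum(tf)))
  for (j in seq_along(degradable)) {
    rate <- switch(tier[j],
                   low = stats::runif(1, 0.005, 0.045),
                   mid = stats::runif(1, 0.06, 0.29),
                   high = stats::runif(1, 0.32, 0.60),
                   none = 0)
    if (rate > 0) {
      miss <- stats::runif(n) < rate
      x[miss, degradable[j]] <- NA
    }
  }
  rownames(x) <- sprintf("mol_%05d", seq_len(n))
  x
}

#' Write the synthetic study files
#'
#' Writes `molecules.csv` (`smiles` plus one 0/1 column per label) and, when
#' a descriptor table is given, a row-aligned `descriptors.csv`.
#'
#' @param smiles SMILES vector.
#' @param labels Label matrix from [plant_labels()].
#' @param dir Output directory (created if needed).
#' @param descriptors Optional descriptor matrix from
#'   [synth_descriptor_table()].
#' @return Invisibly, the paths written.
#' @export
write_synthetic_csv <- function(smiles, labels, dir, descriptors = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mpath <- file.path(dir, "molecules.csv")
  utils::write.csv(data.frame(smiles = smiles, unclass(labels),
                              check.names = FALSE),
                   mpath, row.names = FALSE)
  paths <- mpath
  if (!is.null(descriptors)) {
    dpath <- file.path(dir, "descriptors.csv")
    utils::write.csv(as.data.frame(descriptors), dpath, row.names = FALSE)
    paths <- c(paths, dpath)
  }
  invisible(paths)
}

# All stochastic operations seed R's generator through this helper so a
# single integer seed reproduces a whole run.
.local_rng <- function(seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  invisible(NULL)
}
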