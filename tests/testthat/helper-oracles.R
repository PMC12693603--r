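# Independent oracles and shared fixtures for the test suite.
#
# The rdkit oracle runs in a python subprocess and returns per-atom/bond
# chemistry for a batch of SMILES; it is independent of the package's own
# perception code (which is built on the OpenBabel connection table).

rdkit_available <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) {
      cached <<- suppressWarnings(
        system2("python", c("-c", shQuote("import rdkit")),
                stdout = FALSE, stderr = FALSE)) == 0
    }
    cached
  }
})

# batched rdkit oracle: list per molecule with atom-level vectors and
# SMARTS match presence for the supplied patterns
rdkit_oracle <- function(smiles, smarts = character(0)) {
  script <- '
import sys, json
from rdkit import Chem
data = json.load(sys.stdin)
out = []
for smi in data["smiles"]:
    m = Chem.MolFromSmiles(smi)
    if m is None:
        out.append(None); continue
    rec = {
        "symbol": [a.GetSymbol() for a in m.GetAtoms()],
        "z": [a.GetAtomicNum() for a in m.GetAtoms()],
        "charge": [a.GetFormalCharge() for a in m.GetAtoms()],
        "degree": [a.GetDegree() for a in m.GetAtoms()],
        "aromatic": [int(a.GetIsAromatic()) for a in m.GetAtoms()],
        "total_h": [a.GetTotalNumHs() for a in m.GetAtoms()],
        "in_ring": [int(a.IsInRing()) for a in m.GetAtoms()],
        "ring5": [int(a.IsInRingSize(5)) for a in m.GetAtoms()],
        "ring6": [int(a.IsInRingSize(6)) for a in m.GetAtoms()],
        "hyb": [str(a.GetHybridization()) for a in m.GetAtoms()],
        "n_bonds": m.GetNumBonds(),
        "matches": {}
    }
    for s in data["smarts"]:
        q = Chem.MolFromSmarts(s)
        rec["matches"][s] = int(m.HasSubstructMatch(q))
    out.append(rec)
json.dump(out, sys.stdout)
'
  payload <- jsonlite::toJSON(list(smiles = smiles, smarts = smarts))
  res <- system2("python", c("-c", shQuote(script)), input = as.character(payload),
                 stdout = TRUE, stderr = FALSE)
  jsonlite::fromJSON(paste(res, collapse = ""), simplifyDataFrame = FALSE)
}

# shared synthetic fixture, generated once per test run
shared_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generation_config(150, seed = 20260921)
      smi <- generate_molecules(cfg)
      cache <<- list(config = cfg, smiles = smi,
                     labels = plant_labels(smi, cfg),
                     graphs = smiles_to_graphs(smi))
    }
    cache
  }
})

# brute-force F1 used as the independent oracle for threshold optimization
brute_force_f1 <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}
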