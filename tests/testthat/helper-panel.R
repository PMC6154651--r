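# Shared fixtures: parse a named SMILES panel once per file that needs it.

parse_panel <- function(smis) {
  p <- parse_structures(paste(smis, names(smis), collapse = "\n"), "smiles")
  stopifnot(nrow(p$rejects) == 0L)
  stats::setNames(p$molecules, names(smis))
}

# hand-counted descriptor panel: element counts verified by drawing the
# structures; HBD/HBA/rotatable/ring values counted under the package's
# stated conventions (Lipinski HBD = O-H + N-H hydrogens; HBA = N + O;
# rotatable = acyclic single bonds between non-terminal heavy atoms minus
# amide C-N; rings = SSSR)
descriptor_panel <- function() {
  data.frame(
    name = c("ethanol", "benzoic", "glycine", "naphthalene", "cyclohexane",
             "stearic", "malonic", "glycidic", "acid2a", "oleanolic",
             "pyridine_noxide", "acetamide", "nicotinic", "furoic",
             "betaine_cation", "adamantane_acid", "gluconic"),
    smiles = c("CCO", "OC(=O)c1ccccc1", "NCC(=O)O", "c1ccc2ccccc2c1",
               "C1CCCCC1", "CCCCCCCCCCCCCCCCCC(=O)O", "OC(=O)CC(=O)O",
               "OC(=O)C1CO1", "OC(=O)c1cc(-c2ccccc2)no1",
               "CC1(C)CCC2(CCC3(C)C(=CCC4C5(C)CCC(O)C(C)(C)C5CCC34C)C2C1)C(O)=O",
               "OC(=O)c1ccc[n+]([O-])c1", "CC(N)=O", "OC(=O)c1cccnc1",
               "OC(=O)c1ccco1", "OC(=O)C[N+](C)(C)C",
               "OC(=O)C12CC3CC(C1)CC(C2)C3", "OCC(O)C(O)C(O)C(O)C(=O)O"),
    formula = c("C2H6O", "C7H6O2", "C2H5NO2", "C10H8", "C6H12", "C18H36O2",
                "C3H4O4", "C3H4O3", "C10H7NO3", "C30H48O3", "C6H5NO3",
                "C2H5NO", "C6H5NO2", "C5H4O3", "C5H12NO2", "C11H16O2",
                "C6H12O7"),
    hbd = c(1L, 1L, 3L, 0L, 0L, 1L, 2L, 1L, 1L, 2L, 1L, 2L, 1L, 1L, 1L, 1L, 6L),
    hba = c(1L, 2L, 3L, 0L, 0L, 2L, 4L, 3L, 4L, 3L, 4L, 2L, 3L, 3L, 3L, 2L, 7L),
    rot = c(0L, 1L, 1L, 0L, 0L, 16L, 2L, 1L, 2L, 1L, 1L, 0L, 1L, 1L, 2L, 1L, 5L),
    rings = c(0L, 1L, 0L, 2L, 1L, 0L, 0L, 1L, 2L, 5L, 1L, 0L, 1L, 1L, 0L, 3L, 0L),
    arom = c(0L, 1L, 0L, 2L, 0L, 0L, 0L, 0L, 2L, 0L, 1L, 0L, 1L, 1L, 0L, 0L, 0L),
    stringsAsFactors = FALSE
  )
}

# reorder the atoms of a Molecule by `perm` (an index permutation), keeping
# the graph identical; used for renumbering-invariance checks
permute_molecule <- function(m, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  m2 <- m
  m2$atoms <- m$atoms[perm, , drop = FALSE]
  rownames(m2$atoms) <- NULL
  m2$bonds$a1 <- inv[m$bonds$a1]
  m2$bonds$a2 <- inv[m$bonds$a2]
  m2
}

# fingerprint objects built directly from bit sets (for metric-space tests)
raw_fingerprint <- function(bits, spec = fingerprint_spec()) {
  structure(sort(unique(as.integer(bits))), id = "raw", spec = spec,
            class = "fingerprint")
}
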