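# Brute-force graph oracles for the structural alerts, written directly
# against the Molecule atom/bond tables.  These never touch the SMARTS
# machinery, so agreement with apply_alerts() is a genuine dual-route check.

.ng <- function(m, a) c(m$bonds$a2[m$bonds$a1 == a], m$bonds$a1[m$bonds$a2 == a])
.bond_order <- function(m, a, b) {
  i <- which((m$bonds$a1 == a & m$bonds$a2 == b) |
             (m$bonds$a1 == b & m$bonds$a2 == a))
  if (length(i)) m$bonds$order[i[1]] else 0L
}
.all_single <- function(m, a)
  all(m$bonds$order[m$bonds$a1 == a | m$bonds$a2 == a] == 1L)
.has_exo_double_o <- function(m, a)
  any(vapply(.ng(m, a), function(x)
    m$atoms$element[x] == "O" && .bond_order(m, a, x) == 2L, logical(1)))
.is_cooh_c <- function(m, a) {
  if (m$atoms$element[a] != "C") return(FALSE)
  nb <- .ng(m, a)
  has_dbl <- .has_exo_double_o(m, a)
  has_oh <- any(vapply(nb, function(x)
    m$atoms$element[x] == "O" && m$atoms$nh[x] == 1L &&
      m$atoms$charge[x] == 0L && .bond_order(m, a, x) == 1L, logical(1)))
  has_dbl && has_oh
}

oracle_ring_motif <- function(m, size, hetero) {
  for (r in molecule_rings(m)) {
    if (length(r) != size) next
    els <- m$atoms$element[r]
    if (sum(els == hetero) == 1L && sum(els == "C") == size - 1L) return(TRUE)
  }
  FALSE
}
oracle_epoxide <- function(m) oracle_ring_motif(m, 3L, "O")
oracle_aziridine <- function(m) oracle_ring_motif(m, 3L, "N")

oracle_disulfide <- function(m)
  any(m$atoms$element[m$bonds$a1] == "S" & m$atoms$element[m$bonds$a2] == "S")

oracle_azo <- function(m) {
  for (i in seq_len(nrow(m$bonds))) {
    a <- m$bonds$a1[i]; b <- m$bonds$a2[i]
    if (m$bonds$order[i] == 2L && m$atoms$element[a] == "N" &&
        m$atoms$element[b] == "N") {
      a_c <- any(m$atoms$element[setdiff(.ng(m, a), b)] == "C")
      b_c <- any(m$atoms$element[setdiff(.ng(m, b), a)] == "C")
      if (a_c && b_c) return(TRUE)
    }
  }
  FALSE
}

oracle_beta_lactam <- function(m) {
  for (r in molecule_rings(m)) {
    if (length(r) != 4L) next
    ns <- r[m$atoms$element[r] == "N"]
    for (nn in ns) {
      ring_c <- intersect(.ng(m, nn), r)
      if (any(vapply(ring_c, function(cc)
        m$atoms$element[cc] == "C" && .has_exo_double_o(m, cc), logical(1))))
        return(TRUE)
    }
  }
  FALSE
}

oracle_aminonitrile <- function(m) {
  for (cc in which(m$atoms$element == "C")) {
    if (!.all_single(m, cc)) next
    nb <- .ng(m, cc)
    amine <- any(vapply(nb, function(x)
      m$atoms$element[x] == "N" && .all_single(m, x), logical(1)))
    nitrile <- any(vapply(nb, function(x) {
      m$atoms$element[x] == "C" &&
        any(vapply(.ng(m, x), function(y)
          m$atoms$element[y] == "N" && .bond_order(m, x, y) == 3L, logical(1)))
    }, logical(1)))
    if (amine && nitrile) return(TRUE)
  }
  FALSE
}

oracle_thionitrile <- function(m) {
  for (s in which(m$atoms$element == "S")) {
    if (!.all_single(m, s)) next
    if (any(vapply(.ng(m, s), function(x) {
      m$atoms$element[x] == "C" &&
        any(vapply(.ng(m, x), function(y)
          m$atoms$element[y] == "N" && .bond_order(m, x, y) == 3L, logical(1)))
    }, logical(1)))) return(TRUE)
  }
  FALSE
}

oracle_gem_dicarboxylic <- function(m) {
  for (cc in which(m$atoms$element == "C")) {
    if (!.all_single(m, cc)) next
    n_acid <- sum(vapply(.ng(m, cc), function(x) .is_cooh_c(m, x), logical(1)))
    if (n_acid >= 2L) return(TRUE)
  }
  FALSE
}

oracle_quaternary_ammonium <- function(m)
  any(vapply(which(m$atoms$element == "N" & m$atoms$charge == 1L),
             function(a) {
               nb <- .ng(m, a)
               length(nb) == 4L && all(m$atoms$element[nb] == "C")
             }, logical(1)))

oracle_element <- function(m, els) any(m$atoms$element %in% els)

# the 30-molecule alert panel: spiked positives plus clean decoys
alert_panel_smiles <- function() c(
  aminonitrile1 = "NC(C#N)C(=O)O", aminonitrile2 = "CC(NC)(C#N)CC(=O)O",
  thionitrile1 = "OC(=O)CSC#N",
  epoxide1 = "OC(=O)C1CO1", epoxide2 = "CC1(C)OC1C(=O)O",
  aziridine1 = "OC(=O)C1CN1", aziridine2 = "OC(=O)CN1CC1",
  disulfide1 = "OC(=O)CSSC", disulfide2 = "OC(=O)CCSSCC",
  noxide1 = "OC(=O)c1ccc[n+]([O-])c1",
  nitro1 = "OC(=O)c1ccc([N+](=O)[O-])cc1",
  azo1 = "OC(=O)CN=Nc1ccccc1", azo2 = "OC(=O)c1ccc(N=NC)cc1",
  blactam1 = "OC(=O)C1CC(=O)N1", blactam2 = "O=C1CCN1CC(=O)O",
  gem1 = "OC(=O)CC(=O)O", gem2 = "OC(=O)C(C)C(=O)O",
  quat1 = "OC(=O)C[N+](C)(C)C",
  fatty1 = "CCCCCCCCC(=O)O", fatty2 = "CCCCCCCCCCCC(=O)O",
  boron1 = "OC(=O)c1ccc(B(O)O)cc1", sil1 = "OC(=O)C[Si](C)(C)C",
  sel1 = "OC(=O)C[Se]C",
  clean1 = "OC(=O)c1ccccc1", clean2 = "CCCCCC(=O)O", clean3 = "OC(=O)C1CCCCC1",
  clean4 = "OC(=O)c1ccc(OC)cc1", clean5 = "NCC(=O)O",
  clean6 = "OC(=O)CCC(=O)O", clean7 = "OC(=O)c1cccnc1"
)

# oracle evaluation of the shipped catalogue on one molecule
oracle_alert_hits <- function(m, chain_min = 8L) {
  c(aminonitrile = oracle_aminonitrile(m),
    thionitrile = oracle_thionitrile(m),
    epoxide = oracle_epoxide(m),
    aziridine = oracle_aziridine(m),
    disulfide = oracle_disulfide(m),
    azo = oracle_azo(m),
    beta_lactam = oracle_beta_lactam(m),
    gem_dicarboxylic = oracle_gem_dicarboxylic(m),
    quaternary_ammonium = oracle_quaternary_ammonium(m),
    boron_selenium_silicon = oracle_element(m, c("B", "Se", "Si")))
}
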