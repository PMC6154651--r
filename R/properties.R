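# ---- Descriptor profile ------------------------------------------------------

#' Compute the six-descriptor property profile of a molecule
#'
#' Descriptors follow the conventions used throughout the library funnel:
#' \itemize{
#'   \item `hbd`: Lipinski hydrogen-bond donors, counted as the number of
#'     O-H plus N-H hydrogens;
#'   \item `hba`: Lipinski acceptors, the count of nitrogen plus oxygen atoms;
#'   \item `rotatable_bonds`: non-ring single bonds between two non-terminal
#'     heavy atoms, excluding amide C-N bonds;
#'   \item `ring_count`: size of the smallest set of smallest rings (SSSR);
#'   \item `aromatic_ring_count`: SSSR rings whose atoms are all aromatic
#'     under the package's Hueckel-style perception scheme.
#' }
#' Masses are computed from the pinned isotope/atomic-weight tables.
#'
#' @param m A `Molecule`.
#' @return A `property_profile`: list with fields `id`, `formula`,
#'   `mw_average`, `mw_monoisotopic`, `hbd`, `hba`, `rotatable_bonds`,
#'   `ring_count`, `aromatic_ring_count`.
#' @examples
#' p <- parse_structures("OC(=O)c1ccccc1 benzoic", "smiles")
#' compute_properties(p$molecules[[1]])
#' @export
compute_properties <- function(m) {
  f <- molecular_formula(m)
  rings <- sssr(m)
  deg <- heavy_degree(m)
  el <- m$atoms$element

  hbd <- sum(m$atoms$nh[el %in% c("N", "O")])
  hba <- sum(el %in% c("N", "O"))

  ring_bond <- rep(FALSE, nrow(m$bonds))
  for (ring in rings) {
    k <- length(ring)
    for (j in seq_len(k)) {
      a <- ring[j]; b2 <- ring[if (j == k) 1L else j + 1L]
      ring_bond <- ring_bond | (m$bonds$a1 == a & m$bonds$a2 == b2) |
        (m$bonds$a1 == b2 & m$bonds$a2 == a)
    }
  }

  is_amide_cn <- function(i) {
    a <- m$bonds$a1[i]; b <- m$bonds$a2[i]
    pair_ok <- function(cc, nn) {
      el[cc] == "C" && el[nn] == "N" &&
        any((m$bonds$a1 == cc & m$bonds$order == 2L & el[m$bonds$a2] == "O") |
            (m$bonds$a2 == cc & m$bonds$order == 2L & el[m$bonds$a1] == "O"))
    }
    pair_ok(a, b) || pair_ok(b, a)
  }
  rot <- 0L
  for (i in seq_len(nrow(m$bonds))) {
    if (m$bonds$order[i] != 1L || ring_bond[i]) next
    a <- m$bonds$a1[i]; b <- m$bonds$a2[i]
    if (deg[a] < 2L || deg[b] < 2L) next
    if (is_amide_cn(i)) next
    rot <- rot + 1L
  }

  n_arom <- 0L
  for (ring in rings) if (all(m$atoms$aromatic[ring])) n_arom <- n_arom + 1L

  structure(list(
    id = m$id,
    formula = format_formula(f),
    mw_average = average_mass(f),
    mw_monoisotopic = monoisotopic_mass(f),
    hbd = hbd, hba = hba, rotatable_bonds = rot,
    ring_count = length(rings), aromatic_ring_count = n_arom
  ), class = "property_profile")
}

#' @export
print.property_profile <- function(x, ...) {
  cat(sprintf(
    "<properties %s> %s  MW %.2f (mono %.4f)  HBD %d  HBA %d  rot %d  rings %d (aromatic %d)\n",
    x$id, x$formula, x$mw_average, x$mw_monoisotopic, x$hbd, x$hba,
    x$rotatable_bonds, x$ring_count, x$aromatic_ring_count))
  invisible(x)
}

#' Property table for a list of molecules
#'
#' @param molecules List of `Molecule` objects.
#' @return A data.frame with one row per molecule and the profile columns.
#' @export
property_table <- function(molecules) {
  rows <- lapply(molecules, function(m) {
    p <- compute_properties(m)
    data.frame(id = p$id, formula = p$formula, mw_average = p$mw_average,
               mw_monoisotopic = p$mw_monoisotopic, hbd = p$hbd, hba = p$hba,
               rotatable_bonds = p$rotatable_bonds, ring_count = p$ring_count,
               aromatic_ring_count = p$aromatic_ring_count,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
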