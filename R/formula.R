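# ---- Molecular formulas ------------------------------------------------------

#' Molecular formula of a Molecule
#'
#' Tallies heavy atoms and implicit hydrogens into an element-count map.
#' The result is invariant under any permutation of atom indices.
#'
#' @param m A `Molecule`.
#' @return A `chem_formula`: named integer vector of element counts with a
#'   `charge` attribute.
#' @examples
#' p <- parse_structures("CCO ethanol", "smiles")
#' molecular_formula(p$molecules[[1]])
#' @export
molecular_formula <- function(m) {
  counts <- table(m$atoms$element)
  f <- stats::setNames(as.integer(counts), names(counts))
  nh <- sum(m$atoms$nh)
  if (nh > 0) f["H"] <- (if ("H" %in% names(f)) f[["H"]] else 0L) + nh
  f <- f[f > 0L]
  chem_formula(f, charge = sum(m$atoms$charge))
}

#' Construct a chem_formula
#'
#' @param counts Named integer vector (element -> count, all positive).
#' @param charge Net formal charge.
#' @return A `chem_formula` object.
#' @export
chem_formula <- function(counts = integer(0), charge = 0L) {
  counts <- counts[counts > 0L]
  structure(as.integer(counts), names = names(counts),
            charge = as.integer(charge), class = "chem_formula")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' Render a formula in Hill order
#'
#' Carbon first, then hydrogen, then all other elements alphabetically;
#' purely alphabetical when no carbon is present.
#'
#' @param f A `chem_formula`.
#' @return Character scalar such as `"C30H48O3"`.
#' @export
format_formula <- function(f) {
  els <- names(f)
  if ("C" %in% els) {
    rest <- sort(setdiff(els, c("C", "H")))
    ord <- c("C", intersect("H", els), rest)
  } else {
    ord <- sort(els)
  }
  paste0(vapply(ord, function(e) {
    n <- f[[e]]
    if (n == 1L) e else paste0(e, n)
  }, character(1)), collapse = "")
}

# element-wise formula arithmetic (used by the ester mass-conservation checks)
formula_add <- function(a, b) {
  els <- union(names(a), names(b))
  v <- vapply(els, function(e) {
    (if (e %in% names(a)) a[[e]] else 0L) + (if (e %in% names(b)) b[[e]] else 0L)
  }, integer(1))
  chem_formula(stats::setNames(v, els),
               charge = attr(a, "charge") + attr(b, "charge"))
}

formula_subtract <- function(a, b) {
  els <- union(names(a), names(b))
  v <- vapply(els, function(e) {
    (if (e %in% names(a)) a[[e]] else 0L) - (if (e %in% names(b)) b[[e]] else 0L)
  }, integer(1))
  if (any(v < 0L)) stop("formula subtraction went negative")
  chem_formula(stats::setNames(v, els),
               charge = attr(a, "charge") - attr(b, "charge"))
}

# named water formula, used by the esterification bookkeeping
.water_formula <- function() chem_formula(c(H = 2L, O = 1L))

mass_from_table <- function(f, table, what) {
  if (length(f) == 0L) return(0)
  unknown <- setdiff(names(f), names(table))
  if (length(unknown))
    stop("no ", what, " mass tabulated for element(s): ",
         paste(unknown, collapse = ", "))
  sum(table[names(f)] * as.numeric(f))
}

#' Monoisotopic mass of a formula
#'
#' Exact weighted sum over the pinned most-abundant-isotope masses;
#' deterministic to better than 1e-6 u.
#'
#' @param f A `chem_formula` (or a `Molecule`, which is tallied first).
#' @return Mass in u.
#' @examples
#' monoisotopic_mass(chem_formula(c(H = 2L, O = 1L)))  # 18.010565
#' @export
monoisotopic_mass <- function(f) {
  if (inherits(f, "Molecule")) f <- molecular_formula(f)
  mass_from_table(f, .monoisotopic, "monoisotopic")
}

#' Average (standard-atomic-weight) mass of a formula
#'
#' @inheritParams monoisotopic_mass
#' @return Mass in u.
#' @examples
#' average_mass(chem_formula(c(C = 7L, H = 6L, O = 2L)))  # benzoic acid, 122.12
#' @export
average_mass <- function(f) {
  if (inherits(f, "Molecule")) f <- molecular_formula(f)
  mass_from_table(f, .atomic_weight, "average")
}
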