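# ---- Functional-class circular fingerprints (FCFP-style) ---------------------

#' Fingerprint specification
#'
#' Circular functional-class fingerprint of diameter `2 * radius` bond
#' steps; the default (radius 2, 1024 bits) corresponds to the FCFP_4
#' descriptor family.
#'
#' @param radius Number of Morgan iterations (bond steps), >= 0.
#' @param n_bits Folded length; must be a power of two.
#' @return A `fingerprint_spec`.
#' @export
fingerprint_spec <- function(radius = 2L, n_bits = 1024L) {
  radius <- as.integer(radius); n_bits <- as.integer(n_bits)
  if (radius < 0L) stop("radius must be >= 0")
  if (n_bits < 2L || bitwAnd(n_bits, n_bits - 1L) != 0L)
    stop("n_bits must be a power of two")
  structure(list(radius = radius, n_bits = n_bits,
                 invariant = "functional-class"),
            class = "fingerprint_spec")
}

#' @export
print.fingerprint_spec <- function(x, ...) {
  cat(sprintf("<fingerprint_spec> FCFP-style, radius %d (diameter %d), %d bits\n",
              x$radius, 2L * x$radius, x$n_bits))
  invisible(x)
}

# pinned 32-bit mixing function: polynomial accumulation mod 2^31 - 1.
# Exact in double arithmetic (31 * 2^31 < 2^53), hence bit-stable.
hash_tuple <- function(values) {
  h <- 17
  for (v in values) h <- (h * 31 + v) %% 2147483647
  h
}

# The six FCFP functional classes, assigned by documented substructure rules:
#  1 H-bond acceptor: N or O, not positively charged, excluding pyrrole-type
#    aromatic N-H;
#  2 H-bond donor: N or O carrying at least one hydrogen;
#  3 positively ionizable: formal positive charge, or a non-aromatic amine
#    nitrogen (all single bonds) not adjacent to a carbonyl/thiocarbonyl;
#  4 negatively ionizable: formal negative charge, or an acidic O-H (hydroxyl
#    on a C/S/P that bears a double-bonded O);
#  5 aromatic: the package's ring-perception flag;
#  6 halogen: F/Cl/Br/I.
atom_classes <- function(m) {
  el <- m$atoms$element
  nh <- m$atoms$nh
  chg <- m$atoms$charge
  arom <- m$atoms$aromatic
  b <- m$bonds
  n <- nrow(m$atoms)

  has_double_to <- function(a, elems) {
    p <- c(b$a2[b$a1 == a & b$order == 2L], b$a1[b$a2 == a & b$order == 2L])
    any(el[p] %in% elems)
  }
  all_single <- vapply(seq_len(n), function(a)
    all(b$order[b$a1 == a | b$a2 == a] == 1L), logical(1))
  neighbors <- function(a) c(b$a2[b$a1 == a], b$a1[b$a2 == a])

  acceptor <- el %in% c("N", "O") & chg <= 0L & !(arom & el == "N" & nh > 0L)
  donor <- el %in% c("N", "O") & nh > 0L
  pos_ion <- chg > 0L
  neg_ion <- chg < 0L
  for (a in seq_len(n)) {
    if (el[a] == "N" && !arom[a] && chg[a] == 0L && all_single[a]) {
      adj_carbonyl <- any(vapply(neighbors(a), function(x)
        el[x] == "C" && has_double_to(x, c("O", "S", "N")), logical(1)))
      if (!adj_carbonyl) pos_ion[a] <- TRUE
    }
    if (el[a] == "O" && nh[a] > 0L) {
      acidic <- any(vapply(neighbors(a), function(x)
        el[x] %in% c("C", "S", "P") && has_double_to(x, "O"), logical(1)))
      if (acidic) neg_ion[a] <- TRUE
    }
  }
  halogen <- el %in% c("F", "Cl", "Br", "I")

  acceptor + 2L * donor + 4L * pos_ion + 8L * neg_ion + 16L * arom +
    32L * halogen
}

#' Compute the functional-class circular fingerprint of a molecule
#'
#' Morgan-style iterative environment hashing seeded with the six-class
#' pharmacophoric atom invariant.  At radius 0 each atom contributes its
#' class code; each further iteration hashes the atom's current identifier
#' together with the sorted (bond order, neighbour identifier) pairs.  All
#' identifiers from all iterations are folded modulo `n_bits`.  The bit set
#' is invariant under atom renumbering.
#'
#' @param m A `Molecule`.
#' @param spec A [fingerprint_spec()].
#' @return A `fingerprint`: sorted integer vector of 0-based bit positions
#'   with attributes `id` and `spec`.
#' @export
fingerprint <- function(m, spec = fingerprint_spec()) {
  n <- nrow(m$atoms)
  if (n == 0L) {
    return(structure(integer(0), id = m$id, spec = spec,
                     class = "fingerprint"))
  }
  classes <- atom_classes(m)
  rings <- sssr(m)
  arom_bond <- aromatic_bonds(m, rings)
  bond_code <- ifelse(arom_bond, 4L, m$bonds$order)

  nb_idx <- vector("list", n)
  nb_bond <- vector("list", n)
  for (i in seq_len(n)) { nb_idx[[i]] <- integer(0); nb_bond[[i]] <- integer(0) }
  for (i in seq_len(nrow(m$bonds))) {
    a <- m$bonds$a1[i]; b2 <- m$bonds$a2[i]
    nb_idx[[a]] <- c(nb_idx[[a]], b2); nb_bond[[a]] <- c(nb_bond[[a]], bond_code[i])
    nb_idx[[b2]] <- c(nb_idx[[b2]], a); nb_bond[[b2]] <- c(nb_bond[[b2]], bond_code[i])
  }

  inv <- vapply(classes, function(cl) hash_tuple(c(7, cl)), numeric(1))
  ids <- inv
  if (spec$radius > 0L) {
    for (r in seq_len(spec$radius)) {
      new_inv <- numeric(n)
      for (a in seq_len(n)) {
        pairs <- cbind(nb_bond[[a]], inv[nb_idx[[a]]])
        if (nrow(pairs)) {
          ord <- order(pairs[, 1], pairs[, 2])
          pairs <- pairs[ord, , drop = FALSE]
        }
        new_inv[a] <- hash_tuple(c(r, inv[a], t(pairs)))
      }
      inv <- new_inv
      ids <- c(ids, inv)
    }
  }
  bits <- sort(unique(as.integer(ids %% spec$n_bits)))
  structure(bits, id = m$id, spec = spec, class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  sp <- attr(x, "spec")
  cat(sprintf("<fingerprint %s> %d/%d bits set\n", attr(x, "id"),
              length(x), sp$n_bits))
  invisible(x)
}

#' Tanimoto similarity between two fingerprints
#'
#' `T = c / (a + b - c)` on bit counts.  Two empty fingerprints are defined
#' as identical (similarity 1).
#'
#' @param a,b `fingerprint` objects computed under the same spec.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  sa <- attr(a, "spec"); sb <- attr(b, "spec")
  if (!identical(sa$radius, sb$radius) || !identical(sa$n_bits, sb$n_bits))
    stop("fingerprint spec mismatch")
  if (length(a) == 0L && length(b) == 0L) return(1)
  inter <- length(intersect(a, b))
  inter / (length(a) + length(b) - inter)
}

#' Fingerprint a molecule list
#'
#' @param molecules List of `Molecule` objects.
#' @param spec A [fingerprint_spec()].
#' @return Named list of `fingerprint` objects (names = molecule ids).
#' @export
fingerprint_library <- function(molecules, spec = fingerprint_spec()) {
  fps <- lapply(molecules, fingerprint, spec = spec)
  names(fps) <- vapply(molecules, function(m) as.character(m$id), character(1))
  fps
}

# dense 0/1 matrix view (n x n_bits), used by the clustering stage
fingerprint_matrix <- function(fps, spec) {
  M <- matrix(0, length(fps), spec$n_bits)
  for (i in seq_along(fps)) M[i, fps[[i]] + 1L] <- 1
  rownames(M) <- names(fps)
  M
}

#' Export fingerprints as hex strings
#'
#' @param fps List from [fingerprint_library()].
#' @param path Output TSV path (id, hex).
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fps, path) {
  hex <- vapply(fps, function(fp) {
    sp <- attr(fp, "spec")
    bits <- logical(sp$n_bits)
    bits[fp + 1L] <- TRUE
    nib <- vapply(seq_len(sp$n_bits / 4L), function(k) {
      v <- sum(bits[(4L * (k - 1L) + 1L):(4L * k)] * c(8L, 4L, 2L, 1L))
      format.hexmode(v)
    }, character(1))
    paste(nib, collapse = "")
  }, character(1))
  writeLines(paste(names(fps), hex, sep = "\t"), path)
  invisible(path)
}
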