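# ---- Ring perception (SSSR) and aromaticity ----------------------------------

# Shortest path between two atoms avoiding one bond; BFS on the heavy-atom
# graph.  Returns the atom index path or NULL.
shortest_path_avoiding <- function(adj, from, to, avoid_a, avoid_b) {
  n <- length(adj)
  prev <- integer(n)
  seen <- logical(n)
  seen[from] <- TRUE
  queue <- from
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if ((v == avoid_a && w == avoid_b) || (v == avoid_b && w == avoid_a)) next
      if (seen[w]) next
      seen[w] <- TRUE
      prev[w] <- v
      if (w == to) {
        path <- w
        while (path[[1L]] != from) path <- c(prev[path[[1L]]], path)
        return(path)
      }
      queue <- c(queue, w)
    }
  }
  NULL
}

# Smallest set of smallest rings.  Candidate rings are the shortest cycles
# through every cyclic bond; a greedy pass keeps size-sorted candidates that
# are linearly independent over GF(2) on bond incidence, until the circuit
# rank E - V + C is reached.
sssr <- function(m) {
  nb <- nrow(m$bonds)
  n <- nrow(m$atoms)
  if (nb == 0L || n < 3L) return(list())
  rank <- nb - n + n_fragments(m)
  if (rank <= 0L) return(list())
  adj <- adjacency_list(m)

  bond_id <- function(a, b) {
    hit <- which((m$bonds$a1 == a & m$bonds$a2 == b) |
                 (m$bonds$a1 == b & m$bonds$a2 == a))
    hit[[1L]]
  }

  cands <- list()
  seen_keys <- character(0)
  for (i in seq_len(nb)) {
    a <- m$bonds$a1[i]; b <- m$bonds$a2[i]
    path <- shortest_path_avoiding(adj, a, b, a, b)
    if (is.null(path)) next            # bridge bond, not cyclic
    ring <- path                        # atoms in cycle order, a ... b
    key <- paste(sort(ring), collapse = ",")
    if (key %in% seen_keys) next
    seen_keys <- c(seen_keys, key)
    edges <- c(vapply(seq_len(length(ring) - 1L),
                      function(j) bond_id(ring[j], ring[j + 1L]), integer(1)),
               i)
    cands[[length(cands) + 1L]] <- list(atoms = ring, edges = sort(edges))
  }
  if (!length(cands)) return(list())
  cands <- cands[order(vapply(cands, function(r) length(r$atoms), integer(1)))]

  # GF(2) independence on edge-incidence vectors
  basis <- list()
  rings <- list()
  for (cand in cands) {
    v <- cand$edges
    for (bvec in basis) {
      if (length(v) && v[[1L]] %in% bvec) {
        v <- sort(c(setdiff(v, bvec), setdiff(bvec, v)))  # XOR
      }
    }
    # reduce fully against the basis (pivot = smallest edge id)
    repeat {
      if (!length(v)) break
      hit <- FALSE
      for (bvec in basis) {
        if (v[[1L]] == bvec[[1L]]) {
          v <- sort(c(setdiff(v, bvec), setdiff(bvec, v)))
          hit <- TRUE
          break
        }
      }
      if (!hit) break
    }
    if (length(v)) {
      basis <- c(basis, list(v))
      basis <- basis[order(vapply(basis, function(x) x[[1L]], integer(1)))]
      rings[[length(rings) + 1L]] <- cand$atoms
      if (length(rings) == rank) break
    }
  }
  rings
}

#' Ring systems of a molecule
#'
#' @param m A `Molecule`.
#' @return List of integer vectors, one per SSSR ring (atom indices in
#'   cycle order).
#' @export
molecule_rings <- function(m) sssr(m)

# ---- Aromaticity -------------------------------------------------------------

# Hueckel-style perception applied per SSSR ring (documented scheme):
# an atom is sp2-eligible when it is B/C/N/O/S/Se/P without triple bonds;
# it contributes 1 pi electron when double-bonded to a ring atom, 0 when its
# double bond is exocyclic, and 2 (lone pair) when it is N/O/S/Se with only
# single bonds.  A ring is aromatic when every member is eligible and the
# pi total is 4n + 2.  Atom flags are the union over aromatic rings.
perceive_aromaticity <- function(m) {
  rings <- sssr(m)
  m$atoms$aromatic <- FALSE
  if (!length(rings)) return(m)
  ring_member <- unique(unlist(rings))
  b <- m$bonds

  dbl_partners <- function(a) {
    p <- c(b$a2[b$a1 == a & b$order == 2L], b$a1[b$a2 == a & b$order == 2L])
    p
  }
  has_triple <- function(a) any((b$a1 == a | b$a2 == a) & b$order == 3L)

  aromatic_atoms <- integer(0)
  for (ring in rings) {
    ok <- TRUE
    pi_total <- 0L
    for (a in ring) {
      el <- m$atoms$element[a]
      if (!(el %in% c("B", "C", "N", "O", "S", "Se", "P")) || has_triple(a)) {
        ok <- FALSE; break
      }
      dp <- dbl_partners(a)
      if (length(dp) && any(dp %in% ring_member)) {
        pi_total <- pi_total + 1L
      } else if (length(dp)) {
        pi_total <- pi_total + 0L          # exocyclic double bond (e.g. C=O)
      } else if (el %in% c("N", "O", "S", "Se") ||
                 (el == "C" && m$atoms$charge[a] < 0L)) {
        pi_total <- pi_total + 2L          # lone-pair donor
      } else if (el == "B") {
        pi_total <- pi_total + 0L          # empty p orbital
      } else {
        ok <- FALSE; break                 # saturated carbon
      }
    }
    if (ok && pi_total %% 4L == 2L) aromatic_atoms <- c(aromatic_atoms, ring)
  }
  m$atoms$aromatic[unique(aromatic_atoms)] <- TRUE
  m
}

# is bond i aromatic: both endpoints aromatic and the bond lies in a ring
aromatic_bonds <- function(m, rings = NULL) {
  if (is.null(rings)) rings <- sssr(m)
  in_ring <- rep(FALSE, nrow(m$bonds))
  for (ring in rings) {
    k <- length(ring)
    for (j in seq_len(k)) {
      a <- ring[j]; b2 <- ring[if (j == k) 1L else j + 1L]
      in_ring <- in_ring | (m$bonds$a1 == a & m$bonds$a2 == b2) |
        (m$bonds$a1 == b2 & m$bonds$a2 == a)
    }
  }
  in_ring & m$atoms$aromatic[m$bonds$a1] & m$atoms$aromatic[m$bonds$a2]
}
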