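test_that("fingerprint spec validates its arguments", {
  expect_error(fingerprint_spec(n_bits = 1000), "power of two")
  expect_error(fingerprint_spec(radius = -1), "radius")
  sp <- fingerprint_spec()
  expect_equal(sp$radius, 2L)
  expect_equal(sp$n_bits, 1024L)
})

test_that("fingerprints respect molecular symmetry and functional classes", {
  ms <- parse_panel(c(benzene = "c1ccccc1",
                      benzoic1 = "OC(=O)c1ccccc1", benzoic2 = "c1ccccc1C(O)=O",
                      ethane = "CC", ethanol = "CCO"))
  fps <- fingerprint_library(ms)
  # one atom orbit per iteration depth in benzene
  expect_lte(length(fps$benzene), 3L)
  # two spellings of the same structure give identical bit sets
  expect_identical(as.integer(fps$benzoic1), as.integer(fps$benzoic2))
  # donor/acceptor class flips the root invariant
  expect_false(identical(as.integer(fps$ethane), as.integer(fps$ethanol)))
})

test_that("fingerprints are invariant under atom renumbering", {
  lib <- generate_library(library_spec(20, seed = 21, salt_rate = 0))
  p <- parse_structures(paste(lib$smiles, lib$id, collapse = "\n"), "smiles")
  set.seed(31)
  for (m in p$molecules) {
    ref <- as.integer(fingerprint(m))
    for (r in 1:20) {
      perm <- sample(nrow(m$atoms))
      expect_identical(as.integer(fingerprint(permute_molecule(m, perm))), ref)
    }
  }
})

test_that("tanimoto has its defining values and error cases", {
  f <- function(bits) raw_fingerprint(bits)
  expect_equal(tanimoto(f(c(1, 5, 9)), f(c(1, 5, 9))), 1)
  expect_equal(tanimoto(f(1:3), f(4:6)), 0)
  expect_equal(tanimoto(f(1:3), f(2:4)), 0.5)
  expect_equal(tanimoto(f(integer(0)), f(integer(0))), 1)
  expect_equal(tanimoto(f(1:4), f(2:3)), 0.5)              # subset case
  g <- raw_fingerprint(1:3, fingerprint_spec(n_bits = 512L))
  expect_error(tanimoto(f(1:3), g), "mismatch")
})

test_that("1 - tanimoto satisfies the triangle inequality on random triples", {
  set.seed(42)
  n_triples <- 10000L
  ok <- TRUE
  for (i in seq_len(n_triples)) {
    a <- raw_fingerprint(sample(0:127, sample(0:25, 1)))
    b <- raw_fingerprint(sample(0:127, sample(0:25, 1)))
    c_ <- raw_fingerprint(sample(0:127, sample(0:25, 1)))
    dab <- 1 - tanimoto(a, b); dbc <- 1 - tanimoto(b, c_)
    dac <- 1 - tanimoto(a, c_)
    if (dac > dab + dbc + 1e-12) { ok <- FALSE; break }
  }
  expect_true(ok)
})

test_that("clustering handles degenerate k and reference partitions", {
  ms <- parse_panel(c(a = "OC(=O)c1ccccc1", b = "CCCCC(=O)O", c = "OC(=O)C1CC1"))
  fps <- fingerprint_library(ms)
  ca3 <- cluster_fingerprints(fps, k = 3, seed = 1)
  expect_equal(n_nonempty_clusters(ca3), 3L)
  expect_equal(sort(table(ca3$assignment$cluster)), sort(table(1:3)))
  ca1 <- cluster_fingerprints(fps, k = 1, seed = 1)
  expect_equal(n_nonempty_clusters(ca1), 1L)
  expect_warning(ca5 <- cluster_fingerprints(fps, k = 5, seed = 1),
                 "singleton")
  expect_equal(n_nonempty_clusters(ca5), 3L)
})

test_that("identical fingerprints co-cluster away from a disjoint one", {
  # fpA and fpA' identical, fpB structurally unrelated; the minimal
  # within-cluster-distance 2-partition pairs the identical two
  ms <- parse_panel(c(fpA = "OC(=O)c1ccccc1", fpA2 = "c1ccccc1C(O)=O",
                      fpB = "CCCCCCC(=O)O"))
  fps <- fingerprint_library(ms)
  ca <- cluster_fingerprints(fps, k = 2, seed = 4)
  df <- ca$assignment
  expect_equal(df$cluster[df$id == "fpA"], df$cluster[df$id == "fpA2"])
  expect_false(df$cluster[df$id == "fpB"] == df$cluster[df$id == "fpA"])
})

test_that("clustering is deterministic and stable under input permutation", {
  lib <- generate_library(library_spec(60, seed = 13, salt_rate = 0))
  p <- parse_structures(paste(lib$smiles, lib$id, collapse = "\n"), "smiles")
  fps <- fingerprint_library(p$molecules)
  ca1 <- cluster_fingerprints(fps, k = 10, seed = 99)
  ca2 <- cluster_fingerprints(fps, k = 10, seed = 99)
  expect_identical(ca1$assignment, ca2$assignment)

  set.seed(1); ord <- sample(length(fps))
  ca3 <- cluster_fingerprints(fps[ord], k = 10, seed = 99)
  part <- function(ca) {
    s <- split(ca$assignment$id, ca$assignment$cluster)
    unname(sort(vapply(s, function(x) paste(sort(x), collapse = "|"), "")))
  }
  # same medoid set implies the same partition up to cluster relabelling
  expect_equal(length(unique(ca1$medoids)), 10L)
  expect_setequal(ca1$medoids, ca3$medoids)
  expect_identical(part(ca1), part(ca3))
})

test_that("cluster assignment invariants hold after representative selection", {
  lib <- generate_library(library_spec(80, seed = 17, salt_rate = 0))
  p <- parse_structures(paste(lib$smiles, lib$id, collapse = "\n"), "smiles")
  fps <- fingerprint_library(p$molecules)
  ca <- select_representatives(cluster_fingerprints(fps, k = 12, seed = 3), 7)
  df <- ca$assignment
  expect_equal(nrow(df), length(fps))                    # assigned exactly once
  expect_equal(n_nonempty_clusters(ca), 12L)
  reps <- representatives(ca)
  expect_length(reps, 12L)
  # each representative belongs to the cluster it represents, one per cluster
  rep_clusters <- df$cluster[match(reps, df$id)]
  expect_equal(sort(rep_clusters), sort(unique(df$cluster)))
  expect_equal(sum(df$is_representative), 12L)
})

test_that("representative selection is seeded, uniform and cluster-ordered", {
  ms <- parse_panel(c(x1 = "OC(=O)c1ccccc1", x2 = "OC(=O)c1ccccc1C",
                      y1 = "CCCCCC(=O)O"))
  fps <- fingerprint_library(ms)
  ca <- cluster_fingerprints(fps, k = 2, seed = 2)
  r1 <- representatives(select_representatives(ca, 5))
  r2 <- representatives(select_representatives(ca, 5))
  expect_identical(r1, r2)

  # every singleton cluster returns its member regardless of seed
  ca3 <- cluster_fingerprints(fps, k = 3, seed = 2)
  expect_setequal(representatives(select_representatives(ca3, 123)),
                  names(fps))

  # a 2-member cluster is sampled uniformly over a seed sweep
  two <- which(table(ca$assignment$cluster) == 2L)
  expect_length(two, 1L)
  members <- ca$assignment$id[ca$assignment$cluster == as.integer(names(two))]
  picks <- vapply(1:1000, function(s) {
    intersect(representatives(select_representatives(ca, s)), members)
  }, character(1))
  counts <- table(picks)
  expect_equal(sort(names(counts)), sort(members))
  expect_true(all(counts >= 430 & counts <= 570))   # ~4.4 sd binomial band
})

test_that("threshold mode yields an emergent cluster count", {
  lib <- generate_library(library_spec(40, seed = 23, salt_rate = 0))
  p <- parse_structures(paste(lib$smiles, lib$id, collapse = "\n"), "smiles")
  fps <- fingerprint_library(p$molecules)
  ca <- cluster_fingerprints(fps, seed = 1, threshold = 0.4)
  expect_true(ca$k >= 1L && ca$k <= length(fps))
  # tighter threshold never yields fewer clusters
  ca2 <- cluster_fingerprints(fps, seed = 1, threshold = 0.2)
  expect_gte(ca2$k, ca$k)
})
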