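# ---- Diversity clustering and representative selection -----------------------

# run code with a local, restored RNG state
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# Tanimoto similarity of every row of M against the single bit vector v
row_tanimoto <- function(M, pop, v, vpop) {
  inter <- as.numeric(M %*% v)
  uni <- pop + vpop - inter
  s <- ifelse(uni == 0, 1, inter / uni)
  s
}

#' Diversity clustering of a fingerprint set
#'
#' Partitions fingerprints into `k` clusters by maximum-dissimilarity
#' (MaxMin) seeding followed by nearest-medoid assignment in Tanimoto
#' distance.  The first medoid is drawn uniformly under `seed`; each
#' subsequent medoid is the point with the largest minimum distance to the
#' medoids chosen so far (ties broken by lowest input index).  Every point
#' is then assigned to its nearest medoid, ties broken by lowest cluster
#' index; medoids always belong to their own cluster, so all
#' `min(n, k)` clusters are non-empty.  The procedure is deterministic
#' given (inputs, k, seed).
#'
#' In threshold mode (`threshold` non-`NULL`, `k = NULL`) seeding stops
#' as soon as the largest minimum distance falls below `threshold`, and the
#' cluster count is emergent.
#'
#' @param fps Named list of `fingerprint` objects (one spec).
#' @param k Requested cluster count (ignored when `threshold` is given).
#' @param seed Integer seed for the first-medoid draw.
#' @param threshold Optional Tanimoto-distance cutoff for threshold mode.
#' @return A `cluster_assignment`: list with `assignment` (data.frame
#'   `id`, `cluster`, `is_representative`), `k`, `seed`, `medoids`
#'   (ids) and `spec`.
#' @export
cluster_fingerprints <- function(fps, k = NULL, seed = 1L, threshold = NULL) {
  n <- length(fps)
  if (n < 1L) stop("need at least one fingerprint")
  if (is.null(threshold)) {
    if (is.null(k) || k < 1L) stop("k must be >= 1")
    k <- as.integer(k)
    if (k > n) {
      warning("k exceeds the number of fingerprints; every molecule becomes a singleton")
      k <- n
    }
  }
  spec <- attr(fps[[1]], "spec")
  for (fp in fps) {
    sp <- attr(fp, "spec")
    if (!identical(sp$radius, spec$radius) ||
        !identical(sp$n_bits, spec$n_bits))
      stop("fingerprint spec mismatch within the set")
  }
  ids <- names(fps)
  if (is.null(ids))
    ids <- vapply(fps, function(fp) as.character(attr(fp, "id")), character(1))
  names(fps) <- ids

  # work in canonical (id-sorted) order so the partition is invariant to
  # the order the fingerprints arrive in; map back at the end
  ord <- order(ids)
  cids <- ids[ord]
  M <- fingerprint_matrix(fps[ord], spec)
  pop <- rowSums(M)

  first <- with_local_seed(seed, sample.int(n, 1L))
  medoids <- first
  min_dist <- 1 - row_tanimoto(M, pop, M[first, ], pop[first])
  min_dist[first] <- -Inf                 # never re-pick a medoid
  max_k <- if (is.null(threshold)) k else n
  while (length(medoids) < max_k) {
    if (!is.null(threshold) && max(min_dist) < threshold) break
    nxt <- which.max(min_dist)            # ties -> lowest id
    medoids <- c(medoids, nxt)
    d <- 1 - row_tanimoto(M, pop, M[nxt, ], pop[nxt])
    min_dist <- pmin(min_dist, d)
    min_dist[nxt] <- -Inf
  }
  k_eff <- length(medoids)

  # nearest-medoid assignment; ties -> lowest cluster index
  inter <- M %*% t(M[medoids, , drop = FALSE])
  uni <- outer(pop, pop[medoids], "+") - inter
  sim <- ifelse(uni == 0, 1, inter / uni)
  assign_c <- max.col(sim, ties.method = "first")
  assign_c[medoids] <- seq_len(k_eff)     # medoids own their clusters

  back <- integer(n); back[ord] <- seq_len(n)
  assign_idx <- assign_c[back]

  structure(list(
    assignment = data.frame(id = ids, cluster = assign_idx,
                            is_representative = FALSE,
                            stringsAsFactors = FALSE),
    k = k_eff, seed = as.integer(seed), medoids = cids[medoids],
    spec = spec
  ), class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  sizes <- table(x$assignment$cluster)
  cat(sprintf(
    "<cluster_assignment> %d molecules in %d clusters (sizes %d-%d), seed %d\n",
    nrow(x$assignment), x$k, min(sizes), max(sizes), x$seed))
  invisible(x)
}

#' Number of non-empty clusters
#'
#' @param ca A `cluster_assignment`.
#' @return Integer count.
#' @export
n_nonempty_clusters <- function(ca) length(unique(ca$assignment$cluster))

#' Randomly select one representative per cluster
#'
#' Draws one molecule uniformly at random from each non-empty cluster under
#' the given seed and flags it in the assignment.
#'
#' @param ca A `cluster_assignment`.
#' @param seed Integer seed.
#' @return The updated `cluster_assignment`, with `is_representative` set
#'   and `representatives` (ids ordered by cluster index) attached.
#' @export
select_representatives <- function(ca, seed = 1L) {
  df <- ca$assignment
  clusters <- sort(unique(df$cluster))
  reps <- with_local_seed(seed, vapply(clusters, function(cl) {
    members <- sort(df$id[df$cluster == cl])   # order-independent draw
    if (length(members) == 1L) members else members[sample.int(length(members), 1L)]
  }, character(1)))
  df$is_representative <- df$id %in% reps
  ca$assignment <- df
  ca$representatives <- reps
  ca$representative_seed <- as.integer(seed)
  ca
}

#' Representative ids of a cluster assignment
#'
#' @param ca A `cluster_assignment` after [select_representatives()].
#' @return Character vector of ids, ordered by cluster index.
#' @export
representatives <- function(ca) {
  if (is.null(ca$representatives))
    stop("run select_representatives() first")
  ca$representatives
}

#' Write a cluster assignment as TSV
#'
#' @param ca A `cluster_assignment`.
#' @param path Output path (columns id, cluster, is_representative).
#' @return `path`, invisibly.
#' @export
write_cluster_assignment <- function(ca, path) {
  utils::write.table(ca$assignment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
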