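# ---- End-to-end pipeline driver ----------------------------------------------

#' Pipeline configuration
#'
#' Collects every tunable of the library-design funnel: input source
#' (a structure file, or the synthetic generator when `input` is `NULL`),
#' filter criteria, fingerprint spec, cluster count, seeds, adducts and the
#' optional external docking-score table.  One root seed fans out to the
#' per-stage seeds (generation, clustering, representative selection) by
#' fixed offsets, so stages can be rerun independently.
#'
#' @param input Path to a `.smi`/`.sdf` acid library, or `NULL` to use the
#'   synthetic generator.
#' @param input_format Optional format override for `input`.
#' @param synthetic_n Library size when generating synthetically.
#' @param synthetic Extra arguments for [library_spec()] (list).
#' @param criteria A [filter_criteria()].
#' @param fp_spec A [fingerprint_spec()].
#' @param k Requested cluster count (the screening campaign used 285).
#' @param cluster_threshold Optional Tanimoto-distance cutoff; when given,
#'   the cluster count is emergent instead of fixed (see
#'   [cluster_fingerprints()]).
#' @param seed Root integer seed.
#' @param scores Optional path to an external docking-score CSV.
#' @param top_n Ranking truncation for the score table.
#' @param docking A [docking_config()] recorded in the manifest.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, input_format = NULL,
                            synthetic_n = 1000L, synthetic = list(),
                            criteria = filter_criteria(),
                            fp_spec = fingerprint_spec(), k = 285L,
                            cluster_threshold = NULL, seed = 1L,
                            scores = NULL, top_n = 5L,
                            docking = docking_config()) {
  structure(list(input = input, input_format = input_format,
                 synthetic_n = as.integer(synthetic_n), synthetic = synthetic,
                 criteria = criteria, fp_spec = fp_spec, k = as.integer(k),
                 cluster_threshold = cluster_threshold,
                 seed = as.integer(seed), scores = scores,
                 top_n = as.integer(top_n), docking = docking),
            class = "pipeline_config")
}

#' Per-stage seeds derived from the root seed
#'
#' @param seed Root integer seed.
#' @return list with `synthetic`, `cluster`, `representative`.
#' @export
derive_seeds <- function(seed) {
  list(synthetic = as.integer(seed) + 101L,
       cluster = as.integer(seed) + 202L,
       representative = as.integer(seed) + 303L)
}

#' Run the full library-design funnel
#'
#' Parse (or generate) the acid library, curate it (salt strip, descriptor
#' filter, structural alerts), fingerprint and cluster the survivors, pick
#' one representative acid per cluster, enumerate the 3-O-ester library on
#' the oleanolic-acid scaffold, and - when an external score table is
#' supplied - rank the docked ligands.  All stage artifacts are plain text
#' (TSV/CSV/SMILES) under `out_dir`, and a JSON manifest records the
#' configuration, seeds and per-stage counts; a rerun with the same
#' configuration reproduces the artifacts byte-identically.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `funnel`, `clusters`, `products`,
#'   `ranking` (or `NULL`), `manifest` and the artifact paths.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(cfg$seed)
  art <- function(name) file.path(out_dir, name)
  counts <- list()

  # -- stage 0: acquire ---------------------------------------------------
  if (is.null(cfg$input)) {
    lspec <- do.call(library_spec,
                     c(list(n = cfg$synthetic_n, seed = seeds$synthetic),
                       cfg$synthetic))
    records <- generate_library(lspec)
    write_library(records, art("library.smi"), art("library_labels.tsv"))
    payload <- paste(records$smiles, records$id, collapse = "\n")
    parsed <- parse_structures(payload, "smiles")
  } else {
    parsed <- read_structures(cfg$input, cfg$input_format)
  }
  if (nrow(parsed$rejects))
    utils::write.table(parsed$rejects, art("parse_rejects.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  counts$parsed <- length(parsed$molecules)

  # -- stages 1-3: curation ----------------------------------------------
  cur <- curate_acids(parsed$molecules, cfg$criteria)
  utils::write.table(funnel_as_data_frame(cur$report), art("funnel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_structures(cur$survivors, art("curated.smi"), canonical = FALSE)
  counts$curated <- length(cur$survivors)
  if (!counts$curated) stop("curation left no survivors")

  # -- stage 4: fingerprints + clustering ---------------------------------
  fps <- fingerprint_library(cur$survivors, cfg$fp_spec)
  write_fingerprints(fps, art("fingerprints.tsv"))
  ca <- cluster_fingerprints(fps, k = cfg$k, seed = seeds$cluster,
                             threshold = cfg$cluster_threshold)
  ca <- select_representatives(ca, seeds$representative)
  write_cluster_assignment(ca, art("clusters.tsv"))
  counts$clusters <- n_nonempty_clusters(ca)
  counts$representatives <- length(representatives(ca))

  # -- stage 5: ester enumeration -----------------------------------------
  site <- oa_scaffold()
  rep_ids <- representatives(ca)
  by_id <- stats::setNames(cur$survivors,
                           vapply(cur$survivors, `[[`, "", "id"))
  enum <- enumerate_library(site, by_id[rep_ids])
  write_products(enum$products, art("products.csv"), art("products.smi"))
  if (nrow(enum$rejects))
    utils::write.table(enum$rejects, art("enumeration_rejects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  counts$products <- length(enum$products)

  # -- stage 6: external scores (optional) --------------------------------
  ranking <- NULL
  if (!is.null(cfg$scores)) {
    sc <- load_scores(cfg$scores)
    ranking <- rank_ligands(sc, cfg$top_n)
    utils::write.csv(ranking, art("ranked.csv"), row.names = FALSE)
    chk <- control_check(sc)
    counts$ranked <- nrow(ranking)
    counts$control_status <- chk$status
  }

  manifest <- list(
    package = "esterlib",
    version = as.character(utils::packageVersion("esterlib")),
    seed = cfg$seed, seeds = seeds,
    config = list(
      input = cfg$input, synthetic_n = cfg$synthetic_n,
      synthetic = cfg$synthetic,
      criteria = unclass(cfg$criteria),
      fingerprint = unclass(cfg$fp_spec),
      k = cfg$k, cluster_threshold = cfg$cluster_threshold,
      top_n = cfg$top_n, docking = unclass(cfg$docking)
    ),
    counts = counts
  )
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")

  invisible(list(funnel = cur$report, clusters = ca,
                 products = enum$products, enumeration_rejects = enum$rejects,
                 ranking = ranking, manifest = art("manifest.json"),
                 out_dir = out_dir, counts = counts))
}
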