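test_that("salt stripping and acid validation classify reference records", {
  ms <- parse_panel(c(na_benzoate = "[Na+].[O-]C(=O)c1ccccc1",
                      benzoic = "OC(=O)c1ccccc1",
                      benzene = "c1ccccc1"))
  r1 <- strip_and_validate_acid(ms$na_benzoate)
  expect_s3_class(r1, "acid_rejection")
  expect_equal(r1$reason, "salt")
  expect_s3_class(strip_and_validate_acid(ms$benzoic), "Molecule")
  r3 <- strip_and_validate_acid(ms$benzene)
  expect_equal(r3$reason, "not_carboxylic_acid")
})

test_that("drug-likeness filter applies all six thresholds with tallies", {
  ms <- parse_panel(c(
    benzoic = "OC(=O)c1ccccc1",
    heavy = "OC(=O)c1ccc(-c2ccc(Cl)cc2)cc1",     # MW 232.66 > 200
    gluconic = "OCC(O)C(O)C(O)C(O)C(=O)O"))      # HBD 6 > 4
  res <- apply_druglike_filter(ms, filter_criteria())
  ids <- unname(vapply(res$survivors, `[[`, "", "id"))
  expect_equal(ids, "benzoic")
  expect_equal(sort(res$rejects$id), c("gluconic", "heavy"))
  expect_equal(res$rejects$rules[res$rejects$id == "heavy"], "mw_max")
  expect_equal(res$rejects$rules[res$rejects$id == "gluconic"], "hbd_max")
  expect_equal(res$stage$tallies[["mw_max"]], 1L)
  expect_equal(res$stage$n_in - res$stage$n_out, 2L)
})

test_that("structural alerts reject the reference motifs and spare benzoic acid", {
  ms <- parse_panel(c(glycidic = "OC(=O)C1CO1", malonic = "OC(=O)CC(=O)O",
                      stearic = "CCCCCCCCCCCCCCCCCC(=O)O",
                      benzoic = "OC(=O)c1ccccc1"))
  res <- apply_alerts(ms)
  expect_equal(unname(vapply(res$survivors, `[[`, "", "id")), "benzoic")
  rj <- res$rejects
  expect_equal(rj$alerts[rj$id == "glycidic"], "epoxide")
  expect_equal(rj$alerts[rj$id == "malonic"], "gem_dicarboxylic")
  expect_equal(rj$alerts[rj$id == "stearic"], "long_chain_fatty_acid")
})

test_that("SMARTS alerts agree with the brute-force graph oracle on the panel", {
  smis <- alert_panel_smiles()
  ms <- parse_panel(smis)
  alerts <- load_alerts()
  hits <- esterlib:::match_alerts(ms, alerts)
  for (i in seq_along(ms)) {
    oracle <- oracle_alert_hits(ms[[i]])
    for (nm in names(oracle)) {
      expect_identical(unname(hits[i, nm]), unname(oracle[[nm]]),
                       info = paste(names(smis)[i], nm))
    }
  }
})

test_that("long-chain fatty-acid rule has the documented boundary", {
  ms <- parse_panel(c(octanoic = "CCCCCCCC(=O)O",       # 7-carbon chain
                      nonanoic = "CCCCCCCCC(=O)O",      # 8-carbon chain
                      stearic = "CCCCCCCCCCCCCCCCCC(=O)O",
                      branched = "CCCCCC(C)CCCC(=O)O",  # branch breaks the chain
                      ether = "COCCCCCCCC(=O)O"))       # heteroatom breaks it
  hits <- esterlib:::match_alerts(ms, load_alerts())[, "long_chain_fatty_acid"]
  expect_equal(unname(hits), c(FALSE, TRUE, TRUE, FALSE, FALSE))
})

test_that("filtering is monotone in each threshold and idempotent", {
  lib <- generate_library(library_spec(120, seed = 5))
  p <- parse_structures(paste(lib$smiles, lib$id, collapse = "\n"), "smiles")
  ms <- p$molecules
  set.seed(99)
  for (rep in 1:8) {
    loose <- filter_criteria(mw_max = runif(1, 100, 400),
                             hbd_max = sample(0:6, 1), hba_max = sample(0:9, 1),
                             rotatable_max = sample(0:9, 1),
                             ring_max = sample(0:3, 1),
                             aromatic_ring_max = sample(0:3, 1))
    tight <- loose
    which_rule <- sample(names(unclass(loose)), 1)
    tight[[which_rule]] <- max(0, loose[[which_rule]] * 0.5)
    class(tight) <- "filter_criteria"
    s_loose <- vapply(apply_druglike_filter(ms, loose)$survivors, `[[`, "", "id")
    s_tight <- vapply(apply_druglike_filter(ms, tight)$survivors, `[[`, "", "id")
    expect_true(all(s_tight %in% s_loose))
  }
  crit <- filter_criteria()
  once <- apply_druglike_filter(ms, crit)$survivors
  twice <- apply_druglike_filter(once, crit)$survivors
  expect_identical(vapply(twice, `[[`, "", "id"), vapply(once, `[[`, "", "id"))
})

test_that("funnel report counts equal recounts of the emitted sets", {
  lib <- generate_library(library_spec(150, seed = 8))
  p <- parse_structures(paste(lib$smiles, lib$id, collapse = "\n"), "smiles")
  cur <- curate_acids(p$molecules)
  stages <- cur$report$stages
  expect_equal(stages$strip_salts$n_in, length(p$molecules))
  expect_equal(stages$structural_alerts$n_out, length(cur$survivors))
  # adjacent stages hand over exactly their survivors
  expect_equal(stages$strip_salts$n_out, stages$druglike_filter$n_in)
  expect_equal(stages$druglike_filter$n_out, stages$structural_alerts$n_in)
  # per-stage rejected counts match the reject tables
  expect_equal(stages$strip_salts$n_in - stages$strip_salts$n_out,
               nrow(cur$rejects$strip))
  expect_equal(stages$druglike_filter$n_in - stages$druglike_filter$n_out,
               nrow(cur$rejects$druglike))
  expect_equal(stages$structural_alerts$n_in - stages$structural_alerts$n_out,
               nrow(cur$rejects$alerts))
})
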