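test_that("SMILES parsing keeps order, reports rejects with line numbers", {
  p <- parse_structures("CCO ethanol\nC1CC1x bad\nOC(=O)c1ccccc1 benzoic",
                        "smiles")
  expect_length(p$molecules, 2L)
  expect_equal(vapply(p$molecules, `[[`, "", "id"), c("ethanol", "benzoic"))
  expect_equal(nrow(p$molecules[[1]]$atoms), 3L)   # heavy atoms only
  expect_equal(p$rejects$line, 2L)
  expect_equal(p$rejects$reason, "unparseable_smiles")
  expect_error(parse_structures("", "smiles"), "empty")
})

test_that("SDF records parse and report per-record failures", {
  ms <- parse_panel(c(ethanol = "CCO", benzoic = "OC(=O)c1ccccc1"))
  sdf_text <- paste(vapply(ms, esterlib:::mol_to_sdf_text, character(1)),
                    collapse = "\n")
  p <- parse_structures(sdf_text, "sdf")
  expect_length(p$molecules, 2L)
  expect_equal(format_formula(molecular_formula(p$molecules[[2]])), "C7H6O2")
})

test_that("molecular formulas follow Hill order and match hand tallies", {
  panel <- descriptor_panel()
  ms <- parse_panel(stats::setNames(panel$smiles, panel$name))
  for (i in seq_len(nrow(panel))) {
    expect_equal(format_formula(molecular_formula(ms[[panel$name[i]]])),
                 panel$formula[i], info = panel$name[i])
  }
  # no-carbon formulas are purely alphabetical
  expect_equal(format_formula(chem_formula(c(O = 1L, H = 2L))), "H2O")
})

test_that("formula is invariant under atom renumbering", {
  ms <- parse_panel(c(oa = descriptor_panel()$smiles[10],
                      acid2a = "OC(=O)c1cc(-c2ccccc2)no1"))
  set.seed(7)
  for (m in ms) {
    ref <- format_formula(molecular_formula(m))
    for (r in 1:10) {
      perm <- sample(nrow(m$atoms))
      expect_equal(format_formula(molecular_formula(permute_molecule(m, perm))),
                   ref)
    }
  }
})

test_that("monoisotopic and average masses reproduce fixed sums", {
  expect_equal(monoisotopic_mass(chem_formula(c(H = 2L, O = 1L))),
               2 * 1.007825 + 15.994915, tolerance = 1e-9)
  expect_equal(monoisotopic_mass(chem_formula()), 0)
  oa <- parse_panel(c(oa = descriptor_panel()$smiles[10]))$oa
  expect_equal(monoisotopic_mass(oa), 30 * 12 + 48 * 1.007825 + 3 * 15.994915,
               tolerance = 1e-9)
  expect_equal(average_mass(chem_formula(c(C = 7L, H = 6L, O = 2L))), 122.123,
               tolerance = 1e-6)
  expect_equal(average_mass(chem_formula(c(H = 2L))), 2.016, tolerance = 1e-9)
  expect_error(monoisotopic_mass(chem_formula(c(Xx = 1L))), "Xx")
})

test_that("masses agree with the OpenBabel exact-mass oracle", {
  smis <- c("CCO", "OC(=O)c1ccccc1", "OC(=O)c1cc(-c2ccccc2)no1",
            "CCCCCCCCCCCCCCCCCC(=O)O")
  ms <- parse_panel(stats::setNames(smis, paste0("m", seq_along(smis))))
  ob <- unlist(ChemmineOB::forEachMol(
    "SMILES", paste(smis, paste0("m", seq_along(smis)), collapse = "\n"),
    function(mol) ChemmineOB::exactMass_OB(list(mol))))
  mine <- vapply(ms, monoisotopic_mass, numeric(1))
  expect_equal(unname(mine), unname(ob), tolerance = 1e-3)
})

test_that("masses are additive over disjoint fragment unions", {
  ms <- parse_panel(c(a = "CCO", b = "OC(=O)c1ccccc1", ab = "CCO.OC(=O)c1ccccc1"))
  expect_equal(monoisotopic_mass(ms$a) + monoisotopic_mass(ms$b),
               monoisotopic_mass(ms$ab), tolerance = 1e-9)
  expect_equal(average_mass(ms$a) + average_mass(ms$b), average_mass(ms$ab),
               tolerance = 1e-9)
})

test_that("descriptors equal hand counts on the fixed panel", {
  panel <- descriptor_panel()
  ms <- parse_panel(stats::setNames(panel$smiles, panel$name))
  for (i in seq_len(nrow(panel))) {
    pr <- compute_properties(ms[[panel$name[i]]])
    expect_equal(pr$hbd, panel$hbd[i], info = panel$name[i])
    expect_equal(pr$hba, panel$hba[i], info = panel$name[i])
    expect_equal(pr$rotatable_bonds, panel$rot[i], info = panel$name[i])
    expect_equal(pr$ring_count, panel$rings[i], info = panel$name[i])
    expect_equal(pr$aromatic_ring_count, panel$arom[i], info = panel$name[i])
    expect_true(pr$mw_monoisotopic <= pr$mw_average + 1, info = panel$name[i])
    expect_true(pr$aromatic_ring_count <= pr$ring_count, info = panel$name[i])
  }
})

test_that("SSSR ring counts are correct on reference topologies", {
  ms <- parse_panel(c(benzene = "c1ccccc1", naphthalene = "c1ccc2ccccc2c1",
                      cyclohexane = "C1CCCCC1",
                      adamantane = "C1C2CC3CC1CC(C2)C3",
                      biphenyl = "c1ccc(-c2ccccc2)cc1"))
  expect_length(molecule_rings(ms$benzene), 1L)
  expect_length(molecule_rings(ms$naphthalene), 2L)
  expect_length(molecule_rings(ms$cyclohexane), 1L)
  expect_length(molecule_rings(ms$adamantane), 3L)
  expect_length(molecule_rings(ms$biphenyl), 2L)
  ring_sizes <- sort(lengths(molecule_rings(ms$naphthalene)))
  expect_equal(ring_sizes, c(6L, 6L))
})
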