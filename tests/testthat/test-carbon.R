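test_that("composition normalization preserves proportions and sums to 1", {
  expect_equal(normalize_composition(c(Gly = 100)), c(Gly = 1))
  expect_equal(normalize_composition(c(Gly = 50, Ala = 50)),
               c(Gly = 0.5, Ala = 0.5))
  comp <- landsort_composition()
  aa <- intersect(names(aa_carbon_registry()), names(comp))
  row <- unlist(comp[1, aa])
  expect_equal(sum(row), 99.8)  # printed mole % of the shallowest sample
  f <- normalize_composition(row)
  expect_equal(sum(f), 1, tolerance = 1e-12)
  expect_equal(unname(f / f[1]), unname(row / row[1]))
  expect_error(normalize_composition(c(Gly = 0, Ala = 0)),
               class = "invalid_composition_error")
  expect_error(normalize_composition(c(1, 2)), class = "invalid_composition_error")
})

test_that("mean carbon atoms per residue is the composition-weighted count", {
  expect_equal(mean_carbon_atoms_per_residue(c(Gly = 100)), 2)
  expect_equal(mean_carbon_atoms_per_residue(c(Gly = 50, Ala = 50)), 2.5)
  # shallowest reference sample, against an independent weighted-sum oracle
  comp <- landsort_composition()
  reg <- aa_carbon_registry()
  aa <- intersect(names(reg), names(comp))
  row <- unlist(comp[1, aa])
  oracle <- sum(row * reg[aa]) / sum(row)
  expect_equal(mean_carbon_atoms_per_residue(row), oracle, tolerance = 1e-12)
  expect_equal(round(oracle, 2), 4.64)
  expect_error(mean_carbon_atoms_per_residue(c(Xyz = 100)),
               class = "configuration_error")
})

test_that("mean carbon atoms per residue stays within the registry bounds", {
  set.seed(41)
  reg <- aa_carbon_registry()
  for (i in 1:50) {
    comp <- stats::runif(length(reg))
    names(comp) <- names(reg)
    m <- mean_carbon_atoms_per_residue(comp)
    expect_gte(m, 2)
    expect_lte(m, 9)
  }
})

test_that("THAA to THAA-C conversion is linear and tracks the reference table", {
  expect_equal(thaa_to_thaa_c(0, 4.6), 0)
  expect_equal(thaa_to_thaa_c(1, 2), 2)
  set.seed(42)
  x <- runif(5); a <- runif(1, 2, 9)
  expect_equal(thaa_to_thaa_c(2 * x, a), 2 * thaa_to_thaa_c(x, a))
  # composition-weighted conversion agrees with the measured THAA-C within
  # 10% for every reference sample (inputs printed to 2 significant figures)
  ct <- carbon_table(landsort_thaa(), landsort_composition())
  expect_true(all(abs(ct$thaa_c_fmol_derived / ct$thaa_c_fmol - 1) < 0.10))
  expect_equal(round(ct$thaa_c_fmol_derived[1], 2), 0.83)
  expect_error(thaa_to_thaa_c(-1, 4), class = "invalid_measurement_error")
})

test_that("total cell carbon applies the molar mass and amino-acid-carbon share", {
  expect_equal(total_cell_carbon(0.88, 0.55), 0.88 * 12.011 / 0.55)
  expect_equal(round(total_cell_carbon(0.88, 0.55)), 19)
  expect_equal(round(total_cell_carbon(1.4, 0.55)), 31)
  expect_equal(round(total_cell_carbon(0.78, 0.40)), 23)
  # inverse proportionality in the assumed share
  expect_equal(total_cell_carbon(1, 0.275), 2 * total_cell_carbon(1, 0.55))
  expect_error(total_cell_carbon(1, 0), class = "configuration_error")
  expect_error(total_cell_carbon(1, 1.2), class = "configuration_error")
  expect_error(total_cell_carbon(-1), class = "invalid_measurement_error")
})

test_that("all reference samples recompute to the published totals within 1 fg", {
  ct <- carbon_table(landsort_thaa(), landsort_composition())
  published <- landsort_thaa()$total_c_fg_published
  expect_true(all(abs(ct$total_c_fg - published) <= 1))
})

test_that("carbon density divides by the morphotype-weighted mean volume", {
  expect_equal(carbon_density(20, c(coccoid = 1), c(coccoid = 0.02)), 1000)
  f <- c(coccoid = 0.6, elongated = 0.35, filamentous = 0.05)
  v <- c(coccoid = 0.05, elongated = 0.1, filamentous = 0.3)
  # weighted-mean oracle: 0.6*0.05 + 0.35*0.1 + 0.05*0.3 = 0.08
  expect_equal(carbon_density(19, f, v), 19 / 0.08, tolerance = 1e-12)
  # exact inverse identity and permutation invariance
  cd <- carbon_density(19, f, v)
  expect_equal(cd * sum(f * v), 19, tolerance = 1e-12)
  perm <- c(3, 1, 2)
  expect_equal(carbon_density(19, f[perm], v[perm]), cd)
  expect_error(carbon_density(19, c(coccoid = 0.5), v),
               class = "invalid_fractions_error")
  expect_error(carbon_density(19, c(coccoid = 1), c(coccoid = 0)),
               class = "invalid_measurement_error")
})

test_that("sediment carbon and extraction efficiency convert units correctly", {
  expect_equal(total_sediment_carbon(23, 1e10), 230)
  expect_equal(total_sediment_carbon(10, 1e9), 10)
  expect_equal(total_sediment_carbon(10, 0), 0)
  expect_error(total_sediment_carbon(10, -1), class = "invalid_measurement_error")
  expect_equal(extraction_efficiency(5e8, 1e9), 50)
  expect_equal(extraction_efficiency(0, 1e9), 0)
  expect_equal(extraction_efficiency(1e9, 1e9), 100)
  expect_warning(eff <- extraction_efficiency(1.2e9, 1e9), "above 100")
  expect_equal(eff, 120)
  expect_error(extraction_efficiency(1, 0), class = "degenerate_sample_error")
})

test_that("carbon_table validates its inputs", {
  thaa <- landsort_thaa()
  comp <- landsort_composition()
  expect_error(carbon_table(thaa[, 1:2], comp), class = "schema_error")
  expect_error(carbon_table(thaa, comp[1:3, ]), class = "schema_error")
  # without measured THAA-C the derived value feeds the carbon scaling
  ct <- carbon_table(thaa[, c("sample_id", "depth_mbsf", "thaa_fmol_per_cell")], comp)
  expect_equal(ct$thaa_c_fmol, ct$thaa_c_fmol_derived)
  expect_equal(ct$total_c_fg, total_cell_carbon(ct$thaa_c_fmol_derived))
})
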