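test_that("generator config validates anchors, fractions and spreads", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(surface_median_volume = 0.005,
                                deep_median_volume = 0.05),
               class = "configuration_error")
  expect_error(generator_config(fractions = c(coccoid = 0.7, elongated = 0.7,
                                              filamentous = -0.4)),
               class = "configuration_error")
  expect_error(generator_config(volume_gsd = 0.5), class = "configuration_error")
  expect_error(generator_config(depths = 5), class = "configuration_error")
})

test_that("a fixed seed gives bit-identical studies", {
  a <- simulate_study(generator_config(seed = 33, n_cells_per_depth = 50))
  b <- simulate_study(generator_config(seed = 33, n_cells_per_depth = 50))
  expect_identical(a, b)
  c <- simulate_study(generator_config(seed = 34, n_cells_per_depth = 50))
  expect_false(identical(a$true_cells, c$true_cells))
})

test_that("degenerate spread collapses volumes onto the configured median", {
  cfg <- generator_config(volume_gsd = 1, filament_gsd = 1,
                          n_cells_per_depth = 40, seed = 5)
  cells <- generate_true_cells(cfg)
  surf <- subset(cells, depth_mbsf == min(depth_mbsf) & morphotype != "filamentous")
  expect_true(all(abs(surf$volume_true_um3 - 0.05) < 1e-12))
  fil <- subset(cells, depth_mbsf == min(depth_mbsf) & morphotype == "filamentous")
  if (nrow(fil) > 0) expect_true(all(abs(fil$volume_true_um3 - 0.3) < 1e-12))
})

test_that("morphotype mixture and filament share follow the configuration", {
  cells <- generate_true_cells(generator_config(seed = 8))
  frac_fil <- mean(cells$morphotype == "filamentous")
  # binomial error around the configured 5% at n = 2400
  expect_lt(abs(frac_fil - 0.05), 0.015)
  # back-solved dimensions reproduce the drawn volume under the shape model
  cocc <- cells$morphotype == "coccoid"
  expect_equal(volume_sphere(cells$width_um[cocc]),
               cells$volume_true_um3[cocc], tolerance = 1e-12)
  expect_equal(volume_capsule(cells$length_um[!cocc], cells$width_um[!cocc]),
               cells$volume_true_um3[!cocc], tolerance = 1e-12)
  # aspect ratios stay inside the configured classification bands
  expect_identical(classify_morphotype(cells$length_um, cells$width_um),
                   cells$morphotype)
})

test_that("observation divides by the composite factor; the pipeline round-trips", {
  cfg <- generator_config(seed = 13, n_cells_per_depth = 100)
  true_cells <- generate_true_cells(cfg)
  fm <- observe_cells(true_cells, "FM")
  cocc <- true_cells$morphotype == "coccoid"
  expect_equal(volume_sphere(fm$width_um[cocc]),
               true_cells$volume_true_um3[cocc] / (1.29 * 0.475),
               tolerance = 1e-12)
  for (mod in c("FM", "SEM")) {
    obs <- observe_cells(true_cells, mod)
    corrected <- correct_observed(obs)
    expect_identical(corrected$morphotype, true_cells$morphotype)
    expect_equal(corrected$volume_corrected_um3, true_cells$volume_true_um3,
                 tolerance = 1e-6)
  }
  # identity table: observed equals true
  tab <- default_correction_table()
  tab$factors[] <- 1
  obs <- observe_cells(true_cells, "FM", tab)
  expect_equal(obs$width_um, true_cells$width_um, tolerance = 1e-12)
})

test_that("zero-noise THAA generation reproduces the reference tables", {
  cfg <- generator_config(thaa_gsd = 1, composition_gsd = 1, seed = 2)
  prof <- generate_thaa_profile(cfg)
  ref <- landsort_thaa()
  expect_equal(prof$thaa$thaa_fmol_per_cell, ref$thaa_fmol_per_cell)
  expect_equal(prof$thaa$thaa_c_fmol_per_cell, ref$thaa_c_fmol_per_cell)
  aa <- intersect(names(aa_carbon_registry()), names(prof$composition))
  ref_comp <- landsort_composition()
  # renormalized to exactly 100%, proportions preserved
  expect_equal(unname(rowSums(prof$composition[, aa])), rep(100, 7))
  renorm <- 100 * as.matrix(ref_comp[, aa]) / rowSums(as.matrix(ref_comp[, aa]))
  expect_equal(as.matrix(prof$composition[, aa]), renorm,
               ignore_attr = TRUE, tolerance = 1e-12)
  # carbon pipeline on the zero-noise output matches the published totals
  ct <- carbon_table(prof$thaa, prof$composition)
  expect_true(all(abs(ct$total_c_fg - ref$total_c_fg_published) <= 1))
  # noisy generation still renormalizes to 100%
  noisy <- generate_thaa_profile(generator_config(seed = 3))
  expect_equal(unname(rowSums(noisy$composition[, aa])), rep(100, 7))
})

test_that("abundance profile interpolates log-linearly between anchors", {
  cfg <- generator_config(depths = c(0, 30, 60), n_cells_per_depth = 10)
  ab <- generate_abundance_profile(cfg)
  expect_equal(ab$cells_per_cm3, c(1e10, 1e9, 1e8))
  # surface sediment carbon at the mean cell-carbon scale
  expect_equal(total_sediment_carbon(23, ab$cells_per_cm3[1]), 230)
})

test_that("expected volumes follow the configured lognormal moments", {
  cfg <- generator_config()
  expect_equal(expected_median_volume(cfg, 0.4), 0.05)
  expect_equal(expected_median_volume(cfg, 60), 0.005)
  expect_equal(expected_median_volume(cfg, 60, "filamentous"), 0.08)
  expect_equal(expected_mean_volume(cfg, 0.4), 0.05 * exp(log(2)^2 / 2))
})

test_that("carbon density from the configured study rises with depth", {
  # combine the reference carbon contents with the generator's expected
  # mean volumes: the density starts near 200 fg/um^3 at the surface and
  # approaches 1000 fg/um^3 at depth
  cfg <- generator_config()
  ct <- carbon_table(landsort_thaa(), landsort_composition())
  f <- cfg$fractions
  cd <- vapply(seq_len(nrow(ct)), function(i) {
    d <- ct$depth_mbsf[i]
    v <- c(coccoid = expected_mean_volume(cfg, d, "coccoid"),
           elongated = expected_mean_volume(cfg, d, "elongated"),
           filamentous = expected_mean_volume(cfg, d, "filamentous"))
    carbon_density(ct$total_c_fg[i], f, v)
  }, numeric(1))
  expect_lt(abs(cd[1] / 200 - 1), 0.5)           # surface within a factor 1.5 of 200
  expect_gt(max(cd), 1000 / 1.5)                 # deep densities approach 1000
  expect_gt(cd[length(cd)], 2 * cd[1])           # clear increase with depth
})
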