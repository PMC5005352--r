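# Synthetic-study generator. Emulates the statistical structure the pipeline
# assumes: depth-declining lognormal cell volumes, a coccoid/elongated/
# filamentous morphotype mixture, dimensions back-solved from volume and a
# drawn aspect ratio under each morphotype's shape model, and modality-
# specific observation biases that are the exact inverse of the correction
# cascade. All randomness flows from a single root seed with fixed per-table
# offsets so individual tables regenerate stably.

#' Configuration for a synthetic sediment study
#'
#' Defaults describe an organic-rich sediment column: cell volumes with a
#' lognormal within-sample distribution (geometric standard deviation 2,
#' i.e. ~one order of magnitude spread) whose median declines log-linearly
#' from 0.05 um^3 at the shallowest depth to 0.005 um^3 at the deepest;
#' filaments are rarer (5%) and larger (0.3 -> 0.08 um^3, tighter spread);
#' cell abundance declines log-linearly from 1e10 cells/cm^3 at the surface
#' to 1e8 at 60 mbsf. THAA profiles are anchored to the packaged reference
#' tables with multiplicative lognormal noise.
#'
#' @param depths Sample depths in mbsf.
#' @param n_cells_per_depth Cells generated per depth and modality.
#' @param surface_median_volume,deep_median_volume Median coccoid/elongated
#'   volume (um^3) at the shallowest and deepest depth; the median is
#'   interpolated log-linearly in depth between them.
#' @param volume_gsd Geometric standard deviation of within-sample volumes.
#' @param fractions Named morphotype mixture, summing to 1.
#' @param filament_surface_volume,filament_deep_volume Median filament
#'   volumes at the anchor depths.
#' @param filament_gsd Geometric standard deviation for filament volumes
#'   (default 1.33, ~half an order of magnitude spread).
#' @param coccoid_ar_range,elongated_ar_range,filament_ar_range Uniform
#'   aspect-ratio ranges per morphotype.
#' @param abundance_surface,abundance_deep Cell abundance anchors
#'   (cells/cm^3) at `abundance_depths`.
#' @param abundance_depths Depths (mbsf) of the abundance anchors.
#' @param abundance_gsd Lognormal noise on abundance (1 = none).
#' @param thaa_gsd,composition_gsd Multiplicative lognormal noise on the
#'   THAA anchors and on the mole-percent compositions (1 = exact anchors).
#' @param seed Root integer seed; fixed seed gives bit-identical output.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(depths = c(0.4, 2.75, 4.32, 9.57, 14.55, 20.53, 38.95, 60),
                             n_cells_per_depth = 300,
                             surface_median_volume = 0.05,
                             deep_median_volume = 0.005,
                             volume_gsd = 2,
                             fractions = c(coccoid = 0.45, elongated = 0.50,
                                           filamentous = 0.05),
                             filament_surface_volume = 0.3,
                             filament_deep_volume = 0.08,
                             filament_gsd = 1.33,
                             coccoid_ar_range = c(1, 1.3),
                             elongated_ar_range = c(1.3, 3),
                             filament_ar_range = c(10, 15),
                             abundance_surface = 1e10,
                             abundance_deep = 1e8,
                             abundance_depths = c(0, 60),
                             abundance_gsd = 1,
                             thaa_gsd = 1.15,
                             composition_gsd = 1.05,
                             seed = 1L) {
  cfg <- list(depths = sort(depths), n_cells_per_depth = n_cells_per_depth,
              surface_median_volume = surface_median_volume,
              deep_median_volume = deep_median_volume,
              volume_gsd = volume_gsd, fractions = fractions,
              filament_surface_volume = filament_surface_volume,
              filament_deep_volume = filament_deep_volume,
              filament_gsd = filament_gsd,
              coccoid_ar_range = coccoid_ar_range,
              elongated_ar_range = elongated_ar_range,
              filament_ar_range = filament_ar_range,
              abundance_surface = abundance_surface,
              abundance_deep = abundance_deep,
              abundance_depths = abundance_depths,
              abundance_gsd = abundance_gsd,
              thaa_gsd = thaa_gsd, composition_gsd = composition_gsd,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (length(cfg$depths) < 2L || any(cfg$depths < 0)) {
    stop_configuration("need at least two non-negative depths")
  }
  if (cfg$n_cells_per_depth < 1) stop_configuration("n_cells_per_depth must be >= 1")
  if (cfg$deep_median_volume >= cfg$surface_median_volume) {
    stop_configuration("deep median volume must be below the surface anchor")
  }
  if (cfg$filament_deep_volume >= cfg$filament_surface_volume) {
    stop_configuration("deep filament volume must be below the surface anchor")
  }
  if (!setequal(names(cfg$fractions), MORPHOTYPES) ||
      abs(sum(cfg$fractions) - 1) > 1e-6 || any(cfg$fractions < 0)) {
    stop_configuration("fractions must be named over the morphotypes and sum to 1")
  }
  if (cfg$volume_gsd < 1 || cfg$filament_gsd < 1 || cfg$thaa_gsd < 1 ||
      cfg$composition_gsd < 1 || cfg$abundance_gsd < 1) {
    stop_configuration("geometric standard deviations must be >= 1")
  }
  invisible(cfg)
}

# Log-linear interpolation of a positive quantity between two depth anchors.
log_linear <- function(depth, d0, d1, v0, v1) {
  frac <- (depth - d0) / (d1 - d0)
  10^(log10(v0) + frac * (log10(v1) - log10(v0)))
}

#' Expected median and mean volumes under a generator configuration
#'
#' The configured lognormal median at a depth, per morphotype (coccoid and
#' elongated share the main anchors; filaments have their own), and the
#' corresponding arithmetic mean `median * exp(log(gsd)^2 / 2)`.
#'
#' @param cfg A `generator_config`.
#' @param depth Depth in mbsf (vectorized).
#' @param morphotype Single morphotype.
#' @return Numeric vector of volumes (um^3).
#' @export
expected_median_volume <- function(cfg, depth, morphotype = "coccoid") {
  stopifnot(inherits(cfg, "generator_config"))
  d0 <- min(cfg$depths); d1 <- max(cfg$depths)
  if (morphotype == "filamentous") {
    log_linear(depth, d0, d1, cfg$filament_surface_volume, cfg$filament_deep_volume)
  } else {
    log_linear(depth, d0, d1, cfg$surface_median_volume, cfg$deep_median_volume)
  }
}

#' @rdname expected_median_volume
#' @export
expected_mean_volume <- function(cfg, depth, morphotype = "coccoid") {
  gsd <- if (morphotype == "filamentous") cfg$filament_gsd else cfg$volume_gsd
  expected_median_volume(cfg, depth, morphotype) * exp(log(gsd)^2 / 2)
}

# Back-solve (length, width) from a volume and aspect ratio under the
# morphotype's shape model, so the forward pipeline recovers the volume
# exactly: coccoid cells satisfy sphere(width) = V (length = AR * width is
# cosmetic elongation within the coccoid band); elongated and filamentous
# cells satisfy capsule(AR * W, W) = V.
dims_from_volume <- function(volume, ar, morphotype) {
  width <- ifelse(morphotype == "coccoid",
                  (6 * volume / pi)^(1 / 3),
                  (4 * volume / (pi * (ar - 1 / 3)))^(1 / 3))
  data.frame(length_um = ar * width, width_um = width)
}

#' Generate the true (unobserved) cells of a synthetic study
#'
#' Draws a morphotype for each cell, a true volume from the depth-specific
#' lognormal, and an aspect ratio from the morphotype's range, then
#' back-solves length and width under the morphotype's shape model.
#'
#' @param cfg A `generator_config`.
#' @return Data.frame with `cell_id`, `sample_id`, `depth_mbsf`,
#'   `morphotype`, `volume_true_um3`, `length_um`, `width_um`.
#' @export
generate_true_cells <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    rows <- lapply(seq_along(cfg$depths), function(i) {
      d <- cfg$depths[i]
      n <- cfg$n_cells_per_depth
      morph <- sample(MORPHOTYPES, n, replace = TRUE, prob = cfg$fractions)
      med <- ifelse(morph == "filamentous",
                    expected_median_volume(cfg, d, "filamentous"),
                    expected_median_volume(cfg, d, "coccoid"))
      gsd <- ifelse(morph == "filamentous", cfg$filament_gsd, cfg$volume_gsd)
      vol <- stats::rlnorm(n, meanlog = log(med), sdlog = log(gsd))
      ar_range <- rbind(coccoid = cfg$coccoid_ar_range,
                        elongated = cfg$elongated_ar_range,
                        filamentous = cfg$filament_ar_range)
      ar <- stats::runif(n, ar_range[morph, 1], ar_range[morph, 2])
      dims <- dims_from_volume(vol, ar, morph)
      data.frame(cell_id = sprintf("S%02d_C%04d", i, seq_len(n)),
                 sample_id = sprintf("S%02d", i),
                 depth_mbsf = d, morphotype = morph,
                 volume_true_um3 = vol,
                 length_um = dims$length_um, width_um = dims$width_um,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate biased observation of true cells by a microscopy modality
#'
#' Applies the inverse of the correction cascade: the observed volume is the
#' true volume divided by the composite correction factor of the cell's
#' morphotype under the modality, and the linear dimensions scale by the
#' cube root. Emits the measurement schema consumed by
#' [read_measurements()]; by construction, classify -> volume -> correct
#' recovers the true volumes exactly.
#'
#' @param true_cells Output of [generate_true_cells()].
#' @param modality `"FM"` or `"SEM"` (AFM observation is not modeled).
#' @param table A `correction_table`.
#' @return Measurement data.frame (`cell_id`, `sample_id`, `depth_mbsf`,
#'   `modality`, `length_um`, `width_um`, `height_um` = `NA`).
#' @export
observe_cells <- function(true_cells, modality = c("FM", "SEM"),
                          table = default_correction_table()) {
  modality <- match.arg(modality)
  stopifnot(is.data.frame(true_cells))
  cf <- composite_factor(true_cells$morphotype, modality, table)
  scale <- cf^(-1 / 3)
  data.frame(cell_id = true_cells$cell_id,
             sample_id = true_cells$sample_id,
             depth_mbsf = true_cells$depth_mbsf,
             modality = modality,
             length_um = true_cells$length_um * scale,
             width_um = true_cells$width_um * scale,
             height_um = NA_real_,
             stringsAsFactors = FALSE)
}

#' Generate THAA and composition tables around the packaged anchors
#'
#' Per-sample THAA values are drawn lognormally around the reference
#' anchors; mole-percent compositions are perturbed multiplicatively and
#' renormalized to 100%. With both noise levels at 1 the anchors are
#' reproduced exactly. Anchor depths that coincide with configured study
#' depths inherit that depth's sample id.
#'
#' @param cfg A `generator_config`.
#' @return List with `thaa` and `composition` data.frames (schemas as
#'   [landsort_thaa()] / [landsort_composition()], without the published
#'   carbon column).
#' @export
generate_thaa_profile <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  anchors <- landsort_thaa()
  comp <- landsort_composition()
  idx <- match(anchors$depth_mbsf, cfg$depths)
  ids <- ifelse(is.na(idx), anchors$sample_id, sprintf("S%02d", idx))
  aa_cols <- intersect(names(aa_carbon_registry()), names(comp))
  with_seed(cfg$seed + 1L, {
    thaa <- data.frame(
      sample_id = ids, depth_mbsf = anchors$depth_mbsf,
      thaa_fmol_per_cell = anchors$thaa_fmol_per_cell *
        stats::rlnorm(nrow(anchors), 0, log(cfg$thaa_gsd)),
      thaa_c_fmol_per_cell = anchors$thaa_c_fmol_per_cell *
        stats::rlnorm(nrow(anchors), 0, log(cfg$thaa_gsd)),
      stringsAsFactors = FALSE)
    pct <- as.matrix(comp[, aa_cols])
    noise <- matrix(stats::rlnorm(length(pct), 0, log(cfg$composition_gsd)),
                    nrow = nrow(pct))
    pct <- pct * noise
    pct <- 100 * pct / rowSums(pct)
    composition <- cbind(data.frame(sample_id = ids,
                                    depth_mbsf = comp$depth_mbsf,
                                    stringsAsFactors = FALSE),
                         as.data.frame(pct))
    list(thaa = thaa, composition = composition)
  })
}

#' Generate a cell-abundance depth profile
#'
#' Deterministic log-linear interpolation between the configured abundance
#' anchors, with optional multiplicative lognormal noise.
#'
#' @param cfg A `generator_config`.
#' @return Data.frame with `sample_id`, `depth_mbsf`, `cells_per_cm3`.
#' @export
generate_abundance_profile <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  ab <- log_linear(cfg$depths, cfg$abundance_depths[1], cfg$abundance_depths[2],
                   cfg$abundance_surface, cfg$abundance_deep)
  if (cfg$abundance_gsd > 1) {
    ab <- with_seed(cfg$seed + 2L,
                    ab * stats::rlnorm(length(ab), 0, log(cfg$abundance_gsd)))
  }
  data.frame(sample_id = sprintf("S%02d", seq_along(cfg$depths)),
             depth_mbsf = cfg$depths, cells_per_cm3 = ab,
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic study
#'
#' Generates true cells, FM and SEM observations, THAA/composition tables
#' and an abundance profile from one configuration, optionally writing the
#' tables (`cells_fm.csv`, `cells_sem.csv`, `thaa.csv`, `composition.csv`,
#' `abundance.csv`) and a `manifest.json` recording the configuration.
#'
#' @param cfg A `generator_config`.
#' @param dir Optional output directory (created if needed).
#' @param table Correction table defining the observation biases.
#' @return (Invisibly when writing) list with `true_cells`, `cells_fm`,
#'   `cells_sem`, `thaa`, `composition`, `abundance`, `config`.
#' @export
simulate_study <- function(cfg = generator_config(), dir = NULL,
                           table = default_correction_table()) {
  true_cells <- generate_true_cells(cfg)
  thaa_tabs <- generate_thaa_profile(cfg)
  out <- list(true_cells = true_cells,
              cells_fm = observe_cells(true_cells, "FM", table),
              cells_sem = observe_cells(true_cells, "SEM", table),
              thaa = thaa_tabs$thaa,
              composition = thaa_tabs$composition,
              abundance = generate_abundance_profile(cfg),
              config = unclass(cfg))
  # named vectors serialize as JSON arrays; keep the morphotype names
  out$config$fractions <- as.list(out$config$fractions)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$cells_fm, file.path(dir, "cells_fm.csv"), row.names = FALSE)
    utils::write.csv(out$cells_sem, file.path(dir, "cells_sem.csv"), row.names = FALSE)
    utils::write.csv(out$thaa, file.path(dir, "thaa.csv"), row.names = FALSE)
    utils::write.csv(out$composition, file.path(dir, "composition.csv"), row.names = FALSE)
    utils::write.csv(out$abundance, file.path(dir, "abundance.csv"), row.names = FALSE)
    jsonlite::write_json(out$config, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}
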