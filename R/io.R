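# File I/O and the end-to-end pipeline. Measurement tables use a fixed CSV
# schema with units baked into the column names (_um, _um3, _fmol, _fg) so a
# unit mistake is a schema error, not a silent factor.

MEASUREMENT_COLS <- c("cell_id", "sample_id", "depth_mbsf", "modality",
                      "length_um", "width_um", "height_um")

#' Read and validate a cell-measurement CSV
#'
#' Schema: `cell_id,sample_id,depth_mbsf,modality,length_um,width_um,
#' height_um`; the height field is empty except for AFM rows, where it is
#' required. Dimensions must be positive; rows with `width_um > length_um`
#' are canonicalized (axes swapped) with a warning counting the swaps.
#' Unknown columns are preserved. Violations report the offending rows.
#'
#' @param path Path to a CSV file, or a data.frame already in memory.
#' @return Validated, canonicalized measurement data.frame.
#' @export
read_measurements <- function(path) {
  df <- if (is.data.frame(path)) path else {
    if (!file.exists(path)) stop_schema(sprintf("file not found: %s", path))
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  missing <- setdiff(MEASUREMENT_COLS, names(df))
  if (length(missing)) {
    stop_schema(paste("missing column(s):", paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0L) stop_degenerate_sample("measurement table is empty")
  for (col in c("depth_mbsf", "length_um", "width_um", "height_um")) {
    if (!is.numeric(df[[col]]) && !all(is.na(df[[col]]))) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))) & !is.na(df[[col]]))
      stop_schema(sprintf("non-numeric value in '%s' at row(s) %s", col,
                          paste(utils::head(bad, 5), collapse = ", ")))
    }
    df[[col]] <- as.numeric(df[[col]])
  }
  bad_mod <- which(!df$modality %in% MODALITIES)
  if (length(bad_mod)) {
    stop_schema(sprintf("unknown modality at row(s) %s",
                        paste(utils::head(bad_mod, 5), collapse = ", ")))
  }
  bad_dim <- which(!is.finite(df$length_um) | df$length_um <= 0 |
                   !is.finite(df$width_um) | df$width_um <= 0 |
                   !is.finite(df$depth_mbsf) | df$depth_mbsf < 0)
  if (length(bad_dim)) {
    stop_schema(sprintf(
      "non-positive or missing dimension/depth at row(s) %s",
      paste(utils::head(bad_dim, 5), collapse = ", ")))
  }
  afm <- df$modality == "AFM"
  if (any(afm & (is.na(df$height_um) | df$height_um <= 0))) {
    bad <- which(afm & (is.na(df$height_um) | df$height_um <= 0))
    stop_schema(sprintf("AFM row(s) without a positive height_um: %s",
                        paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (any(!afm & !is.na(df$height_um))) {
    bad <- which(!afm & !is.na(df$height_um))
    stop_schema(sprintf("height_um set on non-AFM row(s): %s",
                        paste(utils::head(bad, 5), collapse = ", ")))
  }
  swap <- df$width_um > df$length_um
  if (any(swap)) {
    tmp <- df$length_um[swap]
    df$length_um[swap] <- df$width_um[swap]
    df$width_um[swap] <- tmp
    warning(sprintf("canonicalized %d row(s) with width_um > length_um", sum(swap)))
  }
  df
}

#' Write per-sample summaries to CSV
#'
#' @param path Output CSV path.
#' @param summaries A `sample_summary` or list of them (see
#'   [summarize_samples()]).
#' @return The flattened data.frame, invisibly.
#' @export
write_summary <- function(path, summaries) {
  df <- summaries_to_df(summaries)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Run the full morphometry-to-biomass pipeline
#'
#' Orchestrates the analysis stages: validate measurements, classify
#' morphotypes, compute raw biovolumes, apply the correction cascade,
#' summarize samples, convert THAA to cell carbon, and combine both branches
#' into carbon densities and (when abundance is given) sediment-integrated
#' carbon. Deterministic given its inputs.
#'
#' @param measurements Measurement CSV path or data.frame (may be `NULL` to
#'   run the carbon branch alone).
#' @param thaa,composition THAA and composition tables (paths or
#'   data.frames; see [carbon_table()]); `NULL` skips the carbon branch.
#' @param abundance Optional abundance table with `depth_mbsf` and
#'   `cells_per_cm3`.
#' @param correction_table A `correction_table`.
#' @param coccoid_max_ar,filament_min_ar Classification thresholds.
#' @param aa_c_fraction Amino-acid carbon share of total cell carbon.
#' @param output_dir Optional directory: writes `cells.csv`, `summary.csv`,
#'   `carbon.csv` and a `results.json` document with the parameters and
#'   factor set used.
#' @return A `pipeline_result` list: `cells` (augmented measurement table),
#'   `summaries` (list of `sample_summary`), `summary_table`, `carbon`
#'   (per-sample carbon table with `carbon_density_fg_um3` and
#'   `sediment_c_ug_cm3` where computable), and `params`.
#' @export
run_pipeline <- function(measurements = NULL, thaa = NULL, composition = NULL,
                         abundance = NULL,
                         correction_table = default_correction_table(),
                         coccoid_max_ar = 1.3, filament_min_ar = 10,
                         aa_c_fraction = 0.55, output_dir = NULL) {
  as_table <- function(x) {
    if (is.null(x) || is.data.frame(x)) x else utils::read.csv(x, stringsAsFactors = FALSE)
  }
  cells <- NULL
  summaries <- NULL
  summary_table <- NULL
  if (!is.null(measurements)) {
    cells <- read_measurements(measurements)
    cells <- classify_cells(cells, coccoid_max_ar, filament_min_ar)
    cells <- cell_volume(cells)
    cells <- correct_cells(cells, correction_table)
    summaries <- summarize_samples(cells)
    summary_table <- summaries_to_df(summaries)
  }
  carbon <- NULL
  if (!is.null(thaa)) {
    if (is.null(composition)) {
      stop_configuration("a composition table is required with THAA data")
    }
    carbon <- carbon_table(as_table(thaa), as_table(composition), aa_c_fraction)
    carbon$carbon_density_fg_um3 <- NA_real_
    if (!is.null(summaries)) {
      for (i in seq_len(nrow(carbon))) {
        s <- summaries[[carbon$sample_id[i]]]
        if (!is.null(s)) {
          carbon$carbon_density_fg_um3[i] <-
            carbon$total_c_fg[i] / s$weighted_mean_volume
        }
      }
    }
    carbon$sediment_c_ug_cm3 <- NA_real_
    ab <- as_table(abundance)
    if (!is.null(ab)) {
      j <- match(carbon$depth_mbsf, ab$depth_mbsf)
      ok <- !is.na(j)
      carbon$sediment_c_ug_cm3[ok] <-
        total_sediment_carbon(carbon$total_c_fg[ok], ab$cells_per_cm3[j[ok]])
    }
  }
  params <- list(aa_c_fraction = aa_c_fraction,
                 coccoid_max_ar = coccoid_max_ar,
                 filament_min_ar = filament_min_ar,
                 correction_factors = correction_table$factors,
                 applicability = correction_table$applicability)
  result <- structure(list(cells = cells, summaries = summaries,
                           summary_table = summary_table, carbon = carbon,
                           params = params),
                      class = "pipeline_result")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    ok <- FALSE
    written <- character(0)
    on.exit(if (!ok) unlink(written))
    wr <- function(obj, name) {
      p <- file.path(output_dir, name)
      utils::write.csv(obj, p, row.names = FALSE)
      written <<- c(written, p)
    }
    if (!is.null(cells)) wr(cells, "cells.csv")
    if (!is.null(summary_table)) wr(summary_table, "summary.csv")
    if (!is.null(carbon)) wr(carbon, "carbon.csv")
    doc <- list(params = list(aa_c_fraction = aa_c_fraction,
                              coccoid_max_ar = coccoid_max_ar,
                              filament_min_ar = filament_min_ar),
                correction_factors = as.data.frame(correction_table$factors),
                applicability = correction_table$applicability,
                n_cells = if (is.null(cells)) 0L else nrow(cells),
                n_samples = if (is.null(summaries)) 0L else length(summaries))
    p <- file.path(output_dir, "results.json")
    jsonlite::write_json(doc, p, auto_unbox = TRUE, digits = NA)
    written <- c(written, p)
    ok <- TRUE
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("cellcarbon pipeline result\n")
  if (!is.null(x$cells)) {
    cat(sprintf("  %d cells in %d sample(s)\n", nrow(x$cells),
                length(unique(x$cells$sample_id))))
  }
  if (!is.null(x$carbon)) {
    cat(sprintf("  carbon estimates for %d sample(s); total C %.3g-%.3g fg/cell\n",
                nrow(x$carbon), min(x$carbon$total_c_fg), max(x$carbon$total_c_fg)))
  }
  invisible(x)
}
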