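# THAA -> carbon conversion. Total hydrolyzable amino acids (THAA, fmol per
# cell) are converted to amino-acid carbon (THAA-C, fmol C per cell) by
# weighting each analyte's mole fraction with its carbon-atom count, then
# scaled to whole-cell carbon under the assumption that amino acids hold a
# fixed share (default 55%) of total cell carbon. Dividing cell carbon by the
# morphotype-weighted mean biovolume gives the cell-specific carbon density.

CARBON_MOLAR_MASS <- 12.011  # g mol^-1; fmol C * g mol^-1 = fg C

#' Carbon atoms per hydrolyzable amino-acid residue
#'
#' Standard free-amino-acid carbon counts for the 18 analytes quantified by
#' OPA-derivatization HPLC of cell hydrolyzates (free-residue stoichiometry:
#' acid hydrolysis restores the water lost on peptide-bond formation).
#' Includes the non-protein amino acids beta-alanine (`bAla`), taurine
#' (`Tau`), gamma-aminobutyric acid (`gAba`) and ornithine (`Orn`), which are
#' part of the analytical window even where not detected.
#'
#' @return Named integer vector: carbon atoms per residue.
#' @examples
#' aa_carbon_registry()[["Gly"]]  # 2
#' @export
aa_carbon_registry <- function() {
  c(Asp = 4L, Glu = 5L, Ser = 3L, His = 6L, Gly = 2L, Thr = 4L,
    Arg = 6L, bAla = 3L, Tau = 2L, Ala = 3L, gAba = 4L, Tyr = 9L,
    Val = 5L, Phe = 9L, Ile = 6L, Leu = 6L, Orn = 5L, Lys = 6L)
}

#' Normalize an amino-acid mole-percent composition
#'
#' Rescales a non-negative mole-percent (or mole-fraction) vector to sum to
#' exactly 1 while preserving relative proportions. Analytes reported "not
#' detected" should be present with value 0.
#'
#' @param composition Named non-negative numeric vector.
#' @return Named numeric vector of mole fractions summing to 1.
#' @examples
#' normalize_composition(c(Gly = 50, Ala = 50))
#' @export
normalize_composition <- function(composition) {
  if (!is.numeric(composition) || is.null(names(composition)) ||
      any(!is.finite(composition)) || any(composition < 0)) {
    stop_invalid_composition("composition must be a named, finite, non-negative vector")
  }
  total <- sum(composition)
  if (total <= 0) stop_invalid_composition("composition sums to zero")
  composition / total
}

#' Composition-weighted mean carbon atoms per residue
#'
#' \eqn{\bar{n}_C = \sum_i f_i \, n_{C,i}} over the normalized mole fractions
#' \eqn{f_i} and per-residue carbon counts \eqn{n_{C,i}}. Bounded by 2 (pure
#' glycine) and 9 (pure tyrosine/phenylalanine) for any valid composition.
#'
#' @inheritParams normalize_composition
#' @param registry Named carbon-count vector (default [aa_carbon_registry()]).
#' @return Mean carbon atoms per amino-acid residue.
#' @export
mean_carbon_atoms_per_residue <- function(composition, registry = aa_carbon_registry()) {
  f <- normalize_composition(composition)
  missing <- setdiff(names(f), names(registry))
  if (length(missing)) {
    stop_configuration(paste("analytes missing from carbon registry:",
                             paste(missing, collapse = ", ")))
  }
  sum(f * registry[names(f)])
}

#' Convert THAA to amino-acid carbon
#'
#' @param thaa THAA in fmol per cell, `>= 0`.
#' @param mean_c Mean carbon atoms per residue (see
#'   [mean_carbon_atoms_per_residue()]).
#' @return THAA-C in fmol carbon per cell.
#' @export
thaa_to_thaa_c <- function(thaa, mean_c) {
  if (!is.numeric(thaa) || any(!is.finite(thaa)) || any(thaa < 0)) {
    stop_invalid_measurement("'thaa' must be non-negative and finite")
  }
  thaa * mean_c
}

#' Total cell carbon from amino-acid carbon
#'
#' \eqn{C_{cell} = \mathrm{THAA\text{-}C} \times 12.011 / f_{AA}} where
#' \eqn{f_{AA}} is the assumed share of total cell carbon held in amino
#' acids. The default 0.55 follows culture-based macromolecular budgets;
#' 0.40 and 0.75 are useful sensitivity settings. fmol C x (g/mol) = fg C.
#'
#' @param thaa_c THAA-C in fmol carbon per cell, `>= 0`.
#' @param aa_c_fraction Amino-acid carbon as a fraction of total cell carbon,
#'   in `(0, 1]` (default 0.55).
#' @return Total carbon in fg per cell (unrounded).
#' @examples
#' total_cell_carbon(0.88)        # ~19 fg C per cell
#' total_cell_carbon(0.78, 0.40)  # sensitivity case, ~23 fg
#' @export
total_cell_carbon <- function(thaa_c, aa_c_fraction = 0.55) {
  if (!is.numeric(thaa_c) || any(!is.finite(thaa_c)) || any(thaa_c < 0)) {
    stop_invalid_measurement("'thaa_c' must be non-negative and finite")
  }
  if (!is.numeric(aa_c_fraction) || length(aa_c_fraction) != 1L ||
      !is.finite(aa_c_fraction) || aa_c_fraction <= 0 || aa_c_fraction > 1) {
    stop_configuration("'aa_c_fraction' must lie in (0, 1]")
  }
  thaa_c * CARBON_MOLAR_MASS / aa_c_fraction
}

#' Cell-specific carbon density
#'
#' Divides the cell-specific carbon content by the morphotype-weighted mean
#' cell volume:
#' \deqn{C_d = \frac{C_{cell}}{\sum_m \bar{V}_m f_m}}
#' over the morphotype fractions \eqn{f_m} and per-morphotype mean volumes
#' \eqn{\bar{V}_m}. High values indicate "packed", low-water cells.
#'
#' @param total_c Total carbon in fg per cell.
#' @param fractions Named morphotype fractions summing to 1 (tolerance 1e-6).
#' @param mean_volumes Named mean volumes (cubic micrometers) for the same
#'   morphotypes; must be `> 0` wherever the fraction is nonzero.
#' @return Carbon density in fg C per cubic micrometer.
#' @examples
#' carbon_density(19, c(coccoid = 0.6, elongated = 0.35, filamentous = 0.05),
#'                c(coccoid = 0.05, elongated = 0.1, filamentous = 0.3))
#' @export
carbon_density <- function(total_c, fractions, mean_volumes) {
  if (abs(sum(fractions) - 1) > 1e-6) {
    stop_invalid_fractions("morphotype fractions must sum to 1")
  }
  if (is.null(names(fractions)) || !all(names(fractions) %in% names(mean_volumes))) {
    stop_configuration("'fractions' and 'mean_volumes' must share morphotype names")
  }
  v <- mean_volumes[names(fractions)]
  active <- fractions > 0
  if (any(!is.finite(v[active])) || any(v[active] <= 0)) {
    stop_invalid_measurement("mean volumes must be > 0 for morphotypes with nonzero fraction")
  }
  denom <- sum(fractions[active] * v[active])
  if (denom <= 0) stop_degenerate_sample("weighted mean volume is zero")
  total_c / denom
}

#' Sediment-integrated microbial carbon
#'
#' @param total_c Cell-specific carbon in fg per cell.
#' @param abundance Cell abundance in cells per cubic centimeter of sediment,
#'   `>= 0`.
#' @return Microbial carbon in micrograms per cubic centimeter of sediment
#'   (fg -> ug is a factor 1e-9).
#' @export
total_sediment_carbon <- function(total_c, abundance) {
  if (!is.numeric(abundance) || any(!is.finite(abundance)) || any(abundance < 0)) {
    stop_invalid_measurement("'abundance' must be non-negative and finite")
  }
  total_c * abundance * 1e-9
}

#' Cell extraction efficiency
#'
#' Percentage of the total sediment cell population recovered in a
#' density-gradient cell extract. Values above 100% are possible with
#' independent counts and are returned with a warning.
#'
#' @param extracted Extracted cells per cubic centimeter, `>= 0`.
#' @param total Total cells per cubic centimeter, `> 0`.
#' @return Efficiency in percent.
#' @export
extraction_efficiency <- function(extracted, total) {
  if (!is.numeric(extracted) || any(!is.finite(extracted)) || any(extracted < 0)) {
    stop_invalid_measurement("'extracted' must be non-negative and finite")
  }
  if (!is.numeric(total) || any(!is.finite(total)) || any(total <= 0)) {
    stop_degenerate_sample("'total' must be > 0")
  }
  eff <- 100 * extracted / total
  if (any(eff > 100)) {
    warning("extraction efficiency above 100%; check the paired counts")
  }
  eff
}

#' Per-sample carbon table from THAA and composition tables
#'
#' Runs the full conversion for a table of per-sample THAA measurements and
#' matching amino-acid compositions: normalized composition -> mean carbon
#' atoms per residue -> THAA-C -> total carbon.
#'
#' @param thaa Data.frame with columns `sample_id`, `depth_mbsf`,
#'   `thaa_fmol_per_cell`, and optionally `thaa_c_fmol_per_cell` (measured
#'   THAA-C; used directly for the carbon scaling when present, with the
#'   composition-derived value reported alongside).
#' @param composition Data.frame with `sample_id`, `depth_mbsf` and one
#'   column per amino acid (mole percent; names as in [aa_carbon_registry()]).
#' @param aa_c_fraction See [total_cell_carbon()].
#' @param registry See [mean_carbon_atoms_per_residue()].
#' @return Data.frame with columns `sample_id`, `depth_mbsf`, `thaa_fmol`,
#'   `mean_c_atoms`, `thaa_c_fmol` (the value used for scaling),
#'   `thaa_c_fmol_derived` (from the composition), `total_c_fg`.
#' @export
carbon_table <- function(thaa, composition, aa_c_fraction = 0.55,
                         registry = aa_carbon_registry()) {
  stopifnot(is.data.frame(thaa), is.data.frame(composition))
  need <- c("sample_id", "depth_mbsf", "thaa_fmol_per_cell")
  if (!all(need %in% names(thaa))) {
    stop_schema(paste("thaa table needs columns:", paste(need, collapse = ", ")))
  }
  aa_cols <- intersect(names(registry), names(composition))
  if (length(aa_cols) == 0L) {
    stop_schema("composition table has no recognized amino-acid columns")
  }
  idx <- match(thaa$sample_id, composition$sample_id)
  if (any(is.na(idx))) {
    stop_schema("every THAA sample needs a matching composition row")
  }
  mean_c <- vapply(idx, function(i) {
    row <- unlist(composition[i, aa_cols])
    s <- sum(row)
    if (s < 95 || s > 105) {
      warning(sprintf("composition for sample '%s' sums to %.1f mole %%",
                      composition$sample_id[i], s))
    }
    mean_carbon_atoms_per_residue(row, registry)
  }, numeric(1))
  thaa_c_derived <- thaa_to_thaa_c(thaa$thaa_fmol_per_cell, mean_c)
  thaa_c <- if (!is.null(thaa$thaa_c_fmol_per_cell)) {
    thaa$thaa_c_fmol_per_cell
  } else {
    thaa_c_derived
  }
  data.frame(
    sample_id = thaa$sample_id,
    depth_mbsf = thaa$depth_mbsf,
    thaa_fmol = thaa$thaa_fmol_per_cell,
    mean_c_atoms = mean_c,
    thaa_c_fmol = thaa_c,
    thaa_c_fmol_derived = thaa_c_derived,
    total_c_fg = total_cell_carbon(thaa_c, aa_c_fraction),
    row.names = NULL)
}

#' Packaged Landsort Deep reference tables
#'
#' Transcriptions of the study's per-sample THAA measurements (seven samples,
#' 0.4-38.95 mbsf: THAA, THAA-C and the published rounded total carbon) and
#' the matching amino-acid mole-percent compositions. Analytes below
#' detection (bAla, Tau, gAba, Orn) are stored as 0.
#'
#' @return A data.frame (see [carbon_table()] for the column contract).
#' @export
landsort_thaa <- function() {
  read_packaged_csv("landsort_thaa.csv")
}

#' @rdname landsort_thaa
#' @export
landsort_composition <- function() {
  read_packaged_csv("landsort_composition.csv")
}

read_packaged_csv <- function(name) {
  path <- system.file("extdata", name, package = "cellcarbon", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
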