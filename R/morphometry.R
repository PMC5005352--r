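# Morphotype classification and uncorrected biovolume computation.
#
# Cells are grouped into three morphotypes by their length-to-width aspect
# ratio: coccoid (sphere-like, AR near 1), elongated (rods and prolate
# spheroids), and filamentous (AR of 10 or more). Volumes are computed under
# simple solid-of-revolution shape models; all models are homogeneous of
# degree 3 in the linear dimensions.

#' Morphotype and modality vocabularies
#'
#' Closed enumerations used throughout the package: the three cell
#' morphotypes and the three imaging modalities (epifluorescence microscopy,
#' scanning electron microscopy, atomic force microscopy).
#'
#' @format Character vectors.
#' @export
MORPHOTYPES <- c("coccoid", "elongated", "filamentous")

#' @rdname MORPHOTYPES
#' @export
MODALITIES <- c("FM", "SEM", "AFM")

check_positive <- function(x, what) {
  if (length(x) == 0L || !is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_invalid_measurement(sprintf(
      "'%s' must be strictly positive and finite", what))
  }
  invisible(x)
}

#' Classify cells into morphotypes by aspect ratio
#'
#' Computes the orientation-agnostic aspect ratio
#' `AR = max(length, width) / min(length, width)` and assigns
#' `"filamentous"` when `AR >= filament_min_ar`, `"coccoid"` when
#' `AR <= coccoid_max_ar`, and `"elongated"` otherwise. Rod-shaped and
#' prolate-spheroid cells are deliberately pooled as elongated.
#'
#' @param length,width Cell dimensions in micrometers; vectors are recycled
#'   to common length. Orientation does not matter.
#' @param coccoid_max_ar Largest aspect ratio still counted as coccoid
#'   (default 1.3). The coccoid/elongated boundary is a convention, exposed
#'   here so its sensitivity can be examined.
#' @param filament_min_ar Smallest aspect ratio counted as filamentous
#'   (default 10).
#' @return Character vector of morphotypes (see [MORPHOTYPES]).
#' @examples
#' classify_morphotype(c(0.5, 1.0, 6.0), c(0.5, 0.5, 0.5))
#' @export
classify_morphotype <- function(length, width, coccoid_max_ar = 1.3,
                                filament_min_ar = 10) {
  check_positive(length, "length")
  check_positive(width, "width")
  if (coccoid_max_ar < 1) {
    stop_configuration("'coccoid_max_ar' must be >= 1")
  }
  if (filament_min_ar <= coccoid_max_ar) {
    stop_configuration("'filament_min_ar' must exceed 'coccoid_max_ar'")
  }
  ar <- pmax(length, width) / pmin(length, width)
  out <- rep("elongated", length(ar))
  out[ar <= coccoid_max_ar] <- "coccoid"
  out[ar >= filament_min_ar] <- "filamentous"
  out
}

#' Biovolume shape models
#'
#' Geometric volumes (cubic micrometers) of the standard microbial cell
#' shape models from linear dimensions in micrometers:
#' \describe{
#'   \item{`volume_sphere`}{\eqn{V = \pi/6 \, d^3} for cocci, using the cell
#'     width as diameter.}
#'   \item{`volume_capsule`}{cylinder of width \eqn{W} with hemispherical
#'     caps, \eqn{V = (\pi/4) W^2 (L - W/3)}, for rods and filaments; equals
#'     the sphere when \eqn{L = W}.}
#'   \item{`volume_prolate_spheroid`}{\eqn{V = (\pi/6) L W^2}; equals the
#'     sphere when \eqn{L = W} and is always below the capsule for
#'     \eqn{L > W}.}
#'   \item{`volume_ellipsoid`}{\eqn{V = (\pi/6) L W H}, used when an
#'     independent height is available (AFM); reduces to the prolate
#'     spheroid when \eqn{H = W}.}
#' }
#'
#' @param diameter,length,width,height Dimensions in micrometers, strictly
#'   positive. `length` must be >= `width` unless `canonicalize = TRUE`.
#' @param canonicalize If `TRUE`, swap length and width where width exceeds
#'   length instead of raising an error.
#' @return Numeric vector of volumes in cubic micrometers.
#' @examples
#' volume_sphere(1)                 # pi/6
#' volume_capsule(2, 1)
#' volume_prolate_spheroid(2, 1)
#' volume_ellipsoid(2, 1, 0.5)
#' @export
volume_sphere <- function(diameter) {
  check_positive(diameter, "diameter")
  pi / 6 * diameter^3
}

canonicalize_lw <- function(length, width, canonicalize, where) {
  bad <- length < width
  if (any(bad)) {
    if (!canonicalize) {
      stop_invalid_measurement(sprintf(
        "%s: length < width for %d cell(s); set canonicalize = TRUE to swap",
        where, sum(bad)))
    }
    tmp <- length[bad]
    length[bad] <- width[bad]
    width[bad] <- tmp
  }
  list(length = length, width = width)
}

#' @rdname volume_sphere
#' @export
volume_capsule <- function(length, width, canonicalize = FALSE) {
  check_positive(length, "length")
  check_positive(width, "width")
  lw <- canonicalize_lw(length, width, canonicalize, "volume_capsule")
  (pi / 4) * lw$width^2 * (lw$length - lw$width / 3)
}

#' @rdname volume_sphere
#' @export
volume_prolate_spheroid <- function(length, width, canonicalize = FALSE) {
  check_positive(length, "length")
  check_positive(width, "width")
  lw <- canonicalize_lw(length, width, canonicalize, "volume_prolate_spheroid")
  (pi / 6) * lw$length * lw$width^2
}

#' @rdname volume_sphere
#' @export
volume_ellipsoid <- function(length, width, height) {
  check_positive(length, "length")
  check_positive(width, "width")
  if (any(is.na(height))) {
    stop_invalid_measurement("'height' is missing; ellipsoid volumes need a measured height")
  }
  check_positive(height, "height")
  (pi / 6) * length * width * height
}

#' Add morphotype assignments to a measurement table
#'
#' @param cells Measurement data.frame with columns `length_um` and
#'   `width_um` (see [read_measurements()] for the full schema).
#' @inheritParams classify_morphotype
#' @return `cells` with a `morphotype` column appended (replaced if present).
#' @export
classify_cells <- function(cells, coccoid_max_ar = 1.3, filament_min_ar = 10) {
  stopifnot(is.data.frame(cells))
  if (nrow(cells) == 0L) stop_degenerate_sample("empty measurement table")
  cells$morphotype <- classify_morphotype(cells$length_um, cells$width_um,
                                          coccoid_max_ar, filament_min_ar)
  cells
}

shape_for <- function(morphotype, modality, has_height) {
  shape <- ifelse(morphotype == "coccoid", "sphere", "capsule")
  shape[modality == "AFM" & has_height] <- "ellipsoid"
  shape
}

#' Uncorrected biovolumes for a measurement table
#'
#' Dispatches each cell to a shape model and computes its raw (as-observed,
#' uncorrected) biovolume. Default dispatch: coccoid cells are spheres with
#' the width as diameter; elongated and filamentous cells are capsules; AFM
#' measurements with a height use the general ellipsoid. A single shape can
#' be forced for all cells via `shape`.
#'
#' @param cells Measurement data.frame carrying a `morphotype` column (see
#'   [classify_cells()]).
#' @param shape Optional single shape model, one of `"sphere"`, `"capsule"`,
#'   `"prolate_spheroid"`, `"ellipsoid"`, overriding the dispatch.
#' @return `cells` with `shape_model` and `volume_raw_um3` columns appended.
#' @export
cell_volume <- function(cells, shape = NULL) {
  stopifnot(is.data.frame(cells))
  if (is.null(cells$morphotype)) {
    stop_invalid_measurement("cells must be classified first (see classify_cells)")
  }
  has_height <- if (is.null(cells$height_um)) rep(FALSE, nrow(cells)) else !is.na(cells$height_um)
  if (is.null(shape)) {
    shp <- shape_for(cells$morphotype, cells$modality, has_height)
  } else {
    shape <- match.arg(shape, c("sphere", "capsule", "prolate_spheroid", "ellipsoid"))
    if (shape == "ellipsoid" && !all(has_height)) {
      stop_invalid_measurement("ellipsoid model requires a height for every cell")
    }
    shp <- rep(shape, nrow(cells))
  }
  v <- numeric(nrow(cells))
  for (s in unique(shp)) {
    i <- shp == s
    v[i] <- switch(s,
      sphere = volume_sphere(cells$width_um[i]),
      capsule = volume_capsule(cells$length_um[i], cells$width_um[i]),
      prolate_spheroid = volume_prolate_spheroid(cells$length_um[i], cells$width_um[i]),
      ellipsoid = volume_ellipsoid(cells$length_um[i], cells$width_um[i], cells$height_um[i]))
  }
  cells$shape_model <- shp
  cells$volume_raw_um3 <- v
  cells
}
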