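#' Two-chamber transwell geometry
#'
#' Describes the one-dimensional computational domain of a Boyden transwell
#' assay: two chambers joined at a semi-permeable membrane, an extracellular
#' matrix (ECM) layer coating the insert, and the sub-region into which
#' DNase I is injected. Coordinates are dimensionless; the physical chamber
#' depth is mapped onto `[x_min, x_max]`. By convention the *lower* chamber
#' (where neutrophils are seeded) is `[x_min, x_membrane)` and the *upper*
#' chamber (where tumor cells start) is `(x_membrane, x_max]`, so simulated
#' profiles read left = lower well, right = upper well.
#'
#' @param x_min,x_max Domain bounds (default `0`, `1`).
#' @param x_membrane Membrane position; must lie strictly inside the domain
#'   and coincide with a mesh face (default `0.5`).
#' @param ecm_interval Closed interval occupied by the ECM layer; must
#'   contain the membrane in its interior (default `c(0.35, 0.65)`).
#' @param injection_interval Interval where the DNase I source acts.
#'   Defaults to the whole lower chamber, matching the experimental protocol
#'   of adding DNase I to the lower well.
#'
#' @return An object of class `transwell_geometry`.
#' @examples
#' geom <- transwell_geometry()
#' grid <- build_grid(geom, h = 0.01)
#' sum(region_mask(grid, geom$ecm_interval))  # 30 cells carry ECM
#' @export
transwell_geometry <- function(x_min = 0, x_max = 1, x_membrane = 0.5,
                               ecm_interval = c(0.35, 0.65),
                               injection_interval = NULL) {
  stopifnot(is.numeric(x_min), is.numeric(x_max), is.numeric(x_membrane))
  if (!(x_min < x_membrane && x_membrane < x_max)) {
    stop("membrane position must satisfy x_min < x_membrane < x_max", call. = FALSE)
  }
  ecm_interval <- as.numeric(ecm_interval)
  if (length(ecm_interval) != 2L || ecm_interval[1] >= ecm_interval[2]) {
    stop("ecm_interval must be an increasing interval c(a, b)", call. = FALSE)
  }
  if (ecm_interval[1] < x_min || ecm_interval[2] > x_max) {
    stop("ecm_interval must lie within [x_min, x_max]", call. = FALSE)
  }
  if (!(ecm_interval[1] < x_membrane && x_membrane < ecm_interval[2])) {
    stop("ecm_interval must contain the membrane in its interior", call. = FALSE)
  }
  if (is.null(injection_interval)) injection_interval <- c(x_min, x_membrane)
  injection_interval <- as.numeric(injection_interval)
  if (length(injection_interval) != 2L ||
      injection_interval[1] > injection_interval[2] ||
      injection_interval[1] < x_min || injection_interval[2] > x_max) {
    stop("injection_interval must be an interval within [x_min, x_max]", call. = FALSE)
  }
  structure(
    list(x_min = x_min, x_max = x_max, x_membrane = x_membrane,
         ecm_interval = ecm_interval, injection_interval = injection_interval),
    class = "transwell_geometry"
  )
}

#' @export
print.transwell_geometry <- function(x, ...) {
  cat("<transwell_geometry>\n")
  cat(sprintf("  domain   : [%g, %g], membrane at %g\n", x$x_min, x$x_max, x$x_membrane))
  cat(sprintf("  ECM layer: [%g, %g]\n", x$ecm_interval[1], x$ecm_interval[2]))
  cat(sprintf("  injection: [%g, %g]\n", x$injection_interval[1], x$injection_interval[2]))
  invisible(x)
}

#' Build the uniform finite-volume mesh
#'
#' Partitions the domain into cells of width `h` with the membrane lying
#' exactly on a cell face (the membrane is a zero-thickness interface between
#' two cells, never inside one). Fields live at cell centers; fluxes live at
#' faces.
#'
#' @param geometry A [transwell_geometry()].
#' @param h Cell width; `(x_max - x_min)/h` and `(x_membrane - x_min)/h`
#'   must both be integers.
#' @return An object of class `transwell_grid` with elements `h`,
#'   `cell_centers`, `face_coordinates`, `membrane_face_index` (1-based index
#'   into `face_coordinates`), `n_cells` and the originating `geometry`.
#' @export
build_grid <- function(geometry, h = 0.01) {
  stopifnot(inherits(geometry, "transwell_geometry"), is.numeric(h), h > 0)
  len <- geometry$x_max - geometry$x_min
  ncell <- len / h
  if (abs(ncell - round(ncell)) > 1e-9 * max(1, ncell)) {
    stop(sprintf("domain length %g is not an integer multiple of h = %g", len, h),
         call. = FALSE)
  }
  ncell <- as.integer(round(ncell))
  mpos <- (geometry$x_membrane - geometry$x_min) / h
  if (abs(mpos - round(mpos)) > 1e-9 * max(1, mpos)) {
    stop(sprintf("membrane offset %g is not an integer multiple of h = %g",
                 geometry$x_membrane - geometry$x_min, h), call. = FALSE)
  }
  faces <- geometry$x_min + h * seq(0L, ncell)
  structure(
    list(h = h,
         n_cells = ncell,
         cell_centers = (faces[-1] + faces[-length(faces)]) / 2,
         face_coordinates = faces,
         membrane_face_index = as.integer(round(mpos)) + 1L,
         geometry = geometry),
    class = "transwell_grid"
  )
}

#' @export
print.transwell_grid <- function(x, ...) {
  cat(sprintf("<transwell_grid> %d cells, h = %g, membrane face #%d (x = %g)\n",
              x$n_cells, x$h, x$membrane_face_index,
              x$face_coordinates[x$membrane_face_index]))
  invisible(x)
}

#' Per-cell indicator of an interval
#'
#' Returns 1 for cells whose *center* lies in the interval, 0 otherwise
#' (cell-center membership; a half-open convention at shared cell boundaries
#' is implied because centers never coincide with faces on a uniform mesh).
#'
#' @param grid A [build_grid()] mesh.
#' @param interval Numeric interval `c(a, b)` (possibly empty, `a > b` gives
#'   all zeros).
#' @return Numeric vector of 0/1 of length `grid$n_cells`.
#' @export
region_mask <- function(grid, interval) {
  stopifnot(inherits(grid, "transwell_grid"))
  interval <- as.numeric(interval)
  stopifnot(length(interval) == 2L)
  as.numeric(grid$cell_centers >= interval[1] & grid$cell_centers <= interval[2])
}

#' Chamber masks
#'
#' Indicators of the lower (`[x_min, x_membrane)`) and upper
#' (`(x_membrane, x_max]`) chambers. Every cell belongs to exactly one
#' chamber because the membrane coincides with a face.
#'
#' @param grid A [build_grid()] mesh.
#' @return Numeric 0/1 vector of length `grid$n_cells`.
#' @export
lower_chamber_mask <- function(grid) {
  as.numeric(grid$cell_centers < grid$geometry$x_membrane)
}

#' @rdname lower_chamber_mask
#' @export
upper_chamber_mask <- function(grid) {
  as.numeric(grid$cell_centers > grid$geometry$x_membrane)
}
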