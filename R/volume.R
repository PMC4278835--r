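#' A 3D CT volume in Hounsfield units
#'
#' Wraps a numeric 3D array of attenuation values together with its voxel
#' spacing. Values are assumed to be calibrated Hounsfield units (HU); any
#' storage scaling (slope/intercept) must already have been applied, which
#' [read_ct_series()] does at read time.
#'
#' @param values Numeric 3D array of attenuation values (HU).
#' @param spacing Numeric vector of length 3, millimetres per voxel along
#'   x, y, z. Must be strictly positive.
#'
#' @return An object of class `ct_volume` with elements `values` and
#'   `spacing`.
#'
#' @examples
#' v <- ct_volume(array(40, dim = c(4, 4, 2)), spacing = c(0.8, 0.8, 1))
#' dim(v$values)
#' @export
ct_volume <- function(values, spacing = c(1, 1, 1)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3D array", call. = FALSE)
  }
  if (any(dim(values) < 1L)) {
    stop("all extents must be >= 1", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive numbers (mm)", call. = FALSE)
  }
  # normalise to a bare double array (drops any reader-specific attributes)
  values <- array(as.double(values), dim = dim(values))
  structure(list(values = values, spacing = spacing), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  rng <- suppressWarnings(range(x$values, finite = TRUE))
  if (all(is.finite(rng))) cat(sprintf("  HU range: [%.1f, %.1f]\n", rng[1], rng[2]))
  invisible(x)
}

#' Extents of a volume
#'
#' @param volume A [ct_volume()].
#' @return Integer vector `(nx, ny, nz)`.
#' @export
extents <- function(volume) {
  stopifnot(inherits(volume, "ct_volume"))
  dim(volume$values)
}

#' An ordered 4D CT acquisition (one 3D volume per cardiac phase)
#'
#' Phases are stored in acquisition order; phase numbers are reported
#' 1-based everywhere in this package. All phases must share one grid
#' (identical extents and spacing): resampling between mismatched grids is
#' out of scope.
#'
#' @param phases List of [ct_volume()] objects, all on one grid, in
#'   acquisition order. At least two phases are required.
#' @param times Optional numeric vector of per-phase acquisition times in
#'   seconds, strictly increasing. The detection algorithm trusts the
#'   supplied ordering and never re-sorts by time stamp.
#'
#' @return An object of class `ct_series` with elements `phases` and
#'   `times`.
#' @export
ct_series <- function(phases, times = NULL) {
  if (!is.list(phases) || length(phases) < 2L) {
    stop("a series needs at least 2 phases", call. = FALSE)
  }
  if (!all(vapply(phases, inherits, logical(1), "ct_volume"))) {
    stop("all phases must be ct_volume objects", call. = FALSE)
  }
  d1 <- dim(phases[[1]]$values)
  s1 <- phases[[1]]$spacing
  for (i in seq_along(phases)) {
    if (!identical(dim(phases[[i]]$values), d1) ||
        !isTRUE(all.equal(phases[[i]]$spacing, s1))) {
      stop(sprintf("phase %d is on a different grid than phase 1", i),
           call. = FALSE)
    }
  }
  if (!is.null(times)) {
    times <- as.numeric(times)
    if (length(times) != length(phases)) {
      stop("`times` must have one entry per phase", call. = FALSE)
    }
    if (anyNA(times) || any(diff(times) <= 0)) {
      stop("`times` must be strictly increasing", call. = FALSE)
    }
  }
  structure(list(phases = phases, times = times), class = "ct_series")
}

#' Number of phases in a series
#'
#' @param series A [ct_series()].
#' @return Integer count of phases.
#' @export
n_phases <- function(series) {
  stopifnot(inherits(series, "ct_series"))
  length(series$phases)
}

#' @export
print.ct_series <- function(x, ...) {
  d <- dim(x$phases[[1]]$values)
  cat(sprintf("<ct_series> %d phases of %d x %d x %d voxels\n",
              length(x$phases), d[1], d[2], d[3]))
  if (!is.null(x$times)) {
    cat(sprintf("  times: %.1f .. %.1f s\n", x$times[1], x$times[length(x$times)]))
  }
  invisible(x)
}
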