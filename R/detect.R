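#' Per-voxel temporal maximum and its phase
#'
#' For every voxel position, scans the phases in acquisition order and
#' records the maximum attenuation and the (1-based) phase at which it
#' occurs. Ties in the maximum are broken toward the earliest phase, so
#' the result is fully deterministic. Voxels that are non-finite in every
#' phase get `NaN` as their maximum and never vote downstream.
#'
#' @param series A [ct_series()] with at least two phases (typically the
#'   shrunken series).
#' @return An object of class `temporal_extremum` with elements
#'   `max_values` ([ct_volume()]), `argmax_phases` (integer array of
#'   1-based phase numbers) and `n_phases`.
#' @export
temporal_extremum <- function(series) {
  stopifnot(inherits(series, "ct_series"))
  p <- length(series$phases)
  if (p < 2L) stop("a series needs at least 2 phases", call. = FALSE)
  d <- dim(series$phases[[1]]$values)
  nvox <- prod(d)
  v <- vapply(series$phases, function(ph) as.vector(ph$values), numeric(nvox))
  v <- matrix(v, nrow = nvox, ncol = p)
  nonfin <- !is.finite(v)
  if (any(nonfin)) v[nonfin] <- -Inf
  arg <- max.col(v, ties.method = "first")
  mx <- v[cbind(seq_len(nvox), arg)]
  mx[mx == -Inf] <- NaN # voxel non-finite in all phases
  structure(
    list(
      max_values = ct_volume(array(mx, dim = d), spacing = series$phases[[1]]$spacing),
      argmax_phases = array(as.integer(arg), dim = d),
      n_phases = p
    ),
    class = "temporal_extremum"
  )
}

#' Build the phase histogram
#'
#' Each voxel casts at most one vote, for the phase at which its
#' attenuation peaks. A voxel votes iff (a) its first-phase attenuation
#' lies in the closed eligibility window and (b) its temporal maximum
#' shows the required increase over the first phase (see
#' [detection_params()]). One bin exists for every phase, including empty
#' bins, and the histogram total equals the number of voxels satisfying
#' both conditions.
#'
#' @param extremum A [temporal_extremum()].
#' @param first_phase The first-phase [ct_volume()] on the same grid.
#' @param params A [detection_params()].
#' @return A tibble of class `phase_histogram` with columns `phase`
#'   (1-based integer) and `votes` (non-negative integer count).
#' @export
build_phase_histogram <- function(extremum, first_phase, params = detection_params()) {
  stopifnot(inherits(extremum, "temporal_extremum"),
            inherits(first_phase, "ct_volume"),
            inherits(params, "detection_params"))
  if (!identical(dim(first_phase$values), dim(extremum$max_values$values))) {
    stop("first phase and extremum grids differ", call. = FALSE)
  }
  first <- as.vector(first_phase$values)
  mx <- as.vector(extremum$max_values$values)
  arg <- as.vector(extremum$argmax_phases)
  eligible <- is.finite(first) & first >= params$hu_lower & first <= params$hu_upper
  increased <- if (params$increase_mode == "relative") {
    mx >= first * (1 + params$increase_value)
  } else {
    mx >= first + params$increase_value
  }
  votes <- eligible & is.finite(mx) & increased
  counts <- tabulate(arg[votes], nbins = extremum$n_phases)
  new_phase_histogram(counts)
}

new_phase_histogram <- function(counts) {
  out <- tibble::tibble(phase = seq_along(counts), votes = as.integer(counts))
  class(out) <- c("phase_histogram", class(out))
  out
}

#' Select the winning phase from a histogram
#'
#' Returns the phase whose bin holds the most votes; ties go to the
#' earliest phase. An all-zero histogram means no voxel satisfied both
#' conditions and yields `NA` — an explicit no-detection, which is a
#' legitimate outcome, not an error.
#'
#' @param histogram A `phase_histogram` tibble (columns `phase`, `votes`).
#' @return 1-based integer phase number, or `NA_integer_` for no-detection.
#'
#' @examples
#' h <- tibble::tibble(phase = 1:3, votes = c(0L, 5L, 5L))
#' select_phase(h) # 2 (earliest of the tied bins)
#' @export
select_phase <- function(histogram) {
  stopifnot(is.data.frame(histogram), all(c("phase", "votes") %in% names(histogram)))
  ord <- order(histogram$phase)
  votes <- histogram$votes[ord]
  if (all(votes == 0L)) return(NA_integer_)
  as.integer(histogram$phase[ord][which.max(votes)])
}

#' Detect the high-LV-contrast phase of a 4D acquisition
#'
#' Runs the full pipeline: derive the shrink factor from the requested
#' matrix size, mean-pool every phase by that factor, take the per-voxel
#' temporal maximum, build the phase histogram over eligible voxels with a
#' sufficient attenuation increase, and select the winning bin. The
#' detected phase is the one with high contrast in the left ventricle —
#' assuming acquisition starts with contrast already high in the right
#' ventricle, so RV voxels exceed the eligibility window in the first
#' phase and are ignored. The algorithm does not verify that the RV is
#' actually low at the detected phase.
#'
#' @param series A [ct_series()].
#' @param params A [detection_params()].
#' @return An object of class `lv_detection` with elements
#'   `detected_phase` (1-based integer or `NA` for no-detection),
#'   `histogram` (tibble, one row per phase), `eligible_voxels` (number of
#'   voxels that voted), `shrink_factor`, `n_phases` and `params`.
#'
#' @examples
#' ph <- generate_phantom(phantom_params(seed = 7))
#' res <- detect_lv_phase(ph$series)
#' res$detected_phase
#' @export
detect_lv_phase <- function(series, params = detection_params()) {
  stopifnot(inherits(series, "ct_series"), inherits(params, "detection_params"))
  f <- compute_shrink_factor(dim(series$phases[[1]]$values)[1], params$matrix_size)
  shrunk <- if (f == 1L) series else {
    ct_series(lapply(series$phases, bin_shrink, factor = f), times = series$times)
  }
  ext <- temporal_extremum(shrunk)
  hist <- build_phase_histogram(ext, shrunk$phases[[1]], params)
  structure(
    list(
      detected_phase = select_phase(hist),
      histogram = hist,
      eligible_voxels = sum(hist$votes),
      shrink_factor = f,
      n_phases = n_phases(series),
      params = params
    ),
    class = "lv_detection"
  )
}

#' @export
print.lv_detection <- function(x, ...) {
  cat("<lv_detection>\n")
  if (is.na(x$detected_phase)) {
    cat("  detected phase: none (no voxel met both conditions)\n")
  } else {
    cat(sprintf("  detected phase: %d of %d\n", x$detected_phase, x$n_phases))
  }
  cat(sprintf("  voting voxels:  %d\n", x$eligible_voxels))
  cat(sprintf("  shrink factor:  %d (matrix size %d)\n",
              x$shrink_factor, x$params$matrix_size))
  invisible(x)
}

#' Tidy a detection result into its phase histogram
#'
#' @param x An `lv_detection` object.
#' @param ... Unused.
#' @return A tibble with columns `phase`, `votes`, and logical `detected`.
#' @method tidy lv_detection
#' @export
tidy.lv_detection <- function(x, ...) {
  out <- tibble::as_tibble(x$histogram)
  out$detected <- !is.na(x$detected_phase) & out$phase == x$detected_phase
  out
}

#' One-row summary of a detection result
#'
#' @param x An `lv_detection` object.
#' @param ... Unused.
#' @return A one-row tibble with the detected phase (NA for
#'   no-detection), number of phases, voting-voxel count, winning-bin
#'   vote count, and shrink factor.
#' @method glance lv_detection
#' @export
glance.lv_detection <- function(x, ...) {
  tibble::tibble(
    detected_phase = x$detected_phase,
    n_phases = x$n_phases,
    eligible_voxels = x$eligible_voxels,
    max_votes = if (x$eligible_voxels > 0L) max(x$histogram$votes) else 0L,
    shrink_factor = x$shrink_factor,
    matrix_size = x$params$matrix_size
  )
}

#' Plot the phase histogram of a detection result
#'
#' Bar chart of votes per phase with the detected bin highlighted.
#'
#' @param object An `lv_detection` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lv_detection
#' @export
autoplot.lv_detection <- function(object, ...) {
  df <- tidy.lv_detection(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase, y = .data$votes,
                                   fill = .data$detected)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey55", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "phase number", y = "voting voxels",
      title = if (is.na(object$detected_phase)) "No phase detected"
              else sprintf("Detected phase %d", object$detected_phase)
    ) +
    ggplot2::theme_minimal()
}
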