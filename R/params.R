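#' Detection parameters
#'
#' Collects every threshold of the phase-detection algorithm.
#'
#' A voxel is *eligible* if its first-phase attenuation lies in the closed
#' window `[hu_lower, hu_upper]`; the defaults of 30 and 150 HU target
#' blood not yet carrying contrast agent. An eligible voxel *votes* only if
#' its temporal maximum shows a sufficient attenuation increase over the
#' first phase:
#'
#' * `increase_mode = "relative"`: `max >= first * (1 + increase_value)`,
#'   with `increase_value` a dimensionless fraction. The default of 1.0
#'   demands at least a doubling, consistent with first-pass left-ventricle
#'   enhancement multiplying baseline blood attenuation severalfold.
#' * `increase_mode = "absolute"`: `max >= first + increase_value`, with
#'   `increase_value` in HU.
#'
#' Both comparisons are inclusive. `matrix_size` is the target number of
#' voxels in the x direction after shrinking; the actual integer shrink
#' factor is derived from it by [compute_shrink_factor()]. The default of
#' 16 offers the best accuracy/speed trade-off in practice.
#'
#' @param hu_lower,hu_upper Closed eligibility window for first-phase
#'   attenuation, in HU. `hu_lower` must be below `hu_upper`.
#' @param increase_mode `"relative"` or `"absolute"`.
#' @param increase_value Positive increase threshold (fraction or HU,
#'   depending on mode).
#' @param matrix_size Positive integer; target x-extent after shrinking.
#'
#' @return An object of class `detection_params`.
#'
#' @examples
#' detection_params()
#' detection_params(increase_mode = "absolute", increase_value = 100)
#' @export
detection_params <- function(hu_lower = 30,
                             hu_upper = 150,
                             increase_mode = c("relative", "absolute"),
                             increase_value = 1,
                             matrix_size = 16L) {
  increase_mode <- match.arg(increase_mode)
  hu_lower <- as.numeric(hu_lower)
  hu_upper <- as.numeric(hu_upper)
  increase_value <- as.numeric(increase_value)
  matrix_size <- as.integer(matrix_size)
  if (anyNA(c(hu_lower, hu_upper, increase_value, matrix_size))) {
    stop("detection parameters must be non-missing", call. = FALSE)
  }
  if (hu_lower >= hu_upper) {
    stop("`hu_lower` must be strictly below `hu_upper`", call. = FALSE)
  }
  if (increase_value <= 0) {
    stop("`increase_value` must be positive", call. = FALSE)
  }
  if (matrix_size < 1L) {
    stop("`matrix_size` must be >= 1", call. = FALSE)
  }
  structure(
    list(
      hu_lower = hu_lower, hu_upper = hu_upper,
      increase_mode = increase_mode, increase_value = increase_value,
      matrix_size = matrix_size
    ),
    class = "detection_params"
  )
}

#' @export
print.detection_params <- function(x, ...) {
  cat(sprintf(
    "<detection_params> window [%g, %g] HU, increase %s %g, matrix size %d\n",
    x$hu_lower, x$hu_upper, x$increase_mode, x$increase_value, x$matrix_size
  ))
  invisible(x)
}
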