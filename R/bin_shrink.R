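#' Map a requested matrix size to an integer shrink factor
#'
#' The shrink factor is controlled indirectly: the user requests a target
#' number of voxels in x (the "matrix size") and the factor is the integer
#' ratio `floor(nx / matrix_size)`, clamped to 1. The filter never
#' up-samples: requesting a matrix size larger than the input leaves the
#' volume untouched. A 512-voxel input shrunk to matrix size 128 uses
#' factor 4.
#'
#' @param input_extent_x Positive integer, input x extent in voxels.
#' @param matrix_size Positive integer, requested output x extent.
#' @return Positive integer shrink factor.
#'
#' @examples
#' compute_shrink_factor(512, 128) # 4
#' compute_shrink_factor(128, 16)  # 8
#' compute_shrink_factor(100, 128) # 1 (never up-samples)
#' @export
compute_shrink_factor <- function(input_extent_x, matrix_size) {
  input_extent_x <- as.integer(input_extent_x)
  matrix_size <- as.integer(matrix_size)
  if (length(input_extent_x) != 1L || is.na(input_extent_x) || input_extent_x < 1L) {
    stop("`input_extent_x` must be a positive integer", call. = FALSE)
  }
  if (length(matrix_size) != 1L || is.na(matrix_size) || matrix_size < 1L) {
    stop("`matrix_size` must be a positive integer", call. = FALSE)
  }
  max(1L, input_extent_x %/% matrix_size)
}

# Sum a 3D array over blocks of `f` consecutive indices along axis 1.
# Boundary blocks may be partial; they sum over the indices present.
pool_axis1_sum <- function(a, f) {
  d <- dim(a)
  if (f == 1L) return(a)
  grp <- (seq_len(d[1]) - 1L) %/% f
  s <- rowsum(matrix(a, nrow = d[1]), grp, reorder = TRUE)
  array(s, dim = c(nrow(s), d[2], d[3]))
}

pool3_sum <- function(a, f) {
  a <- pool_axis1_sum(a, f)
  a <- aperm(pool_axis1_sum(aperm(a, c(2, 1, 3)), f), c(2, 1, 3))
  aperm(pool_axis1_sum(aperm(a, c(3, 2, 1)), f), c(3, 2, 1))
}

#' Shrink a volume by integer-factor mean pooling
#'
#' Downsamples a volume by the same integer factor along all three axes:
#' each output voxel is the arithmetic mean of the input voxels in its
#' `factor^3` block. Output extents are `ceiling(n / factor)` per axis, so
#' boundary blocks may be partial; those are averaged over the voxels
#' actually present (no zero padding, no truncation), which keeps the
#' global mean as close to the input's as possible. Output spacing is the
#' input spacing times the factor. Accumulation is in double precision.
#'
#' Non-finite voxels (NaN/Inf) are excluded from the block mean; a block
#' containing only non-finite voxels yields `NaN`, which downstream
#' detection treats as ineligible.
#'
#' @param volume A [ct_volume()].
#' @param factor Positive integer shrink factor; 1 returns the input
#'   unchanged.
#' @return A [ct_volume()] with reduced extents and scaled spacing.
#'
#' @examples
#' v <- ct_volume(array(c(rep(1, 7), 9), dim = c(2, 2, 2)))
#' bin_shrink(v, 2)$values # 1x1x1, mean (7*1 + 9)/8 = 2
#' @export
bin_shrink <- function(volume, factor) {
  stopifnot(inherits(volume, "ct_volume"))
  factor <- as.integer(factor)
  if (length(factor) != 1L || is.na(factor) || factor < 1L) {
    stop("`factor` must be a positive integer", call. = FALSE)
  }
  if (factor == 1L) return(volume)
  vals <- volume$values
  fin <- is.finite(vals)
  if (!all(fin)) {
    vals[!fin] <- 0
    sums <- pool3_sum(vals, factor)
    cnts <- pool3_sum(array(as.double(fin), dim = dim(fin)), factor)
    out <- sums / cnts # 0/0 -> NaN for all-non-finite blocks
  } else {
    sums <- pool3_sum(vals, factor)
    cnts <- pool3_sum(array(1, dim = dim(vals)), factor)
    out <- sums / cnts
  }
  ct_volume(out, spacing = volume$spacing * factor)
}
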