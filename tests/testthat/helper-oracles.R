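# Independent brute-force reference implementations used as oracles.
# Deliberately written as plain nested loops, sharing no code with the
# package internals they check.

naive_bin_shrink <- function(volume, f) {
  a <- volume$values
  d <- dim(a)
  od <- ceiling(d / f)
  out <- array(NA_real_, dim = od)
  for (i in seq_len(od[1])) {
    for (j in seq_len(od[2])) {
      for (k in seq_len(od[3])) {
        xs <- ((i - 1) * f + 1):min(i * f, d[1])
        ys <- ((j - 1) * f + 1):min(j * f, d[2])
        zs <- ((k - 1) * f + 1):min(k * f, d[3])
        block <- a[xs, ys, zs]
        fin <- block[is.finite(block)]
        out[i, j, k] <- if (length(fin)) mean(fin) else NaN
      }
    }
  }
  ct_volume(out, spacing = volume$spacing * f)
}

naive_detect <- function(series, params) {
  f <- max(1L, dim(series$phases[[1]]$values)[1] %/% params$matrix_size)
  shrunk <- lapply(series$phases, naive_bin_shrink, f = f)
  d <- dim(shrunk[[1]]$values)
  p <- length(shrunk)
  counts <- integer(p)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      for (k in seq_len(d[3])) {
        mx <- -Inf
        arg <- NA_integer_
        for (ph in seq_len(p)) {
          v <- shrunk[[ph]]$values[i, j, k]
          if (is.finite(v) && v > mx) {
            mx <- v
            arg <- ph
          }
        }
        first <- shrunk[[1]]$values[i, j, k]
        if (is.na(arg) || !is.finite(first)) next
        if (first < params$hu_lower || first > params$hu_upper) next
        thr <- if (params$increase_mode == "relative") {
          first * (1 + params$increase_value)
        } else {
          first + params$increase_value
        }
        if (mx >= thr) counts[arg] <- counts[arg] + 1L
      }
    }
  }
  detected <- if (all(counts == 0L)) NA_integer_ else which.max(counts)
  list(detected_phase = detected, counts = counts, shrink_factor = f)
}

rand_volume <- function(dims, lo = -100, hu = 400, spacing = c(1, 1, 1)) {
  ct_volume(array(runif(prod(dims), lo, hu), dim = dims), spacing = spacing)
}

rand_series <- function(dims, p, lo = -100, hu = 400) {
  ct_series(lapply(seq_len(p), function(i) rand_volume(dims, lo, hu)))
}

# Single-voxel series, handy for toy temporal cases
voxel_series <- function(values) {
  ct_series(lapply(values, function(v) ct_volume(array(v, dim = c(1, 1, 1)))))
}
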