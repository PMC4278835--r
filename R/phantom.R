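#' Gamma-variate curve parameters
#'
#' The standard first-pass bolus enhancement model. The curve is zero up
#' to the arrival time `t0` and then rises and falls as a gamma variate,
#' normalised so that its maximum equals `amplitude`, reached at
#' `t0 + alpha * beta`.
#'
#' @param t0 Contrast arrival time in seconds (may be negative to model a
#'   bolus that arrived before acquisition start).
#' @param alpha Shape parameter, dimensionless, > 0.
#' @param beta Scale parameter in seconds, > 0.
#' @param amplitude Peak enhancement in HU, >= 0.
#' @return An object of class `gamma_variate_params`.
#' @export
gamma_variate_params <- function(t0, alpha, beta, amplitude) {
  t0 <- as.numeric(t0); alpha <- as.numeric(alpha)
  beta <- as.numeric(beta); amplitude <- as.numeric(amplitude)
  if (anyNA(c(t0, alpha, beta, amplitude))) {
    stop("gamma-variate parameters must be non-missing", call. = FALSE)
  }
  if (alpha <= 0 || beta <= 0) stop("`alpha` and `beta` must be positive", call. = FALSE)
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  structure(list(t0 = t0, alpha = alpha, beta = beta, amplitude = amplitude),
            class = "gamma_variate_params")
}

#' Evaluate a gamma-variate enhancement curve
#'
#' @param t Numeric vector of times in seconds.
#' @param p A [gamma_variate_params()].
#' @return Enhancement in HU at each time: 0 for `t <= t0`, otherwise
#'   `amplitude * ((t - t0)/(alpha*beta))^alpha * exp(alpha - (t - t0)/beta)`,
#'   which peaks at exactly `amplitude` when `t = t0 + alpha*beta`.
#'
#' @examples
#' p <- gamma_variate_params(t0 = 1.2, alpha = 3, beta = 2, amplitude = 300)
#' gamma_variate(1.2, p)          # 0 (pre-arrival)
#' gamma_variate(1.2 + 3 * 2, p)  # 300 (the analytic maximum)
#' @export
gamma_variate <- function(t, p) {
  stopifnot(inherits(p, "gamma_variate_params"))
  t <- as.numeric(t)
  dt <- t - p$t0
  out <- numeric(length(t))
  pos <- dt > 0
  out[pos] <- p$amplitude * (dt[pos] / (p$alpha * p$beta))^p$alpha *
    exp(p$alpha - dt[pos] / p$beta)
  out
}

#' Parameters of the synthetic first-pass contrast phantom
#'
#' The phantom emulates a dynamic cardiac CT acquisition: one volume per
#' RR-interval during a dynamic window, followed by a few late single
#' acquisitions, with acquisition starting when contrast is already high
#' in the right ventricle. RV enhancement washes out over the series while
#' LV enhancement rises to a later peak. Geometry is two non-overlapping
#' blood-pool ellipsoids (LV, RV), a static myocardial shell around the
#' LV, lateral lung slabs and soft-tissue background, all with additive
#' Gaussian noise.
#'
#' With the default curves the LV peak falls exactly on phase 10 of 20
#' (17 dynamic phases at a 0.8 s RR-interval plus late acquisitions 10,
#' 20 and 35 s after the dynamic window). Default HU constants: background
#' and myocardium 50, lung -800, blood baseline 40, LV peak enhancement
#' +300, RV peak enhancement +400 — so noiseless first-phase LV voxels sit
#' inside the 30-150 HU eligibility window while first-phase RV voxels
#' (~440 HU) sit far above it.
#'
#' @param extents Grid size `(nx, ny, nz)` in voxels.
#' @param spacing Voxel spacing in mm.
#' @param n_phases Total number of phases, including the late ones.
#' @param rr_interval RR-interval in seconds (one dynamic phase each).
#' @param late_phase_offsets Seconds after the end of the dynamic window
#'   at which the late single acquisitions are taken; may be empty.
#' @param lv_centre,lv_semiaxes,rv_centre,rv_semiaxes Ellipsoid centres
#'   and semi-axes in voxel units.
#' @param myocardium_hu,blood_baseline_hu,lung_hu,background_hu Tissue HU
#'   constants.
#' @param lv_curve,rv_curve [gamma_variate_params()] for the chamber
#'   enhancement dynamics.
#' @param noise_sigma Standard deviation of the additive Gaussian noise,
#'   in HU; >= 0.
#' @param seed Integer seed; identical seeds give voxel-identical phantoms.
#' @param pre_rv_arrival If `TRUE`, shift the RV bolus to arrive after
#'   acquisition start (scenario where first-phase RV voxels are eligible
#'   and can steal the vote — the algorithm's known failure mode when
#'   scanning starts too early).
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(extents = c(64L, 64L, 48L),
                           spacing = c(3, 3, 3),
                           n_phases = 20L,
                           rr_interval = 0.8,
                           late_phase_offsets = c(10, 20, 35),
                           lv_centre = c(24, 32, 24),
                           lv_semiaxes = c(10, 10, 14),
                           rv_centre = c(44, 32, 24),
                           rv_semiaxes = c(8, 10, 14),
                           myocardium_hu = 50,
                           blood_baseline_hu = 40,
                           lung_hu = -800,
                           background_hu = 50,
                           lv_curve = gamma_variate_params(1.2, 3, 2, 300),
                           rv_curve = gamma_variate_params(-4, 2.5, 1.6, 400),
                           noise_sigma = 10,
                           seed = 1L,
                           pre_rv_arrival = FALSE) {
  extents <- as.integer(extents)
  n_phases <- as.integer(n_phases)
  stopifnot(length(extents) == 3L, all(extents >= 1L))
  if (n_phases < 2L) stop("`n_phases` must be >= 2", call. = FALSE)
  n_dyn <- n_phases - length(late_phase_offsets)
  if (n_dyn < 2L) {
    stop("`n_phases` must exceed the number of late phases by >= 2", call. = FALSE)
  }
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (rr_interval <= 0) stop("`rr_interval` must be positive", call. = FALSE)
  if (length(late_phase_offsets) && any(diff(c(0, late_phase_offsets)) <= 0)) {
    stop("`late_phase_offsets` must be positive and strictly increasing",
         call. = FALSE)
  }
  stopifnot(inherits(lv_curve, "gamma_variate_params"),
            inherits(rv_curve, "gamma_variate_params"))
  if (isTRUE(pre_rv_arrival)) {
    rv_curve <- gamma_variate_params(rr_interval, rv_curve$alpha,
                                     rv_curve$beta, rv_curve$amplitude)
  }
  p <- structure(
    list(
      extents = extents, spacing = as.numeric(spacing),
      n_phases = n_phases, rr_interval = as.numeric(rr_interval),
      late_phase_offsets = as.numeric(late_phase_offsets),
      lv_centre = as.numeric(lv_centre), lv_semiaxes = as.numeric(lv_semiaxes),
      rv_centre = as.numeric(rv_centre), rv_semiaxes = as.numeric(rv_semiaxes),
      myocardium_hu = as.numeric(myocardium_hu),
      blood_baseline_hu = as.numeric(blood_baseline_hu),
      lung_hu = as.numeric(lung_hu), background_hu = as.numeric(background_hu),
      lv_curve = lv_curve, rv_curve = rv_curve,
      noise_sigma = as.numeric(noise_sigma), seed = as.integer(seed),
      pre_rv_arrival = isTRUE(pre_rv_arrival)
    ),
    class = "phantom_params"
  )
  validate_phantom_geometry(p)
  p
}

ellipsoid_mask <- function(extents, centre, semiaxes) {
  ix <- seq_len(extents[1]); iy <- seq_len(extents[2]); iz <- seq_len(extents[3])
  dx2 <- ((ix - centre[1]) / semiaxes[1])^2
  dy2 <- ((iy - centre[2]) / semiaxes[2])^2
  dz2 <- ((iz - centre[3]) / semiaxes[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

validate_phantom_geometry <- function(p) {
  for (side in c("lv", "rv")) {
    ctr <- p[[paste0(side, "_centre")]]
    ax <- p[[paste0(side, "_semiaxes")]]
    if (any(ax <= 0)) stop("ellipsoid semi-axes must be positive", call. = FALSE)
    if (any(ctr - ax < 1) || any(ctr + ax > p$extents)) {
      stop(sprintf("%s ellipsoid extends outside the grid", toupper(side)),
           call. = FALSE)
    }
  }
  lv <- ellipsoid_mask(p$extents, p$lv_centre, p$lv_semiaxes)
  rv <- ellipsoid_mask(p$extents, p$rv_centre, p$rv_semiaxes)
  if (any(lv & rv)) stop("LV and RV ellipsoids overlap", call. = FALSE)
  invisible(p)
}

phantom_phase_times <- function(p) {
  n_dyn <- p$n_phases - length(p$late_phase_offsets)
  dyn <- (seq_len(n_dyn) - 1) * p$rr_interval
  c(dyn, dyn[n_dyn] + p$late_phase_offsets)
}

#' Generate a synthetic 4D first-pass contrast acquisition
#'
#' Builds the phantom described by [phantom_params()]: a static anatomical
#' background plus time-varying chamber enhancement sampled from the LV
#' and RV gamma-variate curves at the acquisition times, with additive
#' zero-mean Gaussian noise. The generator is fully seeded: the same
#' parameters produce voxel-identical output. The global RNG state is left
#' untouched.
#'
#' @param params A [phantom_params()].
#' @return A list of class `lv_phantom` with elements:
#' \describe{
#'   \item{series}{a [ct_series()] with one volume per phase and strictly
#'     increasing acquisition times,}
#'   \item{truth}{a list with `lv_peak_phase` and `rv_peak_phase` (1-based
#'     argmax of the sampled chamber curves, earliest on ties) and
#'     `chamber_hu`, a tibble of the noiseless per-phase chamber
#'     attenuations (`phase`, `time`, `lv_hu`, `rv_hu`),}
#'   \item{params}{the parameters used.}
#' }
#'
#' @examples
#' ph <- generate_phantom(phantom_params(seed = 42, noise_sigma = 0))
#' ph$truth$lv_peak_phase # 10 with the default curves
#' @export
generate_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  times <- phantom_phase_times(params)
  lv_enh <- gamma_variate(times, params$lv_curve)
  rv_enh <- gamma_variate(times, params$rv_curve)

  ext <- params$extents
  lv_mask <- ellipsoid_mask(ext, params$lv_centre, params$lv_semiaxes)
  rv_mask <- ellipsoid_mask(ext, params$rv_centre, params$rv_semiaxes)
  shell_mask <- ellipsoid_mask(ext, params$lv_centre, params$lv_semiaxes + 4) &
    !lv_mask & !rv_mask
  lung_w <- max(1L, ext[1] %/% 10L)
  ix <- slice.index(array(0, ext), 1)
  lung_mask <- (ix <= lung_w) | (ix > ext[1] - lung_w)

  base <- array(params$background_hu, dim = ext)
  base[lung_mask] <- params$lung_hu
  base[shell_mask] <- params$myocardium_hu
  base[rv_mask | lv_mask] <- params$blood_baseline_hu

  nvox <- prod(ext)
  phases <- withr::with_seed(params$seed, {
    lapply(seq_len(params$n_phases), function(k) {
      vol <- base
      vol[rv_mask] <- params$blood_baseline_hu + rv_enh[k]
      vol[lv_mask] <- params$blood_baseline_hu + lv_enh[k]
      if (params$noise_sigma > 0) {
        vol <- vol + array(stats::rnorm(nvox, 0, params$noise_sigma), dim = ext)
      }
      ct_volume(vol, spacing = params$spacing)
    })
  })

  truth <- list(
    lv_peak_phase = which.max(lv_enh),
    rv_peak_phase = which.max(rv_enh),
    chamber_hu = tibble::tibble(
      phase = seq_len(params$n_phases),
      time = times,
      lv_hu = params$blood_baseline_hu + lv_enh,
      rv_hu = params$blood_baseline_hu + rv_enh
    )
  )
  structure(
    list(series = ct_series(phases, times = times), truth = truth, params = params),
    class = "lv_phantom"
  )
}

#' @export
print.lv_phantom <- function(x, ...) {
  d <- x$params$extents
  cat(sprintf(
    "<lv_phantom> %d x %d x %d voxels, %d phases, LV peak at phase %d\n",
    d[1], d[2], d[3], x$params$n_phases, x$truth$lv_peak_phase
  ))
  invisible(x)
}

#' Plot the phantom's noiseless chamber enhancement curves
#'
#' @param object An `lv_phantom`.
#' @param ... Unused.
#' @return A ggplot object showing LV and RV attenuation over the phases,
#'   with the ground-truth LV peak marked.
#' @method autoplot lv_phantom
#' @export
autoplot.lv_phantom <- function(object, ...) {
  df <- tidyr_longer(object$truth$chamber_hu)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase, y = .data$hu,
                                   colour = .data$chamber)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$truth$lv_peak_phase,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "phase number", y = "attenuation (HU)", colour = NULL) +
    ggplot2::theme_minimal()
}

# long format for the two chamber curves without pulling in tidyr
tidyr_longer <- function(chamber_hu) {
  dplyr::bind_rows(
    tibble::tibble(phase = chamber_hu$phase, hu = chamber_hu$lv_hu, chamber = "LV"),
    tibble::tibble(phase = chamber_hu$phase, hu = chamber_hu$rv_hu, chamber = "RV")
  )
}
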