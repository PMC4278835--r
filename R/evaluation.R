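#' Build a case-outcome table
#'
#' One row per case: the phase the algorithm detected (or `NA` for an
#' explicit no-detection) and the set of acceptable reference phases —
#' typically the intersection of the phase sets chosen independently by
#' two readers, which may contain more than one phase per case.
#'
#' @param case_id Vector of case identifiers.
#' @param detected Integer vector of detected phases; `NA` = no-detection.
#' @param reference List of non-empty integer vectors of acceptable
#'   phases, one per case.
#' @return A tibble with columns `case_id`, `detected` and `reference`
#'   (list column).
#' @export
case_outcomes <- function(case_id, detected, reference) {
  if (!is.list(reference)) reference <- list(reference)
  if (length(case_id) != length(detected) || length(detected) != length(reference)) {
    stop("`case_id`, `detected` and `reference` must have equal length",
         call. = FALSE)
  }
  reference <- lapply(reference, function(r) {
    r <- as.integer(r)
    if (length(r) == 0L || anyNA(r)) {
      stop("each reference set must be a non-empty vector of phases",
           call. = FALSE)
    }
    r
  })
  tibble::tibble(
    case_id = case_id,
    detected = as.integer(detected),
    reference = reference
  )
}

#' Agreement of detected phases with reference phases
#'
#' A case counts as a success iff a phase was detected and it belongs to
#' that case's reference set. No-detection counts as a failure, and the
#' ratio is taken over all cases including no-detections (a run in which
#' the algorithm never detects a phase scores 0 agreement). The result
#' does not depend on the order of the cases.
#'
#' @param outcomes A tibble as produced by [case_outcomes()]: columns
#'   `detected` (integer, `NA` = no-detection) and `reference` (list of
#'   integer vectors).
#' @param level Optional confidence level; if supplied, an exact
#'   Clopper-Pearson interval for the ratio is appended (see
#'   [clopper_pearson_ci()]).
#' @return A one-row tibble with `successes`, `total` and `ratio`, plus
#'   `lower`, `upper` and `level` when `level` is given.
#'
#' @examples
#' oc <- case_outcomes(1:3, c(10L, 10L, NA),
#'                     list(c(9L, 10L), c(16L, 17L, 18L), 5L))
#' agreement(oc)            # 1 success of 3
#' agreement(oc, level = 0.95)
#' @export
agreement <- function(outcomes, level = NULL) {
  stopifnot(is.data.frame(outcomes),
            all(c("detected", "reference") %in% names(outcomes)))
  n <- nrow(outcomes)
  if (n < 1L) stop("`outcomes` must contain at least one case", call. = FALSE)
  if (any(lengths(outcomes$reference) == 0L)) {
    stop("each reference set must be non-empty", call. = FALSE)
  }
  ok <- purrr::map2_lgl(outcomes$detected, outcomes$reference,
                        function(d, ref) !is.na(d) && d %in% ref)
  x <- sum(ok)
  out <- tibble::tibble(successes = x, total = n, ratio = x / n)
  if (!is.null(level)) {
    ci <- clopper_pearson_ci(x, n, level)
    out$lower <- ci$lower
    out$upper <- ci$upper
    out$level <- level
  }
  out
}

#' Exact Clopper-Pearson confidence interval for a binomial proportion
#'
#' Computed from inverse incomplete-beta quantiles:
#' `lower = qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`) and
#' `upper = qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`), with
#' `alpha = 1 - level`. The interval is asymmetric near 0 and 1 and its
#' coverage is conservative (at least the nominal level). For 0 successes
#' out of 29 the upper bound is `1 - 0.025^(1/29)`, about 11.9%, which a
#' whole-percent display rounds to the familiar 0-12% interval.
#'
#' @param x Number of successes, `0 <= x <= n`.
#' @param n Number of trials, >= 1.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return A one-row tibble with `x`, `n`, `estimate` (`x/n`), `lower`,
#'   `upper` and `level`.
#'
#' @examples
#' clopper_pearson_ci(28, 29)  # the asymmetric 82-100% interval
#' @export
clopper_pearson_ci <- function(x, n, level = 0.95) {
  x <- as.integer(x); n <- as.integer(n)
  if (length(x) != 1L || length(n) != 1L || is.na(x) || is.na(n)) {
    stop("`x` and `n` must be single integers", call. = FALSE)
  }
  if (n < 1L || x < 0L || x > n) {
    stop("need 0 <= x <= n with n >= 1", call. = FALSE)
  }
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level <= 0 || level >= 1) {
    stop("`level` must be in (0, 1)", call. = FALSE)
  }
  alpha <- 1 - level
  lower <- if (x == 0L) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  tibble::tibble(x = x, n = n, estimate = x / n,
                 lower = lower, upper = upper, level = level)
}

#' Normal-approximation confidence interval for a mean
#'
#' Symmetric interval `mean +/- z * sd / sqrt(n)` with `z` the standard
#' normal quantile for the given level; used for per-case durations.
#'
#' @param samples Numeric vector with at least two values.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return A one-row tibble with `mean`, `lower`, `upper`, `n` and
#'   `level`.
#' @export
mean_ci_normal <- function(samples, level = 0.95) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L || anyNA(samples)) {
    stop("`samples` must hold at least two non-missing values", call. = FALSE)
  }
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  m <- mean(samples)
  half <- stats::qnorm(1 - (1 - level) / 2) * stats::sd(samples) / sqrt(length(samples))
  tibble::tibble(mean = m, lower = m - half, upper = m + half,
                 n = length(samples), level = level)
}

#' Bonferroni-corrected significance threshold
#'
#' Dividing the family-wise level by the number of comparisons; e.g. all
#' 21 pairwise comparisons among 7 matrix sizes at a family-wise 0.05
#' yield a per-comparison threshold of about 0.00238.
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param m Number of comparisons, >= 1.
#' @return The corrected per-comparison threshold `alpha / m`.
#' @export
bonferroni_alpha <- function(alpha, m) {
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m < 1L) {
    stop("`m` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  alpha / m
}

#' Round a ratio to a whole percentage, halves up
#'
#' Display helper matching the usual reporting style for agreement
#' ratios: 0.545 prints as 55(%). Raw ratios should be kept for any
#' serialized output; this is for display only.
#'
#' @param ratio Numeric vector of ratios in \[0, 1\].
#' @return Integer vector of percentages.
#' @export
percent_round <- function(ratio) {
  as.integer(floor(ratio * 100 + 0.5))
}

#' Run detection over a manifest of cases at several matrix sizes
#'
#' Reads each case's 4D dataset, runs [detect_lv_phase()] once per matrix
#' size, and scores the result against the case's reference phases.
#' Timing of each detection (in seconds) is recorded so duration
#' summaries via [mean_ci_normal()] are possible.
#'
#' @param manifest A data frame with columns `case_id`, `path` (dataset
#'   file, 4D NIfTI or a semicolon-separated list of 3D files) and
#'   `reference` (semicolon-separated phase numbers, or a list column of
#'   integer vectors). A path to a CSV file with those columns is also
#'   accepted.
#' @param matrix_sizes Integer vector of matrix sizes to evaluate.
#' @param params Base [detection_params()]; its `matrix_size` is
#'   overridden per run.
#' @return A tibble with one row per case and matrix size: `case_id`,
#'   `matrix_size`, `detected`, `agree`, `seconds`.
#' @export
evaluate_cases <- function(manifest,
                           matrix_sizes = c(2L, 4L, 8L, 16L, 32L, 64L, 128L),
                           params = detection_params()) {
  if (is.character(manifest) && length(manifest) == 1L) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(manifest),
            all(c("case_id", "path", "reference") %in% names(manifest)))
  if (nrow(manifest) < 1L) stop("empty manifest", call. = FALSE)
  refs <- manifest$reference
  if (!is.list(refs)) {
    refs <- lapply(strsplit(as.character(refs), ";", fixed = TRUE), as.integer)
  }
  purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    paths <- strsplit(as.character(manifest$path[i]), ";", fixed = TRUE)[[1]]
    series <- read_ct_series(paths)
    purrr::map_dfr(matrix_sizes, function(ms) {
      p <- params
      p$matrix_size <- as.integer(ms)
      t0 <- proc.time()[["elapsed"]]
      res <- detect_lv_phase(series, p)
      dt <- proc.time()[["elapsed"]] - t0
      tibble::tibble(
        case_id = manifest$case_id[i],
        matrix_size = as.integer(ms),
        detected = res$detected_phase,
        agree = !is.na(res$detected_phase) && res$detected_phase %in% refs[[i]],
        seconds = dt
      )
    })
  })
}

#' Summarise per-case evaluation into agreement per matrix size
#'
#' @param results Output of [evaluate_cases()].
#' @param level Confidence level for the Clopper-Pearson intervals.
#' @return A tibble with one row per matrix size: `matrix_size`,
#'   `successes`, `total`, `ratio`, `lower`, `upper`.
#' @export
summarise_agreement <- function(results, level = 0.95) {
  stopifnot(is.data.frame(results),
            all(c("matrix_size", "agree") %in% names(results)))
  results |>
    dplyr::group_by(.data$matrix_size) |>
    dplyr::summarise(
      successes = sum(.data$agree),
      total = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::rowwise() |>
    dplyr::mutate(ci = list(clopper_pearson_ci(.data$successes, .data$total, level))) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      ratio = .data$successes / .data$total,
      lower = purrr::map_dbl(.data$ci, "lower"),
      upper = purrr::map_dbl(.data$ci, "upper")
    ) |>
    dplyr::select(-"ci")
}
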