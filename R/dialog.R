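#' Canonical double-gamma HRF parameters
#'
#' The canonical haemodynamic response function used throughout the package:
#' a gamma density peaking near 5--6 s minus a later, smaller gamma density
#' modelling the post-stimulus undershoot, with the classic 1/6 undershoot
#' ratio and a 32 s kernel. All delays and dispersions are in seconds.
#'
#' @param peak_delay Delay of the response gamma (shape x scale), seconds.
#' @param undershoot_delay Delay of the undershoot gamma, seconds.
#' @param dispersion,undershoot_dispersion Gamma scale parameters, seconds.
#' @param undershoot_ratio Amplitude ratio of undershoot to response.
#' @param kernel_length Kernel support in seconds.
#' @param microtime_resolution Time bins per TR used when sampling the kernel
#'   and the stimulus envelope.
#' @return An `hrf_params` list.
#' @export
hrf_params <- function(peak_delay = 6,
                       undershoot_delay = 16,
                       dispersion = 1,
                       undershoot_dispersion = 1,
                       undershoot_ratio = 1 / 6,
                       kernel_length = 32,
                       microtime_resolution = 16L) {
  p <- list(
    peak_delay = peak_delay,
    undershoot_delay = undershoot_delay,
    dispersion = dispersion,
    undershoot_dispersion = undershoot_dispersion,
    undershoot_ratio = undershoot_ratio,
    kernel_length = kernel_length,
    microtime_resolution = as.integer(microtime_resolution)
  )
  if (any(unlist(p) <= 0)) stop_invalid("All HRF parameters must be positive.")
  structure(p, class = "hrf_params")
}

#' Sample the canonical double-gamma HRF
#'
#' Evaluates
#' `h(t) = gamma_pdf(t; peak_delay/dispersion, dispersion) -
#'   undershoot_ratio * gamma_pdf(t; undershoot_delay/u_dispersion, u_dispersion)`
#' on the microtime grid (TR / `microtime_resolution` spacing) over the kernel
#' length, normalized to unit peak amplitude. With shape parameters above 1
#' the kernel starts at exactly zero, peaks near 5 s and dips negative in the
#' 10--20 s undershoot window. Downstream regressors are z-scored, so the
#' unit-peak normalization does not affect any correlation.
#'
#' @param tr Repetition time in seconds.
#' @param params An [hrf_params()] list.
#' @return Numeric kernel values with a `times` attribute (seconds).
#' @export
canonical_hrf <- function(tr, params = hrf_params()) {
  if (tr <= 0) stop_invalid("`tr` must be positive.")
  dt <- tr / params$microtime_resolution
  times <- seq(0, params$kernel_length, by = dt)
  h <- dgamma(times,
              shape = params$peak_delay / params$dispersion,
              scale = params$dispersion) -
    params$undershoot_ratio *
      dgamma(times,
             shape = params$undershoot_delay / params$undershoot_dispersion,
             scale = params$undershoot_dispersion)
  h <- h / max(h)
  attr(h, "times") <- times
  h
}

# Boolean dialog envelope on the microtime grid, convolved with the HRF and
# linearly interpolated to the acquisition midpoint of each volume. This is
# the pre-filter, un-normalized regressor shared by the synthetic generator
# and build_dialog_regressor().
dialog_envelope <- function(schedule, n_volumes, tr, params = hrf_params()) {
  dlg <- schedule[schedule$trial_type == "dialog", , drop = FALSE]
  if (nrow(dlg) == 0) {
    rlang::abort("Schedule contains no dialog events; the regressor would be constant.",
                 class = "narranet_degenerate_input")
  }
  dt <- tr / params$microtime_resolution
  total <- n_volumes * tr
  grid <- seq(0, total, by = dt)
  env <- rep(0, length(grid))
  for (i in seq_len(nrow(dlg))) {
    env[grid >= dlg$onset[i] & grid < dlg$onset[i] + dlg$duration[i]] <- 1
  }
  h <- canonical_hrf(tr, params)
  conv <- stats::convolve(env, rev(h), type = "open")[seq_along(grid)] * dt
  # sample at acquisition midpoints (slice-time centre convention)
  vol_times <- (seq_len(n_volumes) - 0.5) * tr
  stats::approx(grid, conv, xout = vol_times, rule = 2)$y
}

#' Build the preprocessed dialog regressor
#'
#' Extracts the boolean dialog on/off envelope from the event schedule,
#' convolves it with the canonical HRF on the microtime grid, interpolates to
#' volume acquisition times, high-pass filters it at `cutoff_hz` to match the
#' frequency content of the component time-courses, and z-scores it.
#'
#' @param schedule An `event_schedule` with at least one dialog event.
#' @param n_volumes Number of volumes of the target runs.
#' @param tr Repetition time in seconds.
#' @param cutoff_hz High-pass cutoff in Hz.
#' @param params HRF parameters.
#' @return A `dialog_regressor`: list with z-scored `values` (length
#'   `n_volumes`), the pre-filter series, `tr` and a schedule fingerprint.
#' @export
build_dialog_regressor <- function(schedule, n_volumes, tr,
                                   cutoff_hz = 0.01,
                                   params = hrf_params()) {
  if (n_volumes * tr < max(schedule$onset + schedule$duration) - 1e-6) {
    stop_invalid("Run (%.1f s) is shorter than the schedule.", n_volumes * tr)
  }
  raw <- dialog_envelope(schedule, n_volumes, tr, params)
  filtered <- highpass_filter(raw, cutoff_hz = cutoff_hz, tr = tr)
  dlg <- schedule[schedule$trial_type == "dialog", c("onset", "duration")]
  structure(
    list(
      values = zscore(filtered),
      prefilter = raw,
      tr = tr,
      cutoff_hz = cutoff_hz,
      schedule_hash = sum(dlg$onset * 31 + dlg$duration * 7)
    ),
    class = "dialog_regressor"
  )
}

#' @export
print.dialog_regressor <- function(x, ...) {
  cat(sprintf("<dialog_regressor> %d volumes @ TR %.3f s (z-scored, %.3g Hz high-pass)\n",
              length(x$values), x$tr, x$cutoff_hz))
  invisible(x)
}

#' Correlate component time-courses with the dialog regressor
#'
#' For every component and condition, each subject's back-reconstructed
#' time-course is correlated with the dialog regressor; subject-level
#' correlations are averaged into a per-component mean correlation. Two-tailed
#' p-values come from a circular shift-permutation null (the same mean-over-
#' subjects statistic computed at every admissible shift of the regressor,
#' pooled over all components within a condition — for 212 volumes, minimum
#' shift 2 TRs and 40 components this null holds 209 x 40 = 8360 values), and
#' are Benjamini-Hochberg adjusted over components within each condition.
#' Significant components are classified as `activated` (positive mean
#' correlation) or `deactivated` (negative).
#'
#' @param components A `subject_components` object.
#' @param regressor A [build_dialog_regressor()] result (or numeric series)
#'   matching the run length.
#' @param min_shift Minimum circular shift (TRs) admitted into the null.
#' @param fdr_q Significance level on the adjusted q-values.
#' @param pooled_null Pool the null over components within a condition
#'   (default); otherwise each component is tested against its own
#'   per-component null.
#' @return A `dialog_analysis` tibble with columns `condition`, `component`,
#'   `mean_r`, `p`, `q` and `direction`; the per-condition nulls are attached
#'   as the `nulls` attribute.
#' @export
dialog_correlation_analysis <- function(components, regressor,
                                        min_shift = 2L,
                                        fdr_q = 0.05,
                                        pooled_null = TRUE) {
  reg <- if (inherits(regressor, "dialog_regressor")) regressor$values else regressor
  tc <- components$timecourses # S x C x t x K
  dims <- dim(tc)
  n_sub <- dims[1]; n_cond <- dims[2]; t_len <- dims[3]; k <- dims[4]
  if (length(reg) != t_len) {
    stop_invalid("Regressor length (%d) does not match run length (%d).",
                 length(reg), t_len)
  }
  shifts <- admissible_shifts(t_len, min_shift)
  conditions <- components$conditions

  rows <- list()
  nulls <- list()
  for (ci in seq_len(n_cond)) {
    # mean-over-subjects correlation with the regressor at every shift;
    # row 1 (shift 0) is the observed statistic, admissible rows form the null
    shift_mean <- matrix(0, t_len, k)
    for (s in seq_len(n_sub)) {
      shift_mean <- shift_mean +
        all_shift_correlations(reg, matrix(tc[s, ci, , , drop = FALSE],
                                           t_len, k))
    }
    shift_mean <- shift_mean / n_sub
    observed <- shift_mean[1, ]
    null_values <- shift_mean[shifts + 1L, , drop = FALSE]
    nd <- new_null_distribution(as.vector(null_values), length(shifts),
                                min_shift, k)
    nulls[[conditions[ci]]] <- nd
    p <- if (pooled_null) {
      permutation_pvalue(observed, nd)
    } else {
      vapply(seq_len(k), function(j) {
        permutation_pvalue(observed[j],
                           new_null_distribution(null_values[, j],
                                                 length(shifts), min_shift, 1L))
      }, numeric(1))
    }
    q <- fdr_adjust(p)
    rows[[ci]] <- tibble::tibble(
      condition = conditions[ci],
      component = seq_len(k),
      mean_r = observed,
      p = p,
      q = q,
      direction = dplyr::case_when(
        q < fdr_q & observed > 0 ~ "activated",
        q < fdr_q & observed < 0 ~ "deactivated",
        TRUE ~ "n.s."
      )
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "nulls") <- nulls
  attr(out, "fdr_q") <- fdr_q
  class(out) <- c("dialog_analysis", class(out))
  out
}
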