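#' Configuration for the synthetic two-condition BOLD generator
#'
#' Defaults emulate the acquisition of the movie/script study design: 31
#' subjects, two runs of 212 volumes each at TR 2.015 s, on a desk-scale
#' 20x20x12 voxel grid. Planted sources come in four kinds: `shared`
#' (narrative) sources whose movie and script time-courses are correlated at
#' `shared_tc_correlation`; `movie_only` / `script_only` sources active in a
#' single condition; and optional `dialog_locked` sources driven by the
#' HRF-convolved dialog envelope of the event schedule (positively, and, when
#' `dialog_deactivated_source` is set, a second one negatively, emulating a
#' network deactivated by dialog).
#'
#' @param n_subjects Number of subjects.
#' @param n_volumes Volumes per run (>= 8).
#' @param tr Repetition time in seconds.
#' @param n_shared_sources Number of narrative (cross-condition correlated)
#'   sources.
#' @param n_specific_sources_per_condition Number of modality-specific sources
#'   per condition (each active only in its own condition).
#' @param shared_tc_correlation Target Pearson correlation between the movie
#'   and script time-courses of each shared source, in \[0, 1\].
#' @param dialog_source Plant one source locked to the dialog envelope.
#' @param dialog_deactivated_source Plant one source anti-correlated with the
#'   dialog envelope.
#' @param noise_sd Standard deviation of i.i.d. Gaussian voxel noise, in
#'   signal units. With `source_amplitude = 1` a value of 1 gives SNR ~ 1 at
#'   blob peaks.
#' @param source_amplitude Peak amplitude of each planted source's
#'   contribution, in signal units.
#' @param motion_sd Per-step standard deviation (mm) of the translation
#'   random walks; rotation walks use `motion_sd / 50` radians so that both
#'   contribute comparably to framewise displacement.
#' @param drift_amplitude Standard deviation of the slow scanner drift added
#'   to every voxel, in signal units; set 0 to disable.
#' @param drift_max_hz Upper frequency bound of the drift (random
#'   coefficients on the discrete-cosine drift basis below this frequency,
#'   kept under the 0.01 Hz high-pass cutoff so filtering removes it).
#' @param volume_shape Integer voxel grid dimensions, length 3.
#' @param baseline Mean signal level (so percent-signal-change scaling is
#'   well defined).
#' @param source_sigma_vox Gaussian spatial width (sd, voxels) of planted
#'   source blobs.
#' @param seed Integer seed.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_subjects = 31L,
                             n_volumes = 212L,
                             tr = 2.015,
                             n_shared_sources = 3L,
                             n_specific_sources_per_condition = 2L,
                             shared_tc_correlation = 0.7,
                             dialog_source = FALSE,
                             dialog_deactivated_source = FALSE,
                             noise_sd = 1,
                             source_amplitude = 1,
                             motion_sd = 0.025,
                             drift_amplitude = 2,
                             drift_max_hz = 0.0045,
                             volume_shape = c(20L, 20L, 12L),
                             baseline = 100,
                             source_sigma_vox = 1.4,
                             seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_volumes = as.integer(n_volumes),
    tr = tr,
    n_shared_sources = as.integer(n_shared_sources),
    n_specific_sources_per_condition = as.integer(n_specific_sources_per_condition),
    shared_tc_correlation = shared_tc_correlation,
    dialog_source = isTRUE(dialog_source),
    dialog_deactivated_source = isTRUE(dialog_deactivated_source),
    noise_sd = noise_sd,
    source_amplitude = source_amplitude,
    motion_sd = motion_sd,
    drift_amplitude = drift_amplitude,
    drift_max_hz = drift_max_hz,
    volume_shape = as.integer(volume_shape),
    baseline = baseline,
    source_sigma_vox = source_sigma_vox,
    seed = as.integer(seed)
  )
  if (cfg$n_subjects < 1) stop_invalid("`n_subjects` must be >= 1.")
  if (cfg$n_volumes < 8) stop_invalid("`n_volumes` must be >= 8.")
  if (cfg$tr <= 0) stop_invalid("`tr` must be positive.")
  if (cfg$shared_tc_correlation < 0 || cfg$shared_tc_correlation > 1) {
    stop_invalid("`shared_tc_correlation` must be in [0, 1].")
  }
  if (length(cfg$volume_shape) != 3 || any(cfg$volume_shape < 1)) {
    stop_invalid("`volume_shape` must be three positive integers.")
  }
  if (cfg$noise_sd < 0 || cfg$motion_sd < 0 || cfg$drift_amplitude < 0) {
    stop_invalid("`noise_sd`, `motion_sd` and `drift_amplitude` must be >= 0.")
  }
  if (cfg$drift_max_hz <= 0 || cfg$drift_max_hz >= 0.005) {
    stop_invalid("`drift_max_hz` must lie in (0, 0.005).")
  }
  structure(cfg, class = "synthetic_config")
}

# Deterministic farthest-point ordering of candidate blob centres so that a
# small number of sources lands maximally spread out on the grid.
source_centres <- function(vol_dim, n_sources) {
  fr <- list(c(0.25, 0.5, 0.75), c(0.25, 0.5, 0.75), c(0.3, 0.7))
  cand <- as.matrix(expand.grid(
    fr[[1]] * vol_dim[1], fr[[2]] * vol_dim[2], fr[[3]] * vol_dim[3]
  ))
  if (n_sources > nrow(cand)) {
    rlang::abort(
      sprintf("Cannot place %d sources on this grid without overlap.", n_sources),
      class = "narranet_generation_failure"
    )
  }
  chosen <- 1L
  while (length(chosen) < n_sources) {
    rest <- setdiff(seq_len(nrow(cand)), chosen)
    mind <- vapply(rest, function(i) {
      min(sqrt(rowSums((cand[chosen, , drop = FALSE] -
                          matrix(cand[i, ], length(chosen), 3, byrow = TRUE))^2)))
    }, numeric(1))
    chosen <- c(chosen, rest[which.max(mind)])
  }
  cand[chosen, , drop = FALSE]
}

# Gaussian blob maps (n_sources x V), peak 1, small weights truncated to zero
# so maps are sparse (super-Gaussian, as spatial ICA assumes).
source_maps <- function(vol_dim, n_sources, sigma_vox) {
  centres <- source_centres(vol_dim, n_sources)
  coords <- voxel_coords(vol_dim)
  maps <- matrix(0, n_sources, nrow(coords))
  for (k in seq_len(n_sources)) {
    d2 <- rowSums(sweep(coords, 2, centres[k, ])^2)
    w <- exp(-d2 / (2 * sigma_vox^2))
    w[w < 0.01] <- 0
    maps[k, ] <- w
  }
  cc <- cross_correlations(maps, maps)
  off <- abs(cc[upper.tri(cc)])
  if (length(off) && max(off) >= 0.1) {
    rlang::abort(
      sprintf(
        "Source maps overlap too much (max pairwise |r| = %.3f >= 0.1).",
        max(off)
      ),
      class = "narranet_generation_failure"
    )
  }
  maps
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (s == 0) stop_invalid("Cannot z-score a constant series.")
  (x - mean(x)) / s
}

#' Generate a ground-truthed two-condition BOLD dataset
#'
#' Simulates, for every subject and condition, a run equal to
#' `baseline + sum_k amplitude * timecourse_k (x) map_k + drift + noise`,
#' together with 6-parameter motion random walks. Shared sources obtain
#' condition time-course pairs built as
#' `sqrt(rho) * common + sqrt(1 - rho) * residual`, so the target
#' cross-condition correlation `rho` is analytically controlled. A
#' dialog-locked source follows the HRF-convolved dialog envelope of the
#' schedule (plus small condition-specific noise). Modality-specific sources
#' are silent outside their own condition. Identical seeds give bit-identical
#' datasets.
#'
#' @param config A [synthetic_config()].
#' @param schedule An [generate_event_schedule()] result covering the run; if
#'   `NULL`, one is generated from the config seed with a 40% dialog fraction.
#' @return A `bold_dataset`: run matrices (`t x voxels`) per subject and
#'   condition, motion traces, the schedule, the voxel mask, subject metadata
#'   (including counterbalanced `movie_first` flags) and a `ground_truth` list
#'   with planted maps, time-courses, kinds and realized cross-condition
#'   correlations.
#' @export
generate_dataset <- function(config, schedule = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  run_seconds <- config$n_volumes * config$tr
  if (is.null(schedule)) {
    schedule <- generate_event_schedule(
      total_duration = run_seconds,
      dialog_fraction = 0.4,
      seed = derive_seed(config$seed, "schedule")
    )
  }
  if (schedule_total_duration(schedule) < run_seconds - 1e-6) {
    stop_invalid("Schedule (%.1f s) does not cover the run (%.1f s).",
                 schedule_total_duration(schedule), run_seconds)
  }

  kinds <- c(
    rep("shared", config$n_shared_sources),
    rep(c("movie_only", "script_only"),
        each = config$n_specific_sources_per_condition),
    if (config$dialog_source) "dialog_locked",
    if (config$dialog_deactivated_source) "dialog_locked"
  )
  signs <- rep(1, length(kinds))
  if (config$dialog_deactivated_source) signs[length(signs)] <- -1
  n_src <- length(kinds)
  if (n_src == 0 && config$noise_sd == 0 && config$drift_amplitude == 0) {
    stop_invalid("Dataset would be constant: no sources, no noise, no drift.")
  }

  has_dialog_sources <- any(kinds == "dialog_locked")
  if (has_dialog_sources && !any(schedule$trial_type == "dialog")) {
    stop_invalid("A dialog-locked source needs at least one dialog event.")
  }

  vol_dim <- config$volume_shape
  n_vox <- prod(vol_dim)
  t_len <- config$n_volumes
  maps <- if (n_src > 0) {
    source_maps(vol_dim, n_src, config$source_sigma_vox)
  } else {
    matrix(0, 0, n_vox)
  }

  env <- if (has_dialog_sources) {
    zscore(dialog_envelope(schedule, t_len, config$tr))
  } else {
    NULL
  }

  with_local_seed(config$seed, {
    rho <- config$shared_tc_correlation
    tc <- array(0, dim = c(t_len, n_src, 2),
                dimnames = list(NULL, NULL, c("movie", "script")))
    realized <- rep(NA_real_, n_src)
    for (k in seq_len(n_src)) {
      kind <- kinds[k]
      if (kind == "shared") {
        common <- rnorm(t_len)
        a <- sqrt(rho) * common + sqrt(1 - rho) * rnorm(t_len)
        b <- sqrt(rho) * common + sqrt(1 - rho) * rnorm(t_len)
        tc[, k, "movie"] <- zscore(a)
        tc[, k, "script"] <- zscore(b)
      } else if (kind == "movie_only") {
        tc[, k, "movie"] <- zscore(rnorm(t_len))
      } else if (kind == "script_only") {
        tc[, k, "script"] <- zscore(rnorm(t_len))
      } else { # dialog_locked
        # A lone dialog source is the envelope plus small noise. When both an
        # activated and a deactivated dialog source are planted, each needs
        # its own non-envelope temporal direction (loadings sqrt(0.65) and
        # -sqrt(0.5)); otherwise the pair would be temporally collinear
        # through the shared envelope and no decomposition could separate
        # their maps.
        both <- config$dialog_source && config$dialog_deactivated_source
        for (cond in c("movie", "script")) {
          tc[, k, cond] <- if (signs[k] > 0) {
            if (both) {
              zscore(sqrt(0.65) * env + sqrt(0.35) * rnorm(t_len))
            } else {
              zscore(env + 0.15 * rnorm(t_len))
            }
          } else {
            zscore(-(sqrt(0.5) * env + sqrt(0.5) * rnorm(t_len)))
          }
        }
      }
      va <- stats::var(tc[, k, "movie"])
      vb <- stats::var(tc[, k, "script"])
      realized[k] <- if (va > 0 && vb > 0) {
        cor(tc[, k, "movie"], tc[, k, "script"])
      } else {
        0
      }
    }

    n_sub <- config$n_subjects
    runs <- vector("list", n_sub)
    motion <- vector("list", n_sub)
    times <- (seq_len(t_len) - 1) * config$tr
    for (s in seq_len(n_sub)) {
      runs[[s]] <- list()
      motion[[s]] <- list()
      for (cond in c("movie", "script")) {
        signal <- matrix(config$baseline, t_len, n_vox)
        if (n_src > 0) {
          signal <- signal +
            config$source_amplitude * (tc[, , cond, drop = FALSE][, , 1] %*% maps)
        }
        if (config$drift_amplitude > 0) {
          # Slow scanner drift: random coefficients on the discrete-cosine
          # drift basis below drift_max_hz. A windowed off-grid cosine would
          # leave an edge-concentrated residual after high-pass filtering
          # that is spatially global and defeats shift-permutation
          # exchangeability; on-basis drift is removed exactly at the
          # 0.01 Hz cutoff, which is the point of modelling it.
          m <- max(1L, floor(2 * t_len * config$tr * config$drift_max_hz))
          i <- seq_len(t_len)
          dbasis <- vapply(seq_len(m), function(kk) {
            cos(pi * (2 * i - 1) * kk / (2 * t_len))
          }, numeric(t_len))
          drift <- dbasis %*% rnorm(m)
          drift <- config$drift_amplitude * drift / stats::sd(drift)
          signal <- signal + as.vector(drift)
        }
        if (config$noise_sd > 0) {
          signal <- signal + matrix(rnorm(t_len * n_vox, sd = config$noise_sd),
                                    t_len, n_vox)
        }
        runs[[s]][[cond]] <- signal
        trans <- vapply(1:3, function(i) cumsum(rnorm(t_len, sd = config$motion_sd)),
                        numeric(t_len))
        rot <- vapply(1:3, function(i) cumsum(rnorm(t_len, sd = config$motion_sd / 50)),
                      numeric(t_len))
        motion[[s]][[cond]] <- cbind(trans, rot)
      }
    }

    ground_truth <- list(
      maps = maps,
      timecourses = tc,
      kinds = kinds,
      signs = signs,
      amplitude = config$source_amplitude,
      baseline = config$baseline,
      realized_cross_correlation = realized
    )

    structure(
      list(
        runs = runs,
        motion = motion,
        schedule = schedule,
        subjects = tibble::tibble(
          subject = sprintf("sub-%02d", seq_len(n_sub)),
          movie_first = seq_len(n_sub) <= floor(n_sub / 2)
        ),
        conditions = c("movie", "script"),
        vol_dim = vol_dim,
        mask = rep(TRUE, n_vox),
        tr = config$tr,
        n_volumes = t_len,
        ground_truth = ground_truth,
        config = config
      ),
      class = "bold_dataset"
    )
  })
}

#' @export
print.bold_dataset <- function(x, ...) {
  cat(sprintf(
    "<bold_dataset> %d subjects x %d conditions, %d volumes @ TR %.3f s, grid %s\n",
    length(x$runs), length(x$conditions), x$n_volumes, x$tr,
    paste(x$vol_dim, collapse = "x")
  ))
  if (!is.null(x$ground_truth) && length(x$ground_truth$kinds)) {
    cat("  planted sources:",
        paste(x$ground_truth$kinds, collapse = ", "), "\n")
  }
  invisible(x)
}

n_runs <- function(dataset) length(dataset$runs) * length(dataset$conditions)

# Iterate over runs in a fixed order (subject-major, movie before script).
run_index_table <- function(dataset) {
  expand.grid(
    condition = dataset$conditions,
    subject = seq_along(dataset$runs),
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )[, c("subject", "condition")]
}

get_run <- function(dataset, subject, condition) {
  dataset$runs[[subject]][[condition]]
}
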