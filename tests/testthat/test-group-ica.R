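# A noiseless 3-source dataset reused by several blocks.
noiseless_dataset <- function(seed = 2) {
  generate_dataset(quick_config(
    n_subjects = 3L, n_volumes = 80L, n_shared_sources = 3L,
    n_specific_sources_per_condition = 0L, shared_tc_correlation = 0.9,
    noise_sd = 0, drift_amplitude = 0, seed = seed
  ))
}

test_that("noise-free planted maps are recovered at spatial |r| > 0.95", {
  ds <- noiseless_dataset()
  fit <- fit_group_ica(ds, n_components = 3, r1 = 3, seed = 1)
  m <- greedy_match(fit$model$group_maps, ds$ground_truth$maps)
  expect_true(all(m$r > 0.95))
})

test_that("asking for more components than the data rank fails", {
  ds <- generate_dataset(quick_config(
    n_subjects = 2L, n_volumes = 60L, n_shared_sources = 2L,
    n_specific_sources_per_condition = 0L, shared_tc_correlation = 1,
    noise_sd = 0, drift_amplitude = 0, seed = 3
  ))
  # rank 2: identical time-courses across conditions and subjects
  expect_error(fit_group_ica(ds, n_components = 4, r1 = 4, seed = 1),
               class = "narranet_invalid_argument")
  expect_error(fit_group_ica(ds, n_components = 5, r1 = 3, seed = 1),
               class = "narranet_invalid_argument")
})

test_that("the fit is deterministic given the seed", {
  ds <- noiseless_dataset(seed = 5)
  f1 <- fit_group_ica(ds, n_components = 3, r1 = 3, seed = 7)
  f2 <- fit_group_ica(ds, n_components = 3, r1 = 3, seed = 7)
  expect_equal(f1$model$group_maps, f2$model$group_maps, tolerance = 1e-8)
  expect_identical(f1$model$infomax$iterations, f2$model$infomax$iterations)
})

test_that("strict mode raises a convergence failure when starved of iterations", {
  ds <- noiseless_dataset(seed = 6)
  expect_error(
    fit_group_ica(ds, n_components = 3, r1 = 3, seed = 1, max_iter = 3,
                  strict = TRUE),
    class = "narranet_convergence_failure"
  )
  expect_warning(
    fit_group_ica(ds, n_components = 3, r1 = 3, seed = 1, max_iter = 3),
    class = "narranet_convergence_failure"
  )
})

test_that("GICA3 back-reconstruction averages exactly to the group maps", {
  ds <- generate_dataset(quick_config(seed = 11))
  ds <- preprocess_dataset(ds, fwhm = 4, voxel_size = 3)
  fit <- fit_group_ica(ds, n_components = 4, seed = 2)
  comp <- backreconstruct(ds, fit$reduction, fit$model)
  expect_equal(narranet:::mean_over_runs(comp$maps), fit$model$group_maps,
               tolerance = 1e-8)
})

test_that("a single-run dataset back-reconstructs to the group maps", {
  set.seed(8)
  t_len <- 50; vd <- c(8, 8, 4); v <- prod(vd)
  m <- matrix(100 + rnorm(t_len * v), t_len, v)
  ds <- structure(
    list(runs = list(list(movie = m)),
         motion = list(list(movie = matrix(0, t_len, 6))),
         schedule = NULL,
         subjects = tibble::tibble(subject = "sub-01", movie_first = TRUE),
         conditions = "movie", vol_dim = vd, mask = rep(TRUE, v), tr = 2,
         n_volumes = t_len, ground_truth = NULL, config = NULL),
    class = "bold_dataset"
  )
  fit <- suppressWarnings(fit_group_ica(ds, n_components = 2, r1 = 4, seed = 4))
  comp <- backreconstruct(ds, fit$reduction, fit$model)
  expect_equal(matrix(comp$maps[1, 1, , ], 2), fit$model$group_maps,
               tolerance = 1e-8)

  # mismatched reduction/model is rejected
  ds2 <- generate_dataset(quick_config(seed = 1))
  expect_error(backreconstruct(ds2, fit$reduction, fit$model),
               class = "narranet_invalid_argument")
})

test_that("noise-free subject time-courses track the planted sources", {
  ds <- noiseless_dataset(seed = 9)
  fit <- fit_group_ica(ds, n_components = 3, r1 = 3, seed = 1)
  comp <- backreconstruct(ds, fit$reduction, fit$model)
  m <- greedy_match(fit$model$group_maps, ds$ground_truth$maps)
  for (ci in 1:2) {
    cond <- comp$conditions[ci]
    for (s in 1:3) {
      tcs <- matrix(comp$timecourses[s, ci, , ], ds$n_volumes)
      r <- abs(diag(cor(tcs[, m$row], ds$ground_truth$timecourses[, , cond])))
      expect_true(all(r > 0.9))
    }
  }
})

test_that("percent-signal-change scaling has the contracted invariances", {
  ds <- generate_dataset(quick_config(n_subjects = 2L, seed = 13))
  fit <- fit_group_ica(ds, n_components = 4, seed = 5)
  comp <- backreconstruct(ds, fit$reduction, fit$model)
  scaled <- scale_percent_signal_change(comp, ds)

  # product map x tc unchanged by the rescaling
  k <- 2; s <- 1
  prod_raw <- comp$timecourses[s, 1, , k] %o% comp$maps[s, 1, k, ]
  prod_scaled <- scaled$timecourses[s, 1, , k] %o% scaled$maps[s, 1, k, ]
  expect_equal(prod_scaled, prod_raw, tolerance = 1e-8)

  # definitional recomputation: tc * 100 * rms(map) / mean signal
  mu <- colMeans(ds$runs[[s]]$movie)
  fac <- 100 * sqrt(mean(comp$maps[s, 1, k, ]^2)) / mean(mu)
  expect_equal(scaled$timecourses[s, 1, , k],
               comp$timecourses[s, 1, , k] * fac, tolerance = 1e-8)

  # doubling the raw data leaves percent-scaled time-courses unchanged
  ds2 <- ds
  for (i in seq_along(ds2$runs)) {
    for (cond in ds2$conditions) ds2$runs[[i]][[cond]] <- 2 * ds2$runs[[i]][[cond]]
  }
  fit2 <- fit_group_ica(ds2, n_components = 4, seed = 5)
  comp2 <- backreconstruct(ds2, fit2$reduction, fit2$model)
  scaled2 <- scale_percent_signal_change(comp2, ds2)
  m <- greedy_match(
    matrix(scaled2$timecourses[1, 1, , ], ds$n_volumes),
    matrix(scaled$timecourses[1, 1, , ], ds$n_volumes)
  )
  perm <- m$row
  for (k in 1:4) {
    a <- scaled$timecourses[1, 1, , k]
    b <- scaled2$timecourses[1, 1, , perm[k]]
    b <- b * sign(cor(a, b)) # ICA sign indeterminacy
    expect_equal(b, a, tolerance = 1e-6)
  }

  # zero-mean voxels make percent scaling undefined
  ds0 <- ds
  ds0$runs[[1]]$movie[, 5] <- 0
  expect_error(scale_percent_signal_change(comp, ds0),
               class = "narranet_invalid_argument")
})

test_that("component signs are validated against the raw signal", {
  ds <- generate_dataset(quick_config(noise_sd = 0.3, seed = 17))
  fit <- fit_group_ica(ds, n_components = 4, seed = 3)
  comp <- backreconstruct(ds, fit$reduction, fit$model)
  val <- validate_component_signs(comp, ds, n_peak_voxels = 40)
  # positive planted maps, positive-peak group maps: nothing to flip
  expect_identical(val$signs, rep(1L, 4))

  flipped <- comp
  flipped$maps[, , 2, ] <- -flipped$maps[, , 2, ]
  flipped$timecourses[, , , 2] <- -flipped$timecourses[, , , 2]
  val2 <- validate_component_signs(flipped, ds, n_peak_voxels = 40)
  expect_identical(val2$signs[2], -1L)
  expect_identical(val2$signs[-2], rep(1L, 3))
  expect_equal(val2$components$maps, comp$maps, tolerance = 1e-12)

  expect_error(validate_component_signs(comp, ds, n_peak_voxels = 1e6),
               class = "narranet_invalid_argument")
})

test_that("clean component maps are pairwise decorrelated", {
  ds <- generate_dataset(quick_config(
    n_shared_sources = 3L, n_specific_sources_per_condition = 1L,
    noise_sd = 0.1, seed = 19
  ))
  ds <- preprocess_dataset(ds, fwhm = 0) # drop the scanner drift
  fit <- fit_group_ica(ds, n_components = 5, seed = 2)
  cc <- cor(t(fit$model$group_maps))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
})

test_that("five planted sources at SNR 1 are recovered in >= 9 of 10 seeds", {
  hits <- 0L
  for (seed in 1:10) {
    ds <- generate_dataset(quick_config(
      n_subjects = 6L, n_shared_sources = 3L,
      n_specific_sources_per_condition = 1L, noise_sd = 1, seed = seed
    ))
    ds <- preprocess_dataset(ds, fwhm = 4, voxel_size = 3)
    fit <- suppressWarnings(fit_group_ica(ds, n_components = 5, seed = seed))
    m <- greedy_match(fit$model$group_maps, ds$ground_truth$maps)
    if (all(m$r > 0.8)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("InfoMax matches an exhaustive rotation search on a noiseless 2x2 mixture", {
  set.seed(42)
  n <- 2000
  s_true <- rbind(sign(rnorm(n)) * rexp(n), sign(rnorm(n)) * rexp(n))
  a_mix <- matrix(c(1.2, 0.4, -0.3, 0.9), 2, 2)
  x <- a_mix %*% s_true
  xc <- x - rowMeans(x)
  e <- eigen(tcrossprod(xc) / n, symmetric = TRUE)
  z <- diag(1 / sqrt(e$values)) %*% t(e$vectors) %*% xc

  fit <- infomax_unmix(z, seed = 1)
  w <- fit$W
  if (det(w) < 0) w[2, ] <- -w[2, ]
  sv <- svd(w)
  rot <- sv$u %*% t(sv$v)
  theta_w <- (atan2(rot[2, 1], rot[1, 1]) * 180 / pi) %% 90

  grid <- seq(0, 90, by = 0.25)
  quality <- vapply(grid, function(th) {
    r <- th * pi / 180
    rm <- matrix(c(cos(r), sin(r), -sin(r), cos(r)), 2, 2)
    cc <- abs(cor(t(rm %*% z), t(s_true)))
    max(mean(c(cc[1, 1], cc[2, 2])), mean(c(cc[1, 2], cc[2, 1])))
  }, numeric(1))
  theta_star <- grid[which.max(quality)] %% 90

  d <- abs(theta_w - theta_star)
  expect_lt(min(d, 90 - d), 2)
})
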