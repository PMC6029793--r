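test_that("the spatial match tensor books matched and unmatched entries", {
  set.seed(1)
  n_sub <- 3; k <- 4; v <- 200
  maps <- array(rnorm(n_sub * 2 * k * v), c(n_sub, 2, k, v))
  maps[, 2, , ] <- maps[, 1, , ] # identical across conditions
  comp <- make_components(array(rnorm(n_sub * 2 * 30 * k), c(n_sub, 2, 30, k)),
                          maps = maps, vol_dim = c(v, 1, 1))
  mt <- spatial_match_tensor(comp)
  expect_identical(mt$n_total, as.integer(n_sub * k * k))
  expect_identical(mt$n_matched, as.integer(n_sub * k))
  expect_equal(mt$matched_mean, 1, tolerance = 1e-12)
  expect_equal(mt$matched_sd, 0, tolerance = 1e-12)

  # independent random maps: unmatched mean within 3 SE of 0
  maps2 <- array(rnorm(n_sub * 2 * k * v), c(n_sub, 2, k, v))
  mt2 <- spatial_match_tensor(make_components(
    array(rnorm(n_sub * 2 * 30 * k), c(n_sub, 2, 30, k)),
    maps = maps2, vol_dim = c(v, 1, 1)
  ))
  n_un <- mt2$n_total - mt2$n_matched
  se <- (1 / sqrt(v - 3)) / sqrt(n_un)
  expect_lt(abs(mt2$unmatched_mean), 3 * se + 0.01)

  # constant maps are zeroed with a warning
  maps3 <- maps2
  maps3[1, 1, 2, ] <- 5
  expect_warning(
    mt3 <- spatial_match_tensor(make_components(
      array(rnorm(n_sub * 2 * 30 * k), c(n_sub, 2, 30, k)),
      maps = maps3, vol_dim = c(v, 1, 1)
    )),
    "constant"
  )
  expect_equal(mt3$values[1, 2, 3], 0)
  expect_s3_class(tidy(mt3), "tbl_df")
})

test_that("condition-averaged maps follow the arithmetic-mean definition", {
  set.seed(2)
  maps <- array(rnorm(2 * 2 * 3 * 50), c(2, 2, 3, 50))
  comp <- make_components(array(rnorm(2 * 2 * 20 * 3), c(2, 2, 20, 3)),
                          maps = maps, vol_dim = c(50, 1, 1))
  avg <- average_maps_across_conditions(comp)
  expect_equal(avg[2, 3, ], (maps[2, 1, 3, ] + maps[2, 2, 3, ]) / 2,
               tolerance = 1e-12)

  same <- maps; same[, 2, , ] <- same[, 1, , ]
  comp_same <- make_components(comp$timecourses, maps = same, vol_dim = c(50, 1, 1))
  expect_equal(average_maps_across_conditions(comp_same)[1, 1, ],
               same[1, 1, 1, ], tolerance = 1e-12)

  neg <- maps; neg[, 2, , ] <- -neg[, 1, , ]
  comp_neg <- make_components(comp$timecourses, maps = neg, vol_dim = c(50, 1, 1))
  expect_equal(max(abs(average_maps_across_conditions(comp_neg))), 0)
})

test_that("ranking A correlates group-averaged time-courses", {
  set.seed(3)
  t_len <- 60; k <- 3; n_sub <- 4
  tcs <- array(rnorm(n_sub * 2 * t_len * k), c(n_sub, 2, t_len, k))
  tcs[, 2, , 1] <- tcs[, 1, , 1]    # component 1 identical across conditions
  tcs[, 2, , 2] <- -tcs[, 1, , 2]   # component 2 negated
  ra <- rank_correlation_over_averages(make_components(tcs))
  expect_equal(ra$r_A[1], 1, tolerance = 1e-12)
  expect_equal(ra$r_A[2], -1, tolerance = 1e-12)
  expect_identical(ra$rank_A[1], 1L)
})

test_that("ranking B averages subject-level correlations", {
  t_len <- 40; n_sub <- 3
  rho <- c(0.2, 0, -0.2)
  tcs <- array(0, c(n_sub, 2, t_len, 1))
  for (s in 1:n_sub) {
    pair <- exact_correlated_pair(t_len, rho[s], seed = s)
    tcs[s, 1, , 1] <- pair[, 1]
    tcs[s, 2, , 1] <- pair[, 2]
  }
  rb <- rank_average_over_correlations(make_components(tcs))
  expect_equal(rb$r_B, 0, tolerance = 1e-12)

  same <- array(rnorm(2 * 2 * t_len * 2), c(2, 2, t_len, 2))
  same[, 2, , ] <- same[, 1, , ]
  expect_equal(rank_average_over_correlations(make_components(same))$r_B,
               c(1, 1), tolerance = 1e-12)
})

test_that("subject noise attenuates ranking B below ranking A for shared signals", {
  worse <- vapply(1:10, function(seed) {
    set.seed(seed)
    t_len <- 150; n_sub <- 8
    common <- rnorm(t_len)
    tcs <- array(0, c(n_sub, 2, t_len, 1))
    for (s in 1:n_sub) {
      tcs[s, 1, , 1] <- common + rnorm(t_len)
      tcs[s, 2, , 1] <- common + rnorm(t_len)
    }
    comp <- make_components(tcs)
    rank_average_over_correlations(comp)$r_B -
      rank_correlation_over_averages(comp)$r_A
  }, numeric(1))
  expect_true(all(worse <= 0.05))
})

test_that("rankings are invariant to the admissible rescalings", {
  set.seed(4)
  t_len <- 80; k <- 4; n_sub <- 5
  tcs <- array(rnorm(n_sub * 2 * t_len * k), c(n_sub, 2, t_len, k))
  comp <- make_components(tcs)
  base_a <- rank_correlation_over_averages(comp)
  base_b <- rank_average_over_correlations(comp)

  # A: common positive rescaling of each condition's time-courses
  scaled <- tcs
  scaled[, 1, , ] <- 3.2 * scaled[, 1, , ]
  scaled[, 2, , ] <- 0.4 * scaled[, 2, , ]
  expect_equal(rank_correlation_over_averages(make_components(scaled))$r_A,
               base_a$r_A, tolerance = 1e-12)

  # B: arbitrary positive per-subject, per-condition rescaling
  scaled_b <- tcs
  for (s in 1:n_sub) {
    scaled_b[s, 1, , ] <- runif(1, 0.1, 5) * scaled_b[s, 1, , ]
    scaled_b[s, 2, , ] <- runif(1, 0.1, 5) * scaled_b[s, 2, , ]
  }
  expect_equal(rank_average_over_correlations(make_components(scaled_b))$r_B,
               base_b$r_B, tolerance = 1e-12)
})

test_that("shift-permutation nulls have the contracted size and location", {
  set.seed(5)
  nd <- shift_permutation_null(rnorm(212), matrix(rnorm(212 * 40), 212, 40), 2)
  expect_identical(length(nd$values), 8360L)
  expect_identical(nd$n_shifts, 209L)

  tiny <- shift_permutation_null(rnorm(6), rnorm(6), 2)
  expect_identical(tiny$n_shifts, 3L) # offsets {2, 3, 4} by enumeration

  # enumeration oracle for the tiny case
  a <- c(3, 1, 4, 1, 5, 9); b <- c(2, 7, 1, 8, 2, 8)
  nd2 <- shift_permutation_null(a, b, 2)
  manual <- vapply(2:4, function(s) cor(a[((0:5 + s) %% 6) + 1], b), numeric(1))
  expect_equal(sort(nd2$values), sort(manual), tolerance = 1e-12)

  # white-noise null centred at zero
  big <- shift_permutation_null(rnorm(300), matrix(rnorm(300 * 20), 300, 20), 2)
  se <- sd(big$values) / sqrt(length(big$values) / 20) # shifts share series
  expect_lt(abs(mean(big$values)), 3 * sd(big$values) / sqrt(295) + 0.02)

  expect_error(shift_permutation_null(rep(1, 50), rnorm(50)),
               class = "narranet_invalid_argument")
  expect_error(shift_permutation_null(rnorm(5), rnorm(5), 2),
               class = "narranet_invalid_argument")
})

test_that("permutation p-values follow the doubled ecdf with add-one correction", {
  set.seed(6)
  nd <- shift_permutation_null(rnorm(212), matrix(rnorm(212 * 40), 212, 40), 2)
  n <- length(nd$values)
  expect_equal(permutation_pvalue(max(nd$values) + 1, nd), 2 / (n + 1),
               tolerance = 1e-12)
  expect_equal(permutation_pvalue(median(nd$values), nd), 1, tolerance = 0.01)
  expect_equal(unname(permutation_pvalue(quantile(nd$values, 0.975), nd)),
               0.05, tolerance = 0.005)
  # counting oracle on a small null
  small <- narranet:::new_null_distribution(c(-0.3, -0.1, 0, 0.2, 0.5), 5, 2, 1)
  expect_equal(permutation_pvalue(0.4, small), 2 * (1 + 1) / 6, tolerance = 1e-12)
})

test_that("BH adjustment matches the brute-force step-up everywhere", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  expect_equal(fdr_adjust(0.37), 0.37)
  expect_equal(fdr_adjust(rep(0.2, 6)), rep(0.2, 6))
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(fdr_adjust(p), brute_force_bh(p), tolerance = 1e-12)
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), class = "narranet_invalid_argument")
})

test_that("top-component selection reports the scheme-A winners and overlap", {
  set.seed(8)
  tcs <- array(rnorm(4 * 2 * 120 * 8), c(4, 2, 120, 8))
  tcs[, 2, , 3] <- tcs[, 1, , 3] + 0.1 * rnorm(120)
  rt <- ranking_table(make_components(tcs))
  expect_identical(rt$rank_A[3], 1L)
  expect_true(all(rt$q_A >= rt$p_A))
  expect_identical(sort(rt$rank_A), 1:8)

  top <- select_top_components(rt, k = 8)
  expect_setequal(top$selected, 1:8)
  expect_identical(select_top_components(rt, k = 1)$selected, 3L)
  expect_error(select_top_components(rt, k = 9),
               class = "narranet_invalid_argument")

  # identical rankings imply full top-7 overlap
  rt2 <- rt
  rt2$r_B <- rt2$r_A; rt2$rank_B <- rt2$rank_A
  expect_identical(select_top_components(rt2, k = 5)$overlap_top7, 7L)
})

test_that("reference-region correlations recover planted regional synchrony", {
  cfg <- quick_config(n_subjects = 5L, n_volumes = 120L,
                      n_shared_sources = 1L,
                      n_specific_sources_per_condition = 0L,
                      shared_tc_correlation = 0.9, noise_sd = 0.5, seed = 21)
  ds <- preprocess_dataset(generate_dataset(cfg), fwhm = 0)
  blob <- ds$ground_truth$maps[1, ] > 0 # full support, so other ROIs are pure noise
  atlas <- integer(length(ds$mask))
  atlas[blob] <- 1L
  atlas[!blob] <- 1L + synthetic_atlas(ds$vol_dim, n_rois = 5, seed = 2)[!blob]
  rr <- reference_region_correlations(ds, atlas)
  expect_identical(rr$rank[rr$roi == 1], 1L)
  # pure-noise regions stay within 3 SE of zero
  expect_lt(max(abs(rr$r[rr$roi != 1])), 3 / sqrt(120 - 3) + 0.15)

  # one atlas label covering the whole mask reproduces the global correlation
  rr_all <- reference_region_correlations(ds, rep(1L, length(ds$mask)))
  expect_equal(rr_all$r, attr(rr_all, "global_r"), tolerance = 1e-12)

  expect_error(reference_region_correlations(ds, rep(1L, 5)),
               class = "narranet_invalid_argument")
})
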