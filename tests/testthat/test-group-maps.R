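# Build a stat_map directly from a t-value field (tests of thresholding
# logic need exact control over suprathreshold sets).
stat_map_from <- function(t_vals, vol_dim, df = 30L) {
  structure(
    list(t = as.numeric(t_vals), df = df, mask = rep(TRUE, prod(vol_dim)),
         vol_dim = as.integer(vol_dim), n_zero_variance = 0L),
    class = "stat_map"
  )
}

test_that("one-sample t-maps follow the t statistic definition", {
  maps <- rbind(c(1, 0, 5), c(2, 0, 5), c(3, 0, 5))
  sm <- suppressWarnings(one_sample_tmap(maps, vol_dim = c(3, 1, 1)))
  expect_equal(sm$t[1], 2 / (1 / sqrt(3)), tolerance = 1e-12) # 3.4641
  expect_equal(sm$t[2], 0)
  expect_identical(sm$df, 2L)
  expect_warning(one_sample_tmap(maps, vol_dim = c(3, 1, 1)),
                 "zero-variance")

  # 31 subjects give 30 degrees of freedom
  set.seed(1)
  big <- matrix(rnorm(31 * 10), 31, 10)
  expect_identical(one_sample_tmap(big, vol_dim = c(10, 1, 1))$df, 30L)

  # scale invariance
  sm2 <- one_sample_tmap(big * 7.3, vol_dim = c(10, 1, 1))
  expect_equal(sm2$t, one_sample_tmap(big, vol_dim = c(10, 1, 1))$t,
               tolerance = 1e-10)

  expect_error(one_sample_tmap(big[1, , drop = FALSE], vol_dim = c(10, 1, 1)),
               class = "narranet_invalid_argument")
})

test_that("cluster extraction applies height, extent and connectivity rules", {
  vd <- c(12, 12, 6)
  tv <- rep(0, prod(vd))
  sm0 <- stat_map_from(tv, vd)
  expect_identical(nrow(threshold_statmap(sm0, fwe = FALSE)), 0L)

  # a compact blob of exactly 49 suprathreshold voxels vs extent 50
  arr <- array(0, vd)
  blob_vox <- which(array(seq_len(prod(vd)), vd) > 0)[1:49]
  coords <- expand.grid(x = 1:12, y = 1:12, z = 1:6)
  inside <- with(coords, x <= 7 & y <= 7 & z <= 1)  # 49-voxel plate
  arr[inside] <- 10
  cl49 <- threshold_statmap(stat_map_from(arr, vd), height_p = 0.001,
                            fwe = FALSE, extent = 50)
  expect_identical(nrow(cl49), 0L)

  inside50 <- with(coords, (x <= 7 & y <= 7 & z == 1) | (x == 1 & y == 1 & z == 2))
  arr2 <- array(0, vd)
  arr2[inside50] <- 10
  cl50 <- threshold_statmap(stat_map_from(arr2, vd), height_p = 0.001,
                            fwe = FALSE, extent = 50)
  expect_identical(nrow(cl50), 1L)
  expect_identical(cl50$size, 50L)
  expect_equal(cl50$peak_t, 10)

  # two blobs separated by more than one voxel stay distinct clusters
  arr3 <- array(0, vd)
  arr3[2:3, 2:3, 2:3] <- 8
  arr3[8:9, 8:9, 4:5] <- 9
  cl2 <- threshold_statmap(stat_map_from(arr3, vd), fwe = FALSE, extent = 2)
  expect_identical(nrow(cl2), 2L)

  # FWE mode uses the Bonferroni-divided Student-t quantile
  smf <- stat_map_from(arr3, vd)
  clf <- threshold_statmap(smf, height_p = 0.001, fwe = TRUE, extent = 2)
  expect_equal(attr(clf, "threshold_t"),
               qt(1 - 0.001 / prod(vd), df = 30), tolerance = 1e-12)

  expect_error(threshold_statmap(smf, height_p = 2),
               class = "narranet_invalid_argument")
  expect_error(threshold_statmap(smf, connectivity = 7),
               class = "narranet_invalid_argument")
})

test_that("connected components match the igraph flood-fill oracle", {
  set.seed(6)
  vd <- c(10, 10, 5)
  for (conn in c(6, 18, 26)) {
    for (rep in 1:3) {
      supra <- runif(prod(vd)) < 0.2
      labels <- narranet:::label_connected_components(supra, vd, conn)
      sizes <- sort(as.integer(table(labels[labels > 0])), decreasing = TRUE)
      expect_identical(sizes, igraph_cluster_sizes(supra, vd, conn))
    }
  }
})

test_that("thresholding is monotone in extent and height", {
  set.seed(7)
  vd <- c(10, 10, 6)
  sm <- stat_map_from(rnorm(prod(vd), mean = 2, sd = 2), vd)
  sizes <- function(cl) sum(cl$size)
  a <- threshold_statmap(sm, height_p = 0.05, fwe = FALSE, extent = 5)
  b <- threshold_statmap(sm, height_p = 0.05, fwe = FALSE, extent = 20)
  c_ <- threshold_statmap(sm, height_p = 0.005, fwe = FALSE, extent = 5)
  expect_lte(sizes(b), sizes(a))
  expect_lte(sizes(c_), sizes(a))
  expect_true(all(a$size >= 5))
})

test_that("cluster labelling applies the 100-voxel and 75% coverage rules", {
  vd <- c(12, 10, 6)
  # one cluster of 600 voxels: labels A = 400, B = 150, C = 50
  vox <- seq_len(600)
  clusters <- tibble::tibble(
    cluster = 1L, size = 600L, peak_index = 1L, peak_x = 1L, peak_y = 1L,
    peak_z = 1L, peak_t = 5, voxels = list(vox)
  )
  atlas <- integer(prod(vd))
  atlas[vox] <- rep(c(1L, 2L, 3L), times = c(400, 150, 50))
  rep1 <- label_clusters(clusters, atlas, vd)
  expect_identical(rep1$label, c(1L, 2L)) # C suppressed (< 100 voxels)
  expect_equal(rep1$pct, c(400, 150) / 6, tolerance = 1e-10)
  expect_gte(max(rep1$cumulative_pct), 75)

  # coverage rule: labels stop once cumulative 75% is reached
  atlas2 <- integer(prod(vd))
  atlas2[vox] <- rep(c(1L, 2L, 3L), times = c(300, 180, 120))
  rep2 <- label_clusters(clusters, atlas2, vd)
  expect_identical(rep2$label, c(1L, 2L)) # 480/600 = 80% >= 75%: stop before 3

  # a 99-voxel label is never listed, however large the cluster
  atlas3 <- integer(prod(vd))
  atlas3[vox] <- rep(c(1L, 2L), times = c(501, 99))
  rep3 <- label_clusters(clusters, atlas3, vd)
  expect_identical(rep3$label, 1L)

  # cluster entirely inside one label: a single row at 100%
  atlas4 <- integer(prod(vd)); atlas4[vox] <- 4L
  rep4 <- label_clusters(clusters, atlas4, vd)
  expect_identical(nrow(rep4), 1L)
  expect_equal(rep4$pct, 100)

  expect_error(label_clusters(clusters, atlas[1:10], vd),
               class = "narranet_invalid_argument")
})

test_that("the synthetic atlas is a deterministic full partition", {
  a1 <- synthetic_atlas(c(10, 10, 6), n_rois = 8, seed = 3)
  a2 <- synthetic_atlas(c(10, 10, 6), n_rois = 8, seed = 3)
  expect_identical(a1, a2)
  expect_setequal(unique(as.vector(a1)), 1:8)
})
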