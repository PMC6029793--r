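#' Voxelwise one-sample t-map over subject maps
#'
#' `t = mean / (sd / sqrt(n))` per in-mask voxel with `df = n - 1` (30 for 31
#' subjects). Voxels with zero variance across subjects get `t = 0` and are
#' counted in `n_zero_variance`.
#'
#' @param subject_maps `subjects x voxels` matrix (e.g. one component's
#'   condition-averaged maps).
#' @param mask Logical voxel mask; `NULL` uses all voxels.
#' @param vol_dim Integer grid dimensions, length 3.
#' @return A `stat_map`: voxelwise `t` (zero outside the mask), `df`, `mask`
#'   and `vol_dim`.
#' @export
one_sample_tmap <- function(subject_maps, mask = NULL, vol_dim) {
  subject_maps <- as.matrix(subject_maps)
  n <- nrow(subject_maps)
  if (n < 2) stop_invalid("At least 2 subjects are required.")
  n_vox <- ncol(subject_maps)
  if (is.null(mask)) mask <- rep(TRUE, n_vox)
  mask <- as.logical(mask)
  mu <- colMeans(subject_maps)
  s2 <- colSums(sweep(subject_maps, 2, mu)^2) / (n - 1)
  se <- sqrt(s2 / n)
  t_vals <- rep(0, n_vox)
  ok <- mask & se > 0
  t_vals[ok] <- mu[ok] / se[ok]
  n_zero <- sum(mask & se == 0)
  if (n_zero > 0) {
    rlang::warn(sprintf("%d zero-variance voxels set to t = 0.", n_zero))
  }
  structure(
    list(t = t_vals, df = n - 1L, mask = mask, vol_dim = as.integer(vol_dim),
         n_zero_variance = n_zero),
    class = "stat_map"
  )
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %d in-mask voxels, df = %d, max |t| = %.2f\n",
              sum(x$mask), x$df, max(abs(x$t[x$mask]))))
  invisible(x)
}

# Neighbourhood offsets for 6 (faces), 18 (faces + edges) or 26 (full cube)
# connectivity.
connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6, 18, 26)) {
    stop_invalid("`connectivity` must be 6, 18 or 26.")
  }
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nn <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = nn == 1,
                 "18" = nn >= 1 & nn <= 2,
                 "26" = nn >= 1)
  off[keep, , drop = FALSE]
}

# Label connected components of a logical 3D field by breadth-first search.
# Returns an integer vector (0 = background) over the grid.
label_connected_components <- function(supra, vol_dim, connectivity = 18) {
  off <- connectivity_offsets(connectivity)
  labels <- integer(length(supra))
  current <- 0L
  dims <- vol_dim
  idx_of <- function(x, y, z) x + dims[1] * (y - 1L + dims[2] * (z - 1L))
  coords <- voxel_coords(dims)
  for (start in which(supra & labels == 0L)) {
    if (labels[start] != 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      cv <- coords[v, ]
      nb <- sweep(off, 2, cv, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      ni <- idx_of(nb[ok, 1], nb[ok, 2], nb[ok, 3])
      ni <- ni[supra[ni] & labels[ni] == 0L]
      labels[ni] <- current
      queue <- c(queue, ni)
    }
  }
  labels
}

#' Threshold a t-map into extent-filtered clusters
#'
#' Applies a height threshold (the upper Student-t quantile at `height_p`,
#' Bonferroni-divided by the number of in-mask voxels when `fwe = TRUE`),
#' labels the suprathreshold voxels into connected components under the
#' chosen neighbourhood, and discards clusters smaller than `extent` voxels.
#' Bonferroni is a conservative, fully reproducible stand-in for toolbox
#' voxel-level FWE; the uncorrected mode suits small synthetic grids.
#'
#' @param statmap A `stat_map`.
#' @param height_p Height threshold probability.
#' @param fwe Bonferroni-correct the height threshold over in-mask voxels.
#' @param extent Minimum cluster size in voxels.
#' @param connectivity 6, 18 (default) or 26.
#' @return A tibble with one row per surviving cluster: `cluster`, `size`,
#'   `peak_index`, `peak_x/y/z` (voxel coordinates), `peak_t` and a `voxels`
#'   list-column; the height cutoff is the `threshold_t` attribute. An empty
#'   suprathreshold set yields zero rows.
#' @export
threshold_statmap <- function(statmap, height_p = 0.001, fwe = TRUE,
                              extent = 50L, connectivity = 18) {
  stopifnot(inherits(statmap, "stat_map"))
  if (height_p <= 0 || height_p >= 1) stop_invalid("`height_p` must be in (0, 1).")
  n_mask <- sum(statmap$mask)
  p_eff <- if (fwe) height_p / n_mask else height_p
  t_star <- qt(1 - p_eff, df = statmap$df)
  supra <- statmap$mask & statmap$t > t_star
  coords <- voxel_coords(statmap$vol_dim)

  empty <- tibble::tibble(
    cluster = integer(), size = integer(), peak_index = integer(),
    peak_x = integer(), peak_y = integer(), peak_z = integer(),
    peak_t = numeric(), voxels = list()
  )
  out <- if (!any(supra)) {
    empty
  } else {
    labels <- label_connected_components(supra, statmap$vol_dim, connectivity)
    keep <- which(tabulate(labels) >= extent)
    if (!length(keep)) {
      empty
    } else {
      rows <- lapply(seq_along(keep), function(i) {
        vox <- which(labels == keep[i])
        peak <- vox[which.max(statmap$t[vox])]
        tibble::tibble(
          cluster = i, size = length(vox), peak_index = peak,
          peak_x = coords[peak, 1], peak_y = coords[peak, 2],
          peak_z = coords[peak, 3], peak_t = statmap$t[peak],
          voxels = list(vox)
        )
      })
      dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$size))
    }
  }
  out$cluster <- seq_len(nrow(out))
  attr(out, "threshold_t") <- t_star
  attr(out, "connectivity") <- connectivity
  attr(out, "extent") <- as.integer(extent)
  out
}

#' Label clusters against an integer-labelled atlas
#'
#' For each cluster, voxels are counted per atlas label; only labels
#' contributing at least `min_label_voxels` voxels are reported, in
#' descending order of size, until their cumulative share reaches
#' `coverage` of the cluster's voxels. Unlabelled voxels count toward
#' cluster size but are never listed.
#'
#' @param clusters A cluster tibble from [threshold_statmap()].
#' @param atlas Integer-labelled volume on the same grid (3D array or
#'   vector); label 0 = unlabelled.
#' @param vol_dim Grid dimensions, used to check atlas alignment.
#' @param min_label_voxels Minimum voxel contribution for a label to be
#'   listed.
#' @param coverage Cumulative fraction of cluster voxels at which listing
#'   stops.
#' @return A `cluster_report` tibble: `cluster`, `cluster_size`, `label`,
#'   `n_voxels`, `pct`, `cumulative_pct`.
#' @export
label_clusters <- function(clusters, atlas, vol_dim,
                           min_label_voxels = 100L, coverage = 0.75) {
  lab <- as.integer(atlas)
  if (length(lab) != prod(vol_dim)) {
    stop_invalid("Atlas grid does not match the statistic grid.")
  }
  rows <- list()
  for (i in seq_len(nrow(clusters))) {
    vox <- clusters$voxels[[i]]
    counts <- table(lab[vox])
    counts <- counts[names(counts) != "0"]
    counts <- sort(counts, decreasing = TRUE)
    counts <- counts[counts >= min_label_voxels]
    if (!length(counts)) next
    cum <- cumsum(as.integer(counts)) / clusters$size[i]
    n_keep <- which(cum >= coverage)[1]
    if (is.na(n_keep)) n_keep <- length(counts)
    sel <- seq_len(n_keep)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      cluster = clusters$cluster[i],
      cluster_size = clusters$size[i],
      label = as.integer(names(counts)[sel]),
      n_voxels = as.integer(counts[sel]),
      pct = 100 * as.integer(counts[sel]) / clusters$size[i],
      cumulative_pct = 100 * cum[sel]
    )
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(cluster = integer(), cluster_size = integer(),
                   label = integer(), n_voxels = integer(), pct = numeric(),
                   cumulative_pct = numeric())
  }
  class(out) <- c("cluster_report", class(out))
  out
}

#' Deterministic synthetic parcellation of the voxel grid
#'
#' Partitions the grid into `n_rois` compact regions by k-means on voxel
#' coordinates (fixed seed), standing in for an anatomical atlas on the
#' synthetic desk-scale grid. This is a synthetic stand-in, not a real
#' anatomical atlas.
#'
#' @param vol_dim Grid dimensions, length 3.
#' @param n_rois Number of regions.
#' @param seed Integer seed for the k-means initialization.
#' @return Integer 3D array of labels `1..n_rois`.
#' @export
synthetic_atlas <- function(vol_dim, n_rois = 8L, seed = 1L) {
  coords <- voxel_coords(vol_dim)
  km <- with_local_seed(seed, {
    stats::kmeans(coords, centers = n_rois, nstart = 5, iter.max = 100)
  })
  array(as.integer(km$cluster), dim = vol_dim)
}
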