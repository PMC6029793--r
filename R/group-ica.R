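#' Fit a temporal-concatenation group spatial ICA
#'
#' Each run (subject x condition) is voxel-mean-centred and reduced along time
#' by a run-level PCA to `r1` dimensions; the reduced runs are stacked along
#' the reduced-time axis and a second PCA reduces the stack to `n_components`
#' whitened dimensions, on which an InfoMax unmixing matrix is estimated.
#' Components are ordered by explained variance (descending) with unit-RMS
#' spatial maps whose absolute peak is positive, and are shared by every run
#' of both conditions, so the same component is automatically matched across
#' subjects and between the movie and script conditions.
#'
#' @param dataset A (preprocessed) `bold_dataset`.
#' @param n_components Number of independent components K.
#' @param r1 Run-level PCA rank; default `min(ceiling(1.5 * K), t - 1)`,
#'   the usual over-retention before the second reduction stage.
#' @param seed Integer seed (InfoMax initialization); the fit is
#'   deterministic given the seed.
#' @param lr,max_iter,tol,anneal,strict Passed to [infomax_unmix()].
#' @return A list with elements `reduction` (a `reduction_model`: run bases,
#'   group basis, whitener, retained-variance fractions) and `model` (a
#'   `group_ica_model`: unit-RMS `group_maps` (K x voxels), whitened-space
#'   `mixing`/`unmixing`, reduced-time `group_mixing`, explained variances and
#'   InfoMax diagnostics).
#' @export
fit_group_ica <- function(dataset, n_components = 40L, r1 = NULL, seed = 1L,
                          lr = 0.01, max_iter = 2000L, tol = 1e-6,
                          anneal = 0.9, strict = FALSE) {
  stopifnot(inherits(dataset, "bold_dataset"))
  k <- as.integer(n_components)
  idx <- run_index_table(dataset)
  n_run <- nrow(idx)
  t_len <- dataset$n_volumes
  n_vox <- length(dataset$mask)
  if (is.null(r1)) r1 <- min(ceiling(1.5 * k), t_len - 1L)
  r1 <- as.integer(r1)
  if (r1 < k) stop_invalid("`r1` (%d) must be at least `n_components` (%d).", r1, k)
  if (r1 >= t_len) stop_invalid("`r1` must be below the run length.")
  if (k > n_run * r1) {
    stop_invalid("Requested %d components but only %d stacked dimensions.",
                 k, n_run * r1)
  }

  bases <- vector("list", n_run)
  voxel_means <- vector("list", n_run)
  stage1_var <- numeric(n_run)
  stacked <- matrix(0, n_run * r1, n_vox)
  for (j in seq_len(n_run)) {
    y <- get_run(dataset, idx$subject[j], idx$condition[j])
    mu <- colMeans(y)
    yc <- sweep(y, 2, mu)
    e <- eigen(tcrossprod(yc), symmetric = TRUE)
    f <- e$vectors[, seq_len(r1), drop = FALSE]
    bases[[j]] <- f
    voxel_means[[j]] <- mu
    ev <- pmax(e$values, 0)
    stage1_var[j] <- sum(ev[seq_len(r1)]) / max(sum(ev), .Machine$double.eps)
    stacked[(j - 1L) * r1 + seq_len(r1), ] <- crossprod(f, yc)
  }

  e2 <- eigen(tcrossprod(stacked), symmetric = TRUE)
  d2 <- pmax(e2$values, 0)
  if (d2[k] <= 1e-10 * d2[1]) {
    stop_invalid("Data rank is below %d components.", k)
  }
  u2 <- e2$vectors[, seq_len(k), drop = FALSE]
  dk <- d2[seq_len(k)]
  whitener <- sweep(t(u2), 1, sqrt(n_vox / dk), "*")   # K x (n_run * r1)
  g <- sweep(u2, 2, sqrt(dk / n_vox), "*")             # (n_run * r1) x K
  x2 <- whitener %*% stacked                           # K x voxels, whitened

  fit <- infomax_unmix(x2, seed = seed, lr = lr, max_iter = max_iter,
                       tol = tol, anneal = anneal, strict = strict)
  s <- fit$W %*% x2
  a <- solve(fit$W)

  # unit-RMS maps with positive absolute peak
  scale_k <- sqrt(rowMeans(s^2))
  sign_k <- vapply(seq_len(k), function(i) {
    v <- s[i, which.max(abs(s[i, ]))]
    if (v < 0) -1 else 1
  }, numeric(1))
  adj <- scale_k * sign_k
  s <- s / adj
  a <- sweep(a, 2, adj, "*")
  w_eff <- fit$W / adj

  ev_k <- colSums((g %*% a)^2) * n_vox
  ord <- order(ev_k, decreasing = TRUE)
  s <- s[ord, , drop = FALSE]
  a <- a[, ord, drop = FALSE]
  w_eff <- w_eff[ord, , drop = FALSE]
  ev_k <- ev_k[ord]

  reduction <- structure(
    list(
      run_bases = bases,
      voxel_means = voxel_means,
      run_table = idx,
      r1 = r1,
      group_basis = g,
      whitener = whitener,
      stage1_variance = stage1_var,
      stage2_variance = sum(dk) / max(sum(d2), .Machine$double.eps),
      n_volumes = t_len,
      n_voxels = n_vox
    ),
    class = "reduction_model"
  )
  model <- structure(
    list(
      n_components = k,
      group_maps = s,
      mixing = a,
      unmixing = w_eff,
      group_mixing = g %*% a,
      explained_variance = ev_k,
      scale = "raw",
      seed = as.integer(seed),
      infomax = fit[c("converged", "iterations", "delta", "lr")]
    ),
    class = "group_ica_model"
  )
  list(reduction = reduction, model = model)
}

#' @export
print.group_ica_model <- function(x, ...) {
  cat(sprintf("<group_ica_model> K = %d, %s scaling, InfoMax %s in %d iterations\n",
              x$n_components, x$scale,
              if (x$infomax$converged) "converged" else "stopped",
              x$infomax$iterations))
  invisible(x)
}

#' GICA3 back-reconstruction of subject/condition components
#'
#' Derives run-specific spatial maps and time-courses by partitioning the
#' group decomposition through the PCA back-projection operators: for run `j`
#' with reduced data `X_j`, maps are `R * unmixing %*% whitener_j %*% X_j`
#' and time-courses `(1 / R) * F_j %*% G_j %*% mixing` (R = number of runs),
#' so that the average of all run maps equals the group maps exactly and each
#' map/time-course product reproduces the run's reduced-rank data share.
#'
#' @param dataset The `bold_dataset` the model was fitted on.
#' @param reduction The `reduction_model` from [fit_group_ica()].
#' @param model The `group_ica_model` from [fit_group_ica()].
#' @return A `subject_components` object: `maps` is a
#'   `subject x condition x K x voxels` array, `timecourses` a
#'   `subject x condition x t x K` array.
#' @export
backreconstruct <- function(dataset, reduction, model) {
  stopifnot(inherits(reduction, "reduction_model"),
            inherits(model, "group_ica_model"))
  idx <- reduction$run_table
  if (reduction$n_volumes != dataset$n_volumes ||
      reduction$n_voxels != length(dataset$mask) ||
      nrow(idx) != nrow(run_index_table(dataset))) {
    stop_invalid("Reduction model does not match this dataset.")
  }
  k <- model$n_components
  r1 <- reduction$r1
  n_run <- nrow(idx)
  n_sub <- length(dataset$runs)
  conds <- dataset$conditions
  t_len <- dataset$n_volumes
  n_vox <- reduction$n_voxels

  maps <- array(0, dim = c(n_sub, length(conds), k, n_vox))
  tcs <- array(0, dim = c(n_sub, length(conds), t_len, k))
  for (j in seq_len(n_run)) {
    s_i <- idx$subject[j]
    c_i <- match(idx$condition[j], conds)
    rows <- (j - 1L) * r1 + seq_len(r1)
    y <- get_run(dataset, s_i, idx$condition[j])
    yc <- sweep(y, 2, reduction$voxel_means[[j]])
    xj <- crossprod(reduction$run_bases[[j]], yc)       # r1 x V
    maps[s_i, c_i, , ] <- n_run *
      (model$unmixing %*% reduction$whitener[, rows, drop = FALSE]) %*% xj
    tcs[s_i, c_i, , ] <- (reduction$run_bases[[j]] %*%
      reduction$group_basis[rows, , drop = FALSE] %*% model$mixing) / n_run
  }
  structure(
    list(
      maps = maps,
      timecourses = tcs,
      conditions = conds,
      subjects = dataset$subjects$subject,
      vol_dim = dataset$vol_dim,
      mask = dataset$mask,
      tr = dataset$tr,
      scale = "raw"
    ),
    class = "subject_components"
  )
}

#' @export
print.subject_components <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("<subject_components> %d subjects x %d conditions x %d components (%d voxels, %s scaling)\n",
              d[1], d[2], d[3], d[4], x$scale))
  invisible(x)
}

#' Rescale components to percent signal change
#'
#' Moves scale between each run's maps and time-courses so that time-course
#' units read as percent of the run's mean in-mask signal: for component `k`
#' with map RMS `w_k` and run mean signal `m`, time-courses are multiplied by
#' `100 * w_k / m` and maps by `m / (100 * w_k)`. The map (x) time-course
#' product is unchanged, and the scaled time-courses are invariant to
#' rescaling the raw data.
#'
#' @param components A `subject_components` object.
#' @param dataset The dataset the components were reconstructed from (its
#'   voxel temporal means define the percent reference).
#' @return The rescaled `subject_components`.
#' @export
scale_percent_signal_change <- function(components, dataset) {
  stopifnot(inherits(components, "subject_components"))
  mask <- dataset$mask
  d <- dim(components$maps)
  for (s in seq_len(d[1])) {
    for (ci in seq_len(d[2])) {
      mu <- colMeans(get_run(dataset, s, components$conditions[ci]))
      if (any(mu[mask] == 0)) {
        stop_invalid("Zero-mean voxels inside the mask; percent scaling undefined.")
      }
      m_bar <- mean(mu[mask])
      for (k in seq_len(d[3])) {
        w <- sqrt(mean(components$maps[s, ci, k, mask]^2))
        if (w == 0) next
        fac <- 100 * w / m_bar
        components$timecourses[s, ci, , k] <-
          components$timecourses[s, ci, , k] * fac
        components$maps[s, ci, k, ] <- components$maps[s, ci, k, ] / fac
      }
    }
  }
  components$scale <- "percent"
  components
}

#' Validate and correct component signs against the raw signal
#'
#' ICA component signs are arbitrary. For each component, the preprocessed
#' BOLD signal is averaged over the `n_peak_voxels` voxels nearest (Euclidean
#' distance, ties broken by larger absolute map weight) to the absolute peak
#' of the group-average map, averaged over all runs, and correlated with the
#' group-average component time-course; components with negative correlation
#' are flipped (map and time-course together, leaving their product's sign
#' structure coherent with the data).
#'
#' @param components A `subject_components` object.
#' @param dataset The preprocessed `bold_dataset`.
#' @param n_peak_voxels Number of voxels averaged around the peak.
#' @return List with `signs` (one of +1/-1 per component) and `components`
#'   (sign-corrected).
#' @export
validate_component_signs <- function(components, dataset, n_peak_voxels = 500L) {
  stopifnot(inherits(components, "subject_components"))
  mask <- which(dataset$mask)
  if (n_peak_voxels > length(mask)) {
    stop_invalid("`n_peak_voxels` exceeds the %d in-mask voxels.", length(mask))
  }
  d <- dim(components$maps)
  k <- d[3]
  group_maps <- mean_over_runs(components$maps)        # K x V
  group_tc <- mean_over_runs(components$timecourses)   # t x K
  coords <- voxel_coords(dataset$vol_dim)

  # mean BOLD across all runs, once
  mean_bold <- Reduce(`+`, lapply(seq_along(dataset$runs), function(s) {
    Reduce(`+`, dataset$runs[[s]])
  })) / (length(dataset$runs) * length(dataset$conditions))

  signs <- integer(k)
  for (j in seq_len(k)) {
    w <- group_maps[j, mask]
    peak <- mask[which.max(abs(w))]
    dist <- sqrt(rowSums(sweep(coords[mask, , drop = FALSE], 2,
                               coords[peak, ])^2))
    sel <- mask[order(dist, -abs(w))[seq_len(n_peak_voxels)]]
    ref <- rowMeans(mean_bold[, sel, drop = FALSE])
    r <- if (stats::sd(ref) == 0 || stats::sd(group_tc[, j]) == 0) {
      0
    } else {
      cor(ref, group_tc[, j])
    }
    signs[j] <- if (r < 0) -1L else 1L
    if (signs[j] < 0) {
      components$maps[, , j, ] <- -components$maps[, , j, ]
      components$timecourses[, , , j] <- -components$timecourses[, , , j]
    }
  }
  list(signs = signs, components = components)
}
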