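# Independent oracles and fixture builders shared across tests. Oracles are
# deliberately written as naive/brute-force computations, independent of the
# package's implementation paths.

# Greedy maximum-|correlation| assignment of estimated rows to reference rows.
# Returns, per reference row, the matched estimate row and the |r| achieved.
greedy_match <- function(estimated, reference) {
  cc <- abs(stats::cor(t(estimated), t(reference)))
  n_ref <- ncol(cc)
  match_row <- integer(n_ref)
  match_r <- numeric(n_ref)
  used <- rep(FALSE, nrow(cc))
  for (step in seq_len(n_ref)) {
    cc_masked <- cc
    cc_masked[used, ] <- -Inf
    cc_masked[, match_row > 0] <- -Inf
    pos <- which(cc_masked == max(cc_masked), arr.ind = TRUE)[1, ]
    match_row[pos[2]] <- pos[1]
    match_r[pos[2]] <- cc[pos[1], pos[2]]
    used[pos[1]] <- TRUE
  }
  list(row = match_row, r = match_r)
}

# Brute-force Benjamini-Hochberg step-up with monotonicity enforcement.
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m == 1) break
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Naive voxel-loop DVARS in percent units.
naive_dvars_percent <- function(m) {
  v <- ncol(m)
  t_len <- nrow(m)
  xp <- matrix(0, t_len, v)
  for (j in seq_len(v)) xp[, j] <- 100 * m[, j] / mean(m[, j])
  out <- numeric(t_len)
  for (i in 2:t_len) {
    acc <- 0
    for (j in seq_len(v)) acc <- acc + (xp[i, j] - xp[i - 1, j])^2
    out[i] <- sqrt(acc / v)
  }
  out
}

# Connected-component sizes of a logical 3D field via igraph (flood-fill
# oracle), under 6/18/26 connectivity.
igraph_cluster_sizes <- function(supra, vol_dim, connectivity) {
  vox <- which(supra)
  if (!length(vox)) return(integer())
  coords <- as.matrix(expand.grid(x = seq_len(vol_dim[1]),
                                  y = seq_len(vol_dim[2]),
                                  z = seq_len(vol_dim[3])))[vox, , drop = FALSE]
  n <- length(vox)
  edges <- NULL
  for (i in seq_len(n)) {
    d <- abs(sweep(coords, 2, coords[i, ]))
    nb <- which(apply(d, 1, max) <= 1)
    nn <- rowSums(d[nb, , drop = FALSE])
    keep <- switch(as.character(connectivity),
                   "6" = nn == 1, "18" = nn >= 1 & nn <= 2, "26" = nn >= 1)
    nb <- nb[keep]
    nb <- nb[nb > i]
    if (length(nb)) edges <- rbind(edges, cbind(i, nb))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g))
  sort(as.integer(table(igraph::components(g)$membership)), decreasing = TRUE)
}

# Assemble a subject_components object directly from arrays (no ICA), for
# tests of the ranking/matching/dialog statistics.
make_components <- function(timecourses, maps = NULL,
                            conditions = c("movie", "script"),
                            vol_dim = NULL, tr = 2.015) {
  d <- dim(timecourses)
  if (is.null(maps)) {
    if (is.null(vol_dim)) vol_dim <- c(6, 6, 4)
    maps <- array(stats::rnorm(d[1] * d[2] * d[4] * prod(vol_dim)),
                  dim = c(d[1], d[2], d[4], prod(vol_dim)))
  }
  if (is.null(vol_dim)) {
    stopifnot(!is.null(maps))
    vol_dim <- c(dim(maps)[4], 1, 1)
  }
  structure(
    list(maps = maps, timecourses = timecourses, conditions = conditions,
         subjects = sprintf("sub-%02d", seq_len(d[1])),
         vol_dim = vol_dim, mask = rep(TRUE, dim(maps)[4]), tr = tr,
         scale = "raw"),
    class = "subject_components"
  )
}

# A small, quick study configuration for ICA-level tests.
quick_config <- function(...) {
  args <- list(...)
  defaults <- list(n_subjects = 4L, n_volumes = 100L,
                   volume_shape = c(14L, 14L, 8L), source_sigma_vox = 1.2,
                   n_shared_sources = 2L, n_specific_sources_per_condition = 1L,
                   noise_sd = 0.5, seed = 1L)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

# Pair of centred, exactly orthonormal series used to construct time-course
# pairs with an exact target correlation.
exact_correlated_pair <- function(t_len, rho, seed) {
  set.seed(seed)
  u <- stats::rnorm(t_len); u <- u - mean(u); u <- u / sqrt(sum(u^2))
  v <- stats::rnorm(t_len); v <- v - mean(v)
  v <- v - u * sum(u * v); v <- v / sqrt(sum(v^2))
  cbind(u, rho * u + sqrt(1 - rho^2) * v)
}
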