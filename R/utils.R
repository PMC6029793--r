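# Internal helpers shared across modules.

stop_invalid <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "narranet_invalid_argument")
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop_invalid("`%s` must contain only finite values.", what)
  }
  invisible(x)
}

#' Derive a stage-specific seed from a pipeline seed
#'
#' A single pipeline seed fans out to per-stage seeds by stable integer
#' hashing, so that any stage rerun in isolation with its derived seed
#' reproduces the pipeline's behaviour. Results stay below 2^31.
#'
#' @param seed Integer master seed.
#' @param stage Character stage name.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 69069 + h * 12345 + 1) %% 2147483647)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Voxel grid coordinates (in voxel units) for a 3D volume, V x 3.
voxel_coords <- function(vol_dim) {
  as.matrix(expand.grid(
    x = seq_len(vol_dim[1]),
    y = seq_len(vol_dim[2]),
    z = seq_len(vol_dim[3])
  ))
}

# Pearson correlation between corresponding rows of two matrices (n x p each).
# Rows with zero variance yield NA.
row_correlations <- function(a, b) {
  ac <- a - rowMeans(a)
  bc <- b - rowMeans(b)
  num <- rowSums(ac * bc)
  den <- sqrt(rowSums(ac^2) * rowSums(bc^2))
  ifelse(den > 0, num / den, NA_real_)
}

# Full Pearson cross-correlation matrix between rows of a (n1 x p) and rows of
# b (n2 x p): returns n1 x n2. Zero-variance rows give NA entries.
cross_correlations <- function(a, b) {
  ac <- a - rowMeans(a)
  bc <- b - rowMeans(b)
  sa <- sqrt(rowSums(ac^2))
  sb <- sqrt(rowSums(bc^2))
  r <- tcrossprod(ac, bc) / outer(sa, sb)
  r[!is.finite(r)] <- NA_real_
  r
}

# Correlations of every circular shift of `a` against each column of matrix
# `b` (t x K), computed via the FFT circular cross-correlation identity.
# Returns a t x K matrix whose row s+1 holds cor(shift(a, s), b[, k]) where
# shift(a, s)[i] = a[((i - 1 + s) %% t) + 1].
all_shift_correlations <- function(a, b) {
  t_len <- length(a)
  b <- as.matrix(b)
  stopifnot(nrow(b) == t_len)
  ac <- a - mean(a)
  bc <- sweep(b, 2, colMeans(b))
  ssa <- sum(ac^2)
  ssb <- colSums(bc^2)
  if (ssa <= 0 || any(ssb <= 0)) {
    stop_invalid("Constant series have no defined correlation.")
  }
  fa <- fft(ac)
  fb <- stats::mvfft(bc)
  cc <- Re(stats::mvfft(fa * Conj(fb), inverse = TRUE)) / t_len
  sweep(cc, 2, sqrt(ssa * ssb), "/")
}

# Columnwise paired shift correlations: cor(shift(a[, k], s), b[, k]) for all
# circular shifts s (rows) and all columns k, via FFT.
pairwise_shift_correlations <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  t_len <- nrow(a)
  stopifnot(nrow(b) == t_len, ncol(a) == ncol(b))
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  ssa <- colSums(ac^2)
  ssb <- colSums(bc^2)
  if (any(ssa <= 0) || any(ssb <= 0)) {
    stop_invalid("Constant series have no defined correlation.")
  }
  cc <- Re(stats::mvfft(stats::mvfft(ac) * Conj(stats::mvfft(bc)),
                        inverse = TRUE)) / t_len
  sweep(cc, 2, sqrt(ssa * ssb), "/")
}

# Paired per-column Pearson correlations of two equally shaped matrices.
paired_column_correlations <- function(a, b) {
  row_correlations(t(a), t(b))
}

# Dense ranks, largest value first, ties broken by ascending index.
rank_descending <- function(r) {
  o <- order(-r, seq_along(r))
  rk <- integer(length(r))
  rk[o] <- seq_along(r)
  rk
}

# Mean over the first two margins (subject, condition) of a 4D array,
# returned as a matrix over the remaining two margins.
mean_over_runs <- function(arr) {
  d <- dim(arr)
  matrix(colMeans(matrix(arr, d[1] * d[2], d[3] * d[4])), d[3], d[4])
}

# Admissible circular shift offsets for a series of length t with a minimum
# absolute circular offset of `min_shift` in either direction.
admissible_shifts <- function(t_len, min_shift) {
  if (t_len <= 2 * min_shift + 1) {
    stop_invalid("Series too short for min_shift = %d (need t > %d).",
                 min_shift, 2 * min_shift + 1)
  }
  seq.int(min_shift, t_len - min_shift)
}
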