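new_null_distribution <- function(values, n_shifts, min_shift, n_components) {
  structure(
    list(values = as.numeric(values), n_shifts = as.integer(n_shifts),
         min_shift = as.integer(min_shift),
         n_components = as.integer(n_components)),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d values (%d shifts x %d series, min shift %d TRs)\n",
              length(x$values), x$n_shifts, x$n_components, x$min_shift))
  invisible(x)
}

#' Circular shift-permutation null distribution
#'
#' Correlates every admissible circular shift of `series_a` (all offsets with
#' absolute circular value of at least `min_shift` TRs, in either direction)
#' with each series in `series_set_b`, pooling all values into one empirical
#' null. For a 212-volume run with minimum shift 2 there are 209 admissible
#' shifts; against 40 component time-courses the null holds 8360 values.
#'
#' @param series_a Numeric series of length t.
#' @param series_set_b Numeric vector or `t x K` matrix of comparison series.
#' @param min_shift Minimum absolute circular shift in TRs.
#' @return A `null_distribution` with `n_shifts * K` values.
#' @export
shift_permutation_null <- function(series_a, series_set_b, min_shift = 2L) {
  b <- as.matrix(series_set_b)
  t_len <- length(series_a)
  if (nrow(b) != t_len) stop_invalid("Series lengths differ.")
  shifts <- admissible_shifts(t_len, min_shift)
  cc <- all_shift_correlations(series_a, b)
  new_null_distribution(as.vector(cc[shifts + 1L, , drop = FALSE]),
                        length(shifts), min_shift, ncol(b))
}

#' Two-tailed permutation p-value from an empirical null
#'
#' `p = 2 * min(Pr(null <= observed), Pr(null >= observed))` with the add-one
#' correction `(count + 1) / (N + 1)` on each tail, capped at 1. An observed
#' value beyond every one of N null values therefore gets `p = 2 / (N + 1)`.
#'
#' @param observed Observed correlation(s); vectorized.
#' @param null A `null_distribution`.
#' @return Numeric p-value(s) in `(0, 1]`.
#' @export
permutation_pvalue <- function(observed, null) {
  stopifnot(inherits(null, "null_distribution"))
  v <- null$values
  n <- length(v)
  if (n == 0) stop_invalid("Empty null distribution.")
  vapply(observed, function(o) {
    lo <- (sum(v <= o) + 1) / (n + 1)
    hi <- (sum(v >= o) + 1) / (n + 1)
    min(1, 2 * min(lo, hi))
  }, numeric(1))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement over the supplied family
#' of tests (here, typically the K components).
#'
#' @param p_values Numeric p-values in \[0, 1\].
#' @return Adjusted q-values, `q >= p` elementwise.
#' @export
fdr_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop_invalid("p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Between-condition spatial correlation tensor
#'
#' For every subject, correlates each movie-condition component map with each
#' script-condition map over in-mask voxels, giving a
#' `subject x K x K` tensor (31 x 40 x 40 = 49600 values at study scale).
#' Entries on the `i = j` diagonal are "matched" (the same component in both
#' conditions; 31 x 40 = 1240 at study scale); spatial independence of ICA
#' maps predicts that matched correlations dominate unmatched ones.
#'
#' @param components A `subject_components` object with exactly 2 conditions.
#' @return A `match_tensor`: the `values` tensor plus matched/unmatched
#'   means, SDs and counts, and the number of constant-map entries zeroed.
#' @export
spatial_match_tensor <- function(components) {
  stopifnot(inherits(components, "subject_components"))
  d <- dim(components$maps)
  if (d[2] != 2) stop_invalid("Exactly 2 conditions are required.")
  n_sub <- d[1]; k <- d[3]
  mask <- components$mask
  values <- array(NA_real_, dim = c(n_sub, k, k))
  n_constant <- 0L
  for (s in seq_len(n_sub)) {
    a <- components$maps[s, 1, , mask, drop = FALSE]
    b <- components$maps[s, 2, , mask, drop = FALSE]
    cc <- cross_correlations(matrix(a, k), matrix(b, k))
    n_constant <- n_constant + sum(is.na(cc))
    cc[is.na(cc)] <- 0
    values[s, , ] <- cc
  }
  if (n_constant > 0) {
    rlang::warn(sprintf("%d constant-map correlations set to 0.", n_constant))
  }
  matched_idx <- cbind(rep(seq_len(n_sub), k),
                       rep(seq_len(k), each = n_sub),
                       rep(seq_len(k), each = n_sub))
  matched <- values[matched_idx]
  unmatched <- values[-((matched_idx[, 3] - 1) * n_sub * k +
                          (matched_idx[, 2] - 1) * n_sub +
                          matched_idx[, 1])]
  structure(
    list(
      values = values,
      matched_mean = mean(matched),
      matched_sd = stats::sd(matched),
      unmatched_mean = mean(unmatched),
      unmatched_sd = stats::sd(unmatched),
      n_matched = length(matched),
      n_total = length(values),
      n_constant = n_constant
    ),
    class = "match_tensor"
  )
}

#' @export
print.match_tensor <- function(x, ...) {
  cat(sprintf(
    "<match_tensor> %d entries (%d matched): matched r = %.2f (SD %.2f), unmatched r = %.2f (SD %.2f)\n",
    x$n_total, x$n_matched, x$matched_mean, x$matched_sd,
    x$unmatched_mean, x$unmatched_sd
  ))
  invisible(x)
}

#' Average back-reconstructed maps across conditions
#'
#' Arithmetic mean of each subject's movie and script maps, producing one
#' spatial map per subject and component for second-level statistics.
#'
#' @param components A `subject_components` object with 2 conditions.
#' @return A `subject x K x voxels` array.
#' @export
average_maps_across_conditions <- function(components) {
  stopifnot(inherits(components, "subject_components"))
  d <- dim(components$maps)
  if (d[2] != 2) stop_invalid("Exactly 2 conditions are required.")
  a <- array(components$maps[, 1, , , drop = FALSE], d[c(1, 3, 4)])
  b <- array(components$maps[, 2, , , drop = FALSE], d[c(1, 3, 4)])
  (a + b) / 2
}

run_timecourses <- function(components, s, ci) {
  d <- dim(components$timecourses)
  matrix(components$timecourses[s, ci, , , drop = FALSE], d[3], d[4])
}

condition_mean_timecourses <- function(components, ci) {
  d <- dim(components$timecourses)
  matrix(colMeans(matrix(components$timecourses[, ci, , , drop = FALSE],
                         d[1], d[3] * d[4])), d[3], d[4])
}

#' Ranking A: correlation over averages
#'
#' Correlates, per component, the group-averaged movie time-course with the
#' group-averaged script time-course, and ranks components by descending
#' correlation (ties broken by component index). Modality-wise averaging over
#' a large group suppresses subject-specific intrinsic signals, which makes
#' this the primary ranking for isolating narrative networks.
#'
#' @param components A `subject_components` object with 2 conditions.
#' @return A tibble with columns `component`, `r_A`, `rank_A`.
#' @export
rank_correlation_over_averages <- function(components) {
  stopifnot(inherits(components, "subject_components"))
  d <- dim(components$timecourses)
  if (d[2] != 2) stop_invalid("Exactly 2 conditions are required.")
  tca <- condition_mean_timecourses(components, 1)
  tcb <- condition_mean_timecourses(components, 2)
  r <- paired_column_correlations(tca, tcb)
  tibble::tibble(component = seq_len(d[4]), r_A = r,
                 rank_A = rank_descending(r))
}

#' Ranking B: average over correlations
#'
#' Correlates, per subject and component, that subject's movie and script
#' time-courses, averages the subject-level correlations per component, and
#' ranks components by the descending average. Subject noise attenuates these
#' values relative to ranking A.
#'
#' @param components A `subject_components` object with 2 conditions.
#' @return A tibble with columns `component`, `r_B`, `rank_B`.
#' @export
rank_average_over_correlations <- function(components) {
  stopifnot(inherits(components, "subject_components"))
  d <- dim(components$timecourses)
  if (d[2] != 2) stop_invalid("Exactly 2 conditions are required.")
  rs <- vapply(seq_len(d[1]), function(s) {
    paired_column_correlations(run_timecourses(components, s, 1),
                               run_timecourses(components, s, 2))
  }, numeric(d[4]))
  r <- rowMeans(matrix(rs, d[4]))
  tibble::tibble(component = seq_len(d[4]), r_B = r,
                 rank_B = rank_descending(r))
}

#' Cross-modal component ranking table
#'
#' Assembles rankings A ("correlation over averages") and B ("average over
#' correlations") with two-tailed circular shift-permutation p-values and
#' Benjamini-Hochberg q-values over the K components. Both schemes share one
#' permutation design: the movie-condition series is circularly shifted over
#' all admissible offsets (minimum `min_shift` TRs), the scheme's statistic
#' is recomputed at each shift, and values are pooled over components into
#' the scheme's null distribution.
#'
#' @param components A `subject_components` object with 2 conditions.
#' @param min_shift Minimum circular shift in TRs.
#' @return A `ranking_table` tibble with columns `component`, `r_A`, `p_A`,
#'   `q_A`, `rank_A`, `r_B`, `p_B`, `q_B`, `rank_B`; the scheme nulls are
#'   attached as the `nulls` attribute.
#' @export
ranking_table <- function(components, min_shift = 2L) {
  d <- dim(components$timecourses)
  k <- d[4]
  t_len <- d[3]
  shifts <- admissible_shifts(t_len, min_shift)

  tca <- condition_mean_timecourses(components, 1)
  tcb <- condition_mean_timecourses(components, 2)
  shift_a <- pairwise_shift_correlations(tca, tcb)
  ra <- rank_correlation_over_averages(components)
  null_a <- new_null_distribution(
    as.vector(shift_a[shifts + 1L, , drop = FALSE]),
    length(shifts), min_shift, k
  )
  p_a <- permutation_pvalue(ra$r_A, null_a)

  shift_b <- matrix(0, t_len, k)
  for (s in seq_len(d[1])) {
    shift_b <- shift_b +
      pairwise_shift_correlations(run_timecourses(components, s, 1),
                                  run_timecourses(components, s, 2))
  }
  shift_b <- shift_b / d[1]
  rb <- rank_average_over_correlations(components)
  null_b <- new_null_distribution(
    as.vector(shift_b[shifts + 1L, , drop = FALSE]),
    length(shifts), min_shift, k
  )
  p_b <- permutation_pvalue(rb$r_B, null_b)

  out <- tibble::tibble(
    component = seq_len(k),
    r_A = ra$r_A, p_A = p_a, q_A = fdr_adjust(p_a), rank_A = ra$rank_A,
    r_B = rb$r_B, p_B = p_b, q_B = fdr_adjust(p_b), rank_B = rb$rank_B
  )
  attr(out, "nulls") <- list(A = null_a, B = null_b)
  attr(out, "min_shift") <- as.integer(min_shift)
  class(out) <- c("ranking_table", class(out))
  out
}

#' Select the top cross-modal components
#'
#' Returns the `k` components with the highest correlation under the chosen
#' ranking scheme, together with the overlap between the two schemes' top-7
#' sets (the two rankings typically agree on most but not all of their top
#' components).
#'
#' @param ranking A `ranking_table`.
#' @param k Number of components to select.
#' @param scheme `"A"` (correlation over averages) or `"B"`.
#' @return List with `selected` (component indices, best first) and
#'   `overlap_top7`.
#' @export
select_top_components <- function(ranking, k = 5L, scheme = c("A", "B")) {
  scheme <- match.arg(scheme)
  n <- nrow(ranking)
  if (k > n) stop_invalid("`k` cannot exceed the %d components.", n)
  rank_col <- paste0("rank_", scheme)
  selected <- ranking$component[order(ranking[[rank_col]])][seq_len(k)]
  m <- min(7L, n)
  top7_a <- ranking$component[order(ranking$rank_A)][seq_len(m)]
  top7_b <- ranking$component[order(ranking$rank_B)][seq_len(m)]
  list(selected = selected, overlap_top7 = length(intersect(top7_a, top7_b)))
}

#' Cross-condition correlations of atlas reference regions
#'
#' For each integer-labelled atlas region, averages the BOLD signal over the
#' region's in-mask voxels and over subjects, per condition, and correlates
#' the two group-averaged regional time-courses — the "correlation over
#' averages" statistic evaluated on anatomical regions instead of ICA
#' components (e.g. occipital/auditory reference ROIs). The correlation of
#' the whole-mask global signal is attached as the `global_r` attribute.
#'
#' @param dataset A (preprocessed) `bold_dataset`.
#' @param atlas Integer-labelled volume on the data grid (3D array or vector
#'   of length `n_voxels`); label 0 = unlabelled.
#' @return A tibble with columns `roi`, `n_voxels`, `r`, `rank`.
#' @export
reference_region_correlations <- function(dataset, atlas) {
  lab <- as.integer(atlas)
  if (length(lab) != length(dataset$mask)) {
    stop_invalid("Atlas grid (%d voxels) does not match the data grid (%d).",
                 length(lab), length(dataset$mask))
  }
  lab[!dataset$mask] <- 0L
  labels <- sort(unique(lab[lab > 0L]))
  n_sub <- length(dataset$runs)

  region_tc <- function(voxels, cond) {
    acc <- 0
    for (s in seq_len(n_sub)) {
      acc <- acc + rowMeans(get_run(dataset, s, cond)[, voxels, drop = FALSE])
    }
    acc / n_sub
  }
  r <- vapply(labels, function(l) {
    vox <- which(lab == l)
    cor(region_tc(vox, dataset$conditions[1]),
        region_tc(vox, dataset$conditions[2]))
  }, numeric(1))
  out <- tibble::tibble(
    roi = labels,
    n_voxels = vapply(labels, function(l) sum(lab == l), integer(1)),
    r = r,
    rank = rank_descending(r)
  )
  attr(out, "global_r") <- cor(
    region_tc(which(dataset$mask), dataset$conditions[1]),
    region_tc(which(dataset$mask), dataset$conditions[2])
  )
  out
}
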