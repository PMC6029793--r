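#' Tidy a fitted group ICA model
#'
#' @param x A `group_ica_model`.
#' @param ... Unused.
#' @return A tibble with one row per component: `component`,
#'   `explained_variance` and its fraction of the total.
#' @method tidy group_ica_model
#' @export
tidy.group_ica_model <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$n_components),
    explained_variance = x$explained_variance,
    variance_fraction = x$explained_variance / sum(x$explained_variance)
  )
}

#' @rdname tidy.group_ica_model
#' @return For `glance()`: a one-row tibble with fit diagnostics.
#' @method glance group_ica_model
#' @export
glance.group_ica_model <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    converged = x$infomax$converged,
    iterations = x$infomax$iterations,
    final_delta = x$infomax$delta,
    scale = x$scale
  )
}

#' Tidy a between-condition spatial match tensor
#'
#' @param x A `match_tensor`.
#' @param ... Unused.
#' @return Two rows (matched / unmatched) with mean, SD and count.
#' @method tidy match_tensor
#' @export
tidy.match_tensor <- function(x, ...) {
  tibble::tibble(
    set = c("matched", "unmatched"),
    mean_r = c(x$matched_mean, x$unmatched_mean),
    sd_r = c(x$matched_sd, x$unmatched_sd),
    n = c(x$n_matched, x$n_total - x$n_matched)
  )
}

#' @rdname tidy.match_tensor
#' @method glance match_tensor
#' @export
glance.match_tensor <- function(x, ...) {
  tibble::tibble(
    n_total = x$n_total, n_matched = x$n_matched,
    matched_mean = x$matched_mean, unmatched_mean = x$unmatched_mean,
    n_constant = x$n_constant
  )
}

#' Tidy a voxelwise t-map
#'
#' @param x A `stat_map`.
#' @param ... Unused.
#' @return One row per in-mask voxel: `voxel`, grid coordinates and `t`.
#' @method tidy stat_map
#' @export
tidy.stat_map <- function(x, ...) {
  vox <- which(x$mask)
  coords <- voxel_coords(x$vol_dim)[vox, , drop = FALSE]
  t_vals <- x$t[vox]
  tibble::tibble(voxel = vox, x = coords[, 1], y = coords[, 2],
                 z = coords[, 3], t = t_vals)
}

#' Tidy a permutation null distribution
#'
#' @param x A `null_distribution`.
#' @param ... Unused.
#' @return A tibble with a single `value` column.
#' @method tidy null_distribution
#' @export
tidy.null_distribution <- function(x, ...) {
  tibble::tibble(value = x$values)
}

#' Summarize a QC report
#'
#' @param x A `qc_report`.
#' @param ... Unused.
#' @return A one-row tibble: group-mean FD and DVARS RMS and total flagged
#'   volumes.
#' @method glance qc_report
#' @export
glance.qc_report <- function(x, ...) {
  tibble::tibble(
    mean_fd_rms = mean(x$fd_rms),
    mean_dvars_rms = mean(x$dvars_rms),
    n_flagged = sum(x$n_flagged),
    n_runs = nrow(x)
  )
}

#' Summarize a dialog analysis
#'
#' @param x A `dialog_analysis`.
#' @param ... Unused.
#' @return A one-row tibble with counts of activated / deactivated
#'   components and the total number of correlations computed.
#' @method glance dialog_analysis
#' @export
glance.dialog_analysis <- function(x, ...) {
  tibble::tibble(
    n_correlations = nrow(x),
    n_activated = sum(x$direction == "activated"),
    n_deactivated = sum(x$direction == "deactivated")
  )
}
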