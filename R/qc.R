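#' Framewise displacement from a 6-parameter motion trace
#'
#' FD at volume i is the sum of absolute backward differences of the six
#' rigid-body parameters, with the three rotations (radians) converted to arc
#' length on a sphere of `rotation_radius` mm. The first volume has FD 0 by
#' convention.
#'
#' @param motion A `t x 6` matrix: columns 1--3 translations (mm), columns
#'   4--6 rotations (radians).
#' @param rotation_radius Sphere radius (mm) used to convert rotations.
#' @return Numeric FD series (mm), length `t`.
#' @export
framewise_displacement <- function(motion, rotation_radius = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop_invalid("`motion` must have 6 columns.")
  if (nrow(motion) < 2) stop_invalid("`motion` needs at least 2 volumes.")
  assert_finite(motion, "motion")
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      rotation_radius * rowSums(d[, 4:6, drop = FALSE]))
}

# Accept a t x V matrix or an (x, y, z, t) array and return t x V.
as_run_matrix <- function(bold) {
  if (is.matrix(bold)) return(bold)
  if (is.array(bold) && length(dim(bold)) == 4) {
    d <- dim(bold)
    return(t(matrix(bold, prod(d[1:3]), d[4])))
  }
  stop_invalid("`bold` must be a t x voxels matrix or a 4D (x,y,z,t) array.")
}

#' DVARS of a BOLD run
#'
#' Root-mean-square, over in-mask voxels, of the volume-to-volume backward
#' difference of the signal. With `scale = "percent"` (default) each voxel is
#' first expressed as percent of its temporal mean, yielding a dimensionless
#' spike indicator; `scale = "none"` computes DVARS in raw signal units (in
#' which form it is exactly invariant to adding any temporally constant
#' image). The first volume has DVARS 0 by convention.
#'
#' @param bold A `t x voxels` matrix or 4D `(x, y, z, t)` array.
#' @param mask Logical vector (or array) selecting analyzed voxels; `NULL`
#'   uses all voxels.
#' @param scale Intensity normalization, `"percent"` or `"none"`.
#' @return Numeric DVARS series, length `t`.
#' @export
dvars <- function(bold, mask = NULL, scale = c("percent", "none")) {
  scale <- match.arg(scale)
  m <- as_run_matrix(bold)
  if (nrow(m) < 2) stop_invalid("DVARS needs at least 2 volumes.")
  if (is.null(mask)) mask <- rep(TRUE, ncol(m))
  mask <- as.logical(mask)
  if (!any(mask)) stop_invalid("`mask` selects no voxels.")
  m <- m[, mask, drop = FALSE]
  if (scale == "percent") {
    mu <- colMeans(m)
    if (any(mu <= 0)) {
      stop_invalid("Percent scaling requires positive voxel temporal means.")
    }
    m <- 100 * sweep(m, 2, mu, "/")
  }
  d <- diff(m)
  c(0, sqrt(rowMeans(d^2)))
}

#' Quality-control report for a dataset
#'
#' Computes per-run framewise displacement and DVARS series, their
#' root-mean-square summaries, and the indices of volumes whose FD exceeds
#' `fd_threshold` (reported, never repaired).
#'
#' @param dataset A `bold_dataset`.
#' @param fd_threshold FD flagging threshold in mm.
#' @param dvars_scale Passed to [dvars()].
#' @return A `qc_report` tibble with one row per run: `subject`, `condition`,
#'   `fd_rms` (mm), `dvars_rms`, `n_flagged`, and list-columns `fd`, `dvars`,
#'   `flagged_volumes`.
#' @export
qc_report <- function(dataset, fd_threshold = 0.5,
                      dvars_scale = c("percent", "none")) {
  dvars_scale <- match.arg(dvars_scale)
  idx <- run_index_table(dataset)
  rows <- purrr::pmap(idx, function(subject, condition) {
    fd <- framewise_displacement(dataset$motion[[subject]][[condition]])
    dv <- dvars(get_run(dataset, subject, condition), dataset$mask,
                scale = dvars_scale)
    flagged <- which(fd > fd_threshold)
    tibble::tibble(
      subject = dataset$subjects$subject[subject],
      condition = condition,
      fd_rms = sqrt(mean(fd^2)),
      dvars_rms = sqrt(mean(dv^2)),
      n_flagged = length(flagged),
      fd = list(fd),
      dvars = list(dv),
      flagged_volumes = list(flagged)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "fd_threshold") <- fd_threshold
  class(out) <- c("qc_report", class(out))
  out
}
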