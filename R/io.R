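#' Write a dataset to disk in BIDS-like layout
#'
#' Each run is written as `sub-XX_cond-{movie,script}_bold.nii.gz`, motion as
#' 6-column TSVs, the event schedule as `events.tsv`, and ground truth (when
#' present) as NIfTI source maps plus a JSON sidecar with kinds,
#' time-courses and realized cross-condition correlations.
#'
#' @param dataset A `bold_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bold_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vd <- dataset$vol_dim
  for (s in seq_along(dataset$runs)) {
    sub <- dataset$subjects$subject[s]
    for (cond in dataset$conditions) {
      m <- get_run(dataset, s, cond)
      arr <- array(t(m), c(vd, nrow(m)))
      RNifti::writeNifti(
        RNifti::asNifti(arr, pixdim = c(rep(3, 3), dataset$tr)),
        file.path(dir, sprintf("%s_cond-%s_bold.nii.gz", sub, cond))
      )
      mot <- as.data.frame(dataset$motion[[s]][[cond]])
      names(mot) <- c("trans_x", "trans_y", "trans_z",
                      "rot_x", "rot_y", "rot_z")
      readr::write_tsv(mot,
                       file.path(dir, sprintf("%s_cond-%s_motion.tsv", sub, cond)))
    }
  }
  write_events_tsv(dataset$schedule, file.path(dir, "events.tsv"))
  readr::write_tsv(dataset$subjects, file.path(dir, "participants.tsv"))
  gt <- dataset$ground_truth
  if (!is.null(gt) && length(gt$kinds)) {
    RNifti::writeNifti(
      RNifti::asNifti(array(t(gt$maps), c(vd, nrow(gt$maps)))),
      file.path(dir, "ground_truth_maps.nii.gz")
    )
    jsonlite::write_json(
      list(kinds = gt$kinds, signs = gt$signs, amplitude = gt$amplitude,
           baseline = gt$baseline,
           realized_cross_correlation = gt$realized_cross_correlation,
           timecourses = gt$timecourses),
      file.path(dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  jsonlite::write_json(
    list(tr = dataset$tr, n_volumes = dataset$n_volumes, vol_dim = vd,
         conditions = dataset$conditions),
    file.path(dir, "dataset.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a dataset written by [write_bold_dataset()]
#'
#' @param dir Directory containing the BIDS-like layout.
#' @return A `bold_dataset` (without ground truth time-course recovery beyond
#'   what the JSON sidecar stores).
#' @export
read_bold_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "dataset.json"), simplifyVector = TRUE)
  subjects <- readr::read_tsv(file.path(dir, "participants.tsv"),
                              show_col_types = FALSE)
  schedule <- read_events_tsv(file.path(dir, "events.tsv"))
  vd <- as.integer(meta$vol_dim)
  runs <- list()
  motion <- list()
  for (s in seq_len(nrow(subjects))) {
    sub <- subjects$subject[s]
    runs[[s]] <- list()
    motion[[s]] <- list()
    for (cond in meta$conditions) {
      arr <- RNifti::readNifti(
        file.path(dir, sprintf("%s_cond-%s_bold.nii.gz", sub, cond))
      )
      d <- dim(arr)
      runs[[s]][[cond]] <- t(matrix(as.array(arr), prod(d[1:3]), d[4]))
      motion[[s]][[cond]] <- as.matrix(readr::read_tsv(
        file.path(dir, sprintf("%s_cond-%s_motion.tsv", sub, cond)),
        show_col_types = FALSE
      ))
    }
  }
  gt <- NULL
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    maps_arr <- as.array(RNifti::readNifti(file.path(dir, "ground_truth_maps.nii.gz")))
    dm <- dim(maps_arr)
    n_maps <- if (length(dm) == 4) dm[4] else 1L # singleton 4th axis squeezed
    gt$maps <- t(matrix(maps_arr, prod(dm[1:3]), n_maps))
  }
  structure(
    list(
      runs = runs, motion = motion, schedule = schedule,
      subjects = tibble::as_tibble(subjects),
      conditions = meta$conditions, vol_dim = vd,
      mask = rep(TRUE, prod(vd)), tr = meta$tr,
      n_volumes = as.integer(meta$n_volumes),
      ground_truth = gt, config = NULL
    ),
    class = "bold_dataset"
  )
}
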