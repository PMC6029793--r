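#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis: simulation
#' (via a [synthetic_config()]), preprocessing (7 mm FWHM smoothing, 0.01 Hz
#' high-pass), group ICA (K = 40 at study scale), cross-modal ranking
#' (minimum circular shift 2 TRs, q < 0.05 over K components, top 5), the
#' dialog analysis, and group-map thresholding (p < 0.001 height with FWE
#' correction, 50-voxel extent). A single `seed` fans out to per-stage seeds
#' through [derive_seed()].
#'
#' @param synthetic A [synthetic_config()] describing the simulated dataset.
#' @param n_components Number of ICA components K.
#' @param r1 Run-level PCA rank (`NULL` = default over-retention).
#' @param fwhm,voxel_size,cutoff_hz Preprocessing parameters.
#' @param min_shift Minimum circular shift (TRs) for permutation nulls.
#' @param fdr_q FDR significance level over components.
#' @param top_k Number of top-ranked components selected.
#' @param n_peak_voxels Voxels averaged around map peaks for sign validation
#'   (capped at the mask size at run time).
#' @param height_p,fwe,extent,connectivity Group-map thresholding parameters.
#' @param n_rois Regions in the synthetic reference atlas.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            n_components = 40L,
                            r1 = NULL,
                            fwhm = 7,
                            voxel_size = 3,
                            cutoff_hz = 0.01,
                            min_shift = 2L,
                            fdr_q = 0.05,
                            top_k = 5L,
                            n_peak_voxels = 500L,
                            height_p = 0.001,
                            fwe = TRUE,
                            extent = 50L,
                            connectivity = 18,
                            n_rois = 8L,
                            seed = 1L) {
  stopifnot(inherits(synthetic, "synthetic_config"))
  structure(
    list(
      synthetic = synthetic, n_components = as.integer(n_components),
      r1 = if (is.null(r1)) NULL else as.integer(r1),
      fwhm = fwhm, voxel_size = voxel_size, cutoff_hz = cutoff_hz,
      min_shift = as.integer(min_shift), fdr_q = fdr_q,
      top_k = as.integer(top_k), n_peak_voxels = as.integer(n_peak_voxels),
      height_p = height_p, fwe = isTRUE(fwe), extent = as.integer(extent),
      connectivity = connectivity, n_rois = as.integer(n_rois),
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Save / load a pipeline configuration as JSON
#'
#' The JSON round-trip restores an identical configuration
#' (`load_pipeline_config(save_pipeline_config(cfg, path))` equals `cfg`).
#'
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @return `path` / the restored `pipeline_config`.
#' @export
save_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' @rdname save_pipeline_config
#' @export
load_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  syn <- do.call(synthetic_config, raw$synthetic)
  raw$synthetic <- NULL
  do.call(pipeline_config, c(list(synthetic = syn), raw))
}

run_stage <- function(name, verbose, expr) {
  if (verbose) message(sprintf("[narranet] stage %-10s ...", name))
  t0 <- Sys.time()
  result <- tryCatch(expr, error = function(e) {
    rlang::abort(
      sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
      class = "narranet_stage_failure", stage = name, parent = e
    )
  })
  if (verbose) {
    message(sprintf("[narranet] stage %-10s done (%.1f s)", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  result
}

#' Run the full narrative-network pipeline
#'
#' Executes simulate -> QC -> preprocess -> group ICA (with GICA3
#' back-reconstruction, percent-signal-change scaling and sign validation)
#' -> spatial match tensor and cross-modal ranking -> dialog analysis ->
#' group t-maps with cluster labelling and reference-region comparison.
#' Identical configuration and seed give an identical manifest. A failing
#' stage aborts with a `narranet_stage_failure` naming the stage.
#'
#' @param config A [pipeline_config()].
#' @param dataset Optionally, a pre-built `bold_dataset`; when supplied the
#'   simulate stage is skipped.
#' @param out_dir Optional output directory; when given, the resolved
#'   configuration, tables (TSV) and summary (JSON) are written there.
#' @param verbose Log stage progress to stderr.
#' @return A manifest list with the fitted objects (`dataset`, `qc`,
#'   `ica`, `components`, `signs`, `match`, `ranking`, `top`, `dialog`,
#'   `maps`, `reference`) and a JSON-serializable `summary`.
#' @export
run_pipeline <- function(config, dataset = NULL, out_dir = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  if (is.null(dataset)) {
    dataset <- run_stage("simulate", verbose, {
      syn <- config$synthetic
      syn$seed <- derive_seed(seed, "simulate")
      generate_dataset(syn)
    })
  }

  qc <- run_stage("qc", verbose, qc_report(dataset))

  dataset <- run_stage("preprocess", verbose, {
    preprocess_dataset(dataset, fwhm = config$fwhm,
                       voxel_size = config$voxel_size,
                       cutoff_hz = config$cutoff_hz)
  })

  ica <- run_stage("ica", verbose, {
    fit_group_ica(dataset, n_components = config$n_components,
                  r1 = config$r1, seed = derive_seed(seed, "ica"))
  })
  components <- run_stage("backreconstruct", verbose, {
    comp <- backreconstruct(dataset, ica$reduction, ica$model)
    comp <- scale_percent_signal_change(comp, dataset)
    validate_component_signs(comp, dataset,
                             n_peak_voxels = min(config$n_peak_voxels,
                                                 sum(dataset$mask)))
  })
  signs <- components$signs
  components <- components$components

  match <- run_stage("match", verbose, spatial_match_tensor(components))
  ranking <- run_stage("rank", verbose,
                       ranking_table(components, min_shift = config$min_shift))
  top <- select_top_components(ranking, k = config$top_k, scheme = "A")

  dialog <- run_stage("dialog", verbose, {
    if (!any(dataset$schedule$trial_type == "dialog")) {
      stop_invalid("Schedule has no dialog events.")
    }
    regressor <- build_dialog_regressor(dataset$schedule, dataset$n_volumes,
                                        dataset$tr,
                                        cutoff_hz = config$cutoff_hz)
    list(
      regressor = regressor,
      analysis = dialog_correlation_analysis(components, regressor,
                                             min_shift = config$min_shift,
                                             fdr_q = config$fdr_q)
    )
  })

  maps <- run_stage("maps", verbose, {
    avg <- average_maps_across_conditions(components)
    atlas <- synthetic_atlas(dataset$vol_dim, n_rois = config$n_rois,
                             seed = derive_seed(seed, "atlas"))
    per_component <- lapply(top$selected, function(k) {
      sm <- one_sample_tmap(matrix(avg[, k, , drop = FALSE],
                                   dim(avg)[1], dim(avg)[3]),
                            dataset$mask, dataset$vol_dim)
      cl <- threshold_statmap(sm, height_p = config$height_p,
                              fwe = config$fwe, extent = config$extent,
                              connectivity = config$connectivity)
      list(component = k, statmap = sm, clusters = cl,
           report = label_clusters(cl, atlas, dataset$vol_dim))
    })
    list(atlas = atlas, per_component = per_component)
  })
  reference <- run_stage("reference", verbose,
                         reference_region_correlations(dataset, maps$atlas))

  summary <- list(
    seed = seed,
    n_subjects = length(dataset$runs),
    n_volumes = dataset$n_volumes,
    n_components = config$n_components,
    qc = list(mean_fd_rms = mean(qc$fd_rms),
              mean_dvars_rms = mean(qc$dvars_rms),
              n_flagged = sum(qc$n_flagged)),
    match = list(n_total = match$n_total, n_matched = match$n_matched,
                 matched_mean = match$matched_mean,
                 matched_sd = match$matched_sd,
                 unmatched_mean = match$unmatched_mean,
                 unmatched_sd = match$unmatched_sd),
    ranking = as.data.frame(ranking),
    null_size_A = length(attr(ranking, "nulls")$A$values),
    top = top,
    component_signs = signs,
    dialog = as.data.frame(dialog$analysis),
    n_dialog_correlations = nrow(dialog$analysis),
    clusters = lapply(maps$per_component, function(x) {
      list(component = x$component, n_clusters = nrow(x$clusters),
           report = as.data.frame(x$report))
    }),
    reference = as.data.frame(reference),
    global_signal_r = attr(reference, "global_r"),
    ground_truth_kinds = dataset$ground_truth$kinds,
    realized_cross_correlation = dataset$ground_truth$realized_cross_correlation
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_pipeline_config(config, file.path(out_dir, "config.json"))
    readr::write_tsv(as.data.frame(ranking), file.path(out_dir, "ranking.tsv"))
    readr::write_tsv(as.data.frame(dialog$analysis),
                     file.path(out_dir, "dialog.tsv"))
    readr::write_tsv(as.data.frame(reference),
                     file.path(out_dir, "reference_rois.tsv"))
    readr::write_tsv(
      as.data.frame(qc[, c("subject", "condition", "fd_rms", "dvars_rms",
                           "n_flagged")]),
      file.path(out_dir, "qc.tsv")
    )
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, null = "null")
  }

  list(dataset = dataset, qc = qc, ica = ica, components = components,
       signs = signs, match = match, ranking = ranking, top = top,
       dialog = dialog, maps = maps, reference = reference,
       summary = summary, config = config)
}
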