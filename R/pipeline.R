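## Orchestrated runs: simulate/read -> align -> accumulate -> maps -> bin ->
## select -> classify -> summarize, with per-stage error labels and a run log.

resolve_ratio_ave <- function(mode, acc) {
  if (is.numeric(mode)) return(mode)
  switch(as.character(mode),
         "per-image" = mean_sulfur_ratio(acc),
         "cdt" = CDT_S34_S32,
         stop(sprintf("unknown ratio_ave mode: %s", mode)))
}

#' Read a run configuration from YAML
#'
#' Convenience loader: the YAML maps directly onto the configuration lists
#' taken by [run_conjugate_analysis()], [run_hepatocyte_analysis()] and
#' [run_calibration()]; a `scene:` block is converted to [scene_params()].
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$scene)) {
    sc <- cfg$scene
    if (!is.null(sc$conjugate))
      sc$conjugate <- molecule_label_spec(sc$conjugate$name %||% "conjugate",
                                          sc$conjugate$n_s34_labels %||% 0L,
                                          sc$conjugate$n_i127_labels %||% 0L)
    if (!is.null(sc$base_yields)) sc$base_yields <- unlist(sc$base_yields)
    cfg$scene <- do.call(scene_params, sc)
  }
  cfg
}

obtain_stack <- function(config, out_dir) {
  if (!is.null(config$input) && !is.null(config$scene))
    stop("exactly one input source: give either input or scene")
  if (!is.null(config$input)) {
    list(stack = with_stage("read", read_stack(config$input)), truth = NULL)
  } else if (!is.null(config$scene)) {
    params <- config$scene
    if (!is.null(config$seed)) {
      params$seed <- as.integer(config$seed)
    }
    truth <- with_stage("simulate", make_scene(params))
    stack <- with_stage("simulate", simulate_stack(truth))
    if (!is.null(out_dir))
      write_stack(stack, file.path(out_dir, "simulated_stack.tif"))
    list(stack = stack, truth = truth)
  } else stop("exactly one input source: give either input or scene")
}

log_lines <- function(path, lines) {
  writeLines(lines, path)
  invisible(path)
}

#' Full conjugate (coupled/decoupled) analysis run
#'
#' Runs the complete dual-isotope quantification: obtain a stack (read from
#' disk or simulate from a scene), drift-correct and accumulate, compute the
#' excess-34S ASO and 127I ligand maps, bin to the target physical size,
#' select ligand ROIs at the sigma threshold, classify each as coupled or
#' decoupled, and write all artefacts to the output directory.
#'
#' @param config list (or path handled by [read_run_config()]) with fields:
#'   `input` (stack TIFF path) or `scene` ([scene_params()]); `mol`
#'   ([molecule_label_spec()], defaults to the scene conjugate);
#'   `ratio_ave` (`"per-image"`, `"cdt"` or a number; default per-image);
#'   `bin_nm` (default 468); `sigma_k` (default 3); `min_c` (default 1);
#'   `align` (default TRUE for multi-plane stacks);
#'   `reference_channel` (default `"13C14N"`); `per_cell_masks` (optional
#'   bin-space label matrix); `out_dir`; `seed` (overrides the scene seed).
#' @return invisibly, a report list: the accumulated image, maps, ROI table,
#'   coupling summary and effective parameters. Written files:
#'   `aso_map.tif`/`ligand_map.tif` (+ sidecars), `map_summary.csv`,
#'   `roi_table.csv`, `coupling_summary.json`, `scatter.csv` (normalised
#'   ligand vs ASO values of the selected bins), `run.log`.
#' @export
run_conjugate_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  src <- obtain_stack(config, out_dir)
  stack <- src$stack
  align <- config$align %||% (dim(stack$counts)[1] > 1L)
  if (align && dim(stack$counts)[1] > 1L)
    stack <- with_stage("align",
                        align_planes(stack, config$reference_channel %||% "13C14N"))
  acc <- with_stage("accumulate", accumulate(stack))
  ratio_ave <- with_stage("ratio",
                          resolve_ratio_ave(config$ratio_ave %||% "per-image", acc))
  binned <- with_stage("bin", bin_counts(acc, config$bin_nm %||% 468))
  mol <- config$mol %||% config$scene$conjugate %||%
    stop("[maps] no molecule label spec given")
  table <- with_stage("roi", build_roi_table(binned, mol, ratio_ave = ratio_ave,
                                             sigma_k = config$sigma_k %||% 3,
                                             min_c = config$min_c %||% 1L))
  summ <- coupling_summary(table, per_cell_masks = config$per_cell_masks)
  aso_b <- aso_signal_map(binned, mol, ratio_ave = ratio_ave,
                          min_c = config$min_c %||% 1L)
  lig_b <- ligand_signal_map(binned, mol, min_c = config$min_c %||% 1L)
  if (!is.null(out_dir)) {
    write_signal_map(aso_b, file.path(out_dir, "aso_map.tif"))
    write_signal_map(lig_b, file.path(out_dir, "ligand_map.tif"))
    utils::write.csv(rbind(map_summary(aso_b), map_summary(lig_b)),
                     file.path(out_dir, "map_summary.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(table), file.path(out_dir, "roi_table.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summ[c("n_coupled", "n_decoupled", "fraction_coupled")],
                         file.path(out_dir, "coupling_summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    sel <- table[table$selected, c("bin_row", "bin_col", "ligand_norm", "aso_norm")]
    utils::write.csv(sel, file.path(out_dir, "scatter.csv"), row.names = FALSE)
    log_lines(file.path(out_dir, "run.log"), c(
      sprintf("channels: %s", paste(stack$channels$name, collapse = ",")),
      sprintf("planes: %d  aligned: %s", dim(stack$counts)[1], align),
      sprintf("drift_offsets: %s",
              paste(apply(stack$drift_offsets, 1,
                          function(o) sprintf("(%d,%d)", o[1], o[2])),
                    collapse = " ")),
      sprintf("ratio_ave: %.8g", ratio_ave),
      sprintf("bin_factor: %d  realized_bin_nm: %.6g",
              attr(binned, "bin_factor"), binned$pixel_size_nm),
      sprintf("sigma_k: %.3g  sigma_ligand: %.6g",
              attr(table, "sigma_k"), attr(table, "sigma_ligand")),
      sprintf("n_coupled: %d  n_decoupled: %d", summ$n_coupled, summ$n_decoupled)))
  }
  invisible(list(stack = stack, accumulated = acc, binned = binned,
                 aso_map = aso_b, ligand_map = lig_b, roi_table = table,
                 summary = summ, ratio_ave = ratio_ave, truth = src$truth,
                 bin_factor = attr(binned, "bin_factor")))
}

#' Hepatocyte hotspot-ROI analysis run
#'
#' Detects 34S hotspots on the 34S/32S ratio image, excludes those explained
#' by endogenous sulfur-dense bodies (32S hotspots), and writes per-ROI
#' excess-34S statistics (box-plot-ready). A manual ROI label mask may be
#' supplied instead of automatic detection.
#'
#' @param config list with `input`/`scene` as in [run_conjugate_analysis()],
#'   plus `mol`, `ratio_ave`, `threshold_percentile` (default 99),
#'   `min_area_px` (default 3), `max_overlap_frac` (default 0), `roi_mask`
#'   (optional integer label matrix, or path to a label TIFF, for manual
#'   ROIs), `out_dir`, `seed`.
#' @return invisibly, a report list with the ROI set and statistics. Written
#'   files: `hotspot_rois.csv`, `hotspot_labels.tif` (16-bit label image),
#'   `run.log`.
#' @export
run_hepatocyte_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  src <- obtain_stack(config, out_dir)
  stack <- src$stack
  if ((config$align %||% (dim(stack$counts)[1] > 1L)) && dim(stack$counts)[1] > 1L)
    stack <- with_stage("align",
                        align_planes(stack, config$reference_channel %||% "13C14N"))
  acc <- with_stage("accumulate", accumulate(stack))
  ratio_ave <- with_stage("ratio",
                          resolve_ratio_ave(config$ratio_ave %||% "per-image", acc))
  mol <- config$mol %||% config$scene$conjugate %||%
    molecule_label_spec("ASO", n_s34_labels = 15L)
  if (!is.null(config$roi_mask)) {
    mask <- config$roi_mask
    if (is.character(mask)) {
      mask <- tiff::readTIFF(mask, as.is = TRUE)
      storage.mode(mask) <- "integer"
    }
    aso <- aso_signal_map(acc, mol, ratio_ave = ratio_ave)
    stats_df <- with_stage("roi", roi_stats_from_mask(aso, mask))
    stats_df$source <- rep("manual", nrow(stats_df))
    rois <- structure(list(rois = stats_df,
                           labels = list(manual = mask),
                           ratio_ave_used = ratio_ave),
                      class = "hotspot_roi_set")
  } else {
    rois <- with_stage("roi", hotspot_rois(
      acc, mol = mol, ratio_ave = ratio_ave,
      threshold_percentile = config$threshold_percentile %||% 99,
      min_area_px = config$min_area_px %||% 3L,
      max_overlap_frac = config$max_overlap_frac %||% 0))
    stats_df <- rois$rois
  }
  if (!is.null(out_dir)) {
    utils::write.csv(stats_df, file.path(out_dir, "hotspot_rois.csv"),
                     row.names = FALSE)
    lab <- rois$labels[[1]]
    tiff::writeTIFF(lab / 65535, file.path(out_dir, "hotspot_labels.tif"),
                    bits.per.sample = 16L, compression = "none")
    log_lines(file.path(out_dir, "run.log"), c(
      sprintf("ratio_ave: %.8g", ratio_ave),
      sprintf("n_rois: %d", nrow(stats_df))))
  }
  invisible(list(accumulated = acc, rois = rois, stats = stats_df,
                 ratio_ave = ratio_ave, truth = src$truth))
}

#' Measure a calibration series on simulated standard slabs
#'
#' For each concentration, simulates a uniform standard slab, accumulates,
#' bins, and records the mean and standard deviation of the binned scaled
#' signal.
#'
#' @param params a [scene_params()] (yields, labels, signal scale).
#' @param concentrations_uM strictly positive concentrations.
#' @param kind `"ASO"` or `"LIGAND"`.
#' @param bin_nm physical bin size.
#' @param standard_density sulfur density of the slab matrix.
#' @param seed sampling seed.
#' @return a [calibration_series()].
#' @export
measure_standard_series <- function(params, concentrations_uM,
                                    kind = c("ASO", "LIGAND"), bin_nm = 468,
                                    standard_density = 20, seed = params$seed) {
  kind <- match.arg(kind)
  res <- vapply(seq_along(concentrations_uM), function(i) {
    truth <- make_standard_scene(params, concentrations_uM[i],
                                 standard_density = standard_density)
    stack <- simulate_stack(truth, seed = seed + i)
    binned <- bin_counts(accumulate(stack), bin_nm)
    map <- if (kind == "ASO")
      aso_signal_map(binned, params$conjugate,
                     ratio_ave = params$natural_s34_ratio)
    else ligand_signal_map(binned, params$conjugate)
    v <- map$values[map$mask]
    c(mean(v), stats::sd(v))
  }, numeric(2))
  calibration_series(concentrations_uM, res[1, ], res[2, ], label_kind = kind)
}

#' Calibration analysis run
#'
#' Fits the linear response on standards (simulated slabs or a measured
#' CSV), estimates the limit of detection against a blank, and, when the
#' conjugate carries both labels, checks the dual-label linearity.
#'
#' @param config list with either `series_csv` (CSV with columns
#'   `concentration_uM,signal,signal_sd` and optional `background_mean`,
#'   `background_sd` fields in the config) or `scene` + `concentrations`
#'   (default `c(2.6, 26, 260)`); `bin_nm`, `standard_density`, `k_sigma`,
#'   `out_dir`, `seed`.
#' @return invisibly, a report list with the fit, `lod_uM` and (when
#'   applicable) the dual-label linearity. Writes `calibration.json`.
#' @export
run_calibration <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  dual <- NULL
  if (!is.null(config$series_csv)) {
    df <- utils::read.csv(config$series_csv)
    series <- calibration_series(df$concentration_uM, df$signal,
                                 df$signal_sd %||% 0)
    fit <- with_stage("calibrate", fit_linear_response(series))
    bg_mean <- config$background_mean %||% 0
    bg_sd <- config$background_sd %||% 0
  } else if (!is.null(config$scene)) {
    params <- config$scene
    if (!is.null(config$seed)) params$seed <- as.integer(config$seed)
    concs <- config$concentrations %||% c(2.6, 26, 260)
    bin_nm <- config$bin_nm %||% 468
    dens <- config$standard_density %||% 20
    series <- with_stage("calibrate",
      measure_standard_series(params, concs, "ASO", bin_nm = bin_nm,
                              standard_density = dens, seed = params$seed))
    fit <- with_stage("calibrate", fit_linear_response(series))
    blank <- make_standard_scene(params, 0, standard_density = dens)
    bstack <- simulate_stack(blank, seed = params$seed + 1000L)
    bmap <- aso_signal_map(bin_counts(accumulate(bstack), bin_nm),
                           params$conjugate,
                           ratio_ave = params$natural_s34_ratio)
    bv <- bmap$values[bmap$mask]
    bg_mean <- mean(bv); bg_sd <- stats::sd(bv)
    if (params$conjugate$n_i127_labels > 0) {
      series_i <- measure_standard_series(params, concs, "LIGAND",
                                          bin_nm = bin_nm,
                                          standard_density = dens,
                                          seed = params$seed + 2000L)
      dual <- check_dual_label_linearity(series_i, series)
    }
  } else stop("give either series_csv or scene")
  lod <- estimate_lod(fit, bg_mean, bg_sd, k_sigma = config$k_sigma %||% 3)
  fit$lod_uM <- lod
  report <- list(slope = fit$slope, intercept = fit$intercept,
                 r_squared = fit$r_squared, lod_uM = lod,
                 background_mean = bg_mean, background_sd = bg_sd,
                 dual_label = dual)
  if (!is.null(out_dir))
    jsonlite::write_json(report[!vapply(report, is.null, logical(1))],
                         file.path(out_dir, "calibration.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(c(report, list(fit = fit, series = series)))
}
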