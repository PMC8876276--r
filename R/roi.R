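#' Bin an accumulated image to a fixed physical size
#'
#' Individual pixels carry too few counts for stable per-pixel ratios, and
#' with ~65000 ratio pixels per image chance alone puts thousands of pixels
#' above 1 sigma. Counts are therefore summed over k x k pixel blocks chosen
#' to approximate a target physical bin edge (default 468 nm, slightly larger
#' than the endosomal structures observed); downstream signals are recomputed
#' from the summed counts, which is the Poisson-optimal aggregate.
#'
#' @param acc an [accumulated_image()].
#' @param target_bin_nm target bin edge in nm (must be >= the pixel size).
#' @return an [accumulated_image()] at the binned resolution; the integer bin
#'   factor `k = round(target_bin_nm / pixel_size_nm)` is stored in attribute
#'   `"bin_factor"` and the realised bin edge is `k * pixel_size_nm`. Trailing
#'   partial blocks are dropped; totals are conserved exactly when the width
#'   is divisible by `k`.
#' @export
bin_counts <- function(acc, target_bin_nm = 468) {
  stopifnot(inherits(acc, "accumulated_image"))
  if (target_bin_nm < acc$pixel_size_nm)
    stop("target_bin_nm must be at least the pixel size")
  k <- as.integer(round(target_bin_nm / acc$pixel_size_nm))
  d <- dim(acc$counts)
  nb <- d[2] %/% k
  out <- array(0L, dim = c(d[1], nb, nb))
  for (ch in seq_len(d[1]))
    out[ch, , ] <- block_sum(acc$counts[ch, , ], k)
  res <- accumulated_image(out, acc$channels, k * acc$pixel_size_nm,
                           n_planes_accumulated = acc$n_planes_accumulated,
                           drift_offsets = acc$drift_offsets)
  attr(res, "bin_factor") <- k
  res
}

#' Binned ROI table with 3-sigma ligand selection and coupling classes
#'
#' Every bin of a binned image is one candidate region of interest. The ASO
#' (excess-34S) and ligand (127I) signals are recomputed from the binned
#' counts, each is normalised to its own unmasked maximum, and a bin is
#' selected when its ligand value exceeds `sigma_k` times the standard
#' deviation of all unmasked ligand values in the image (default 3 sigma).
#' Selected bins are classified coupled/decoupled by [classify_coupling()].
#'
#' @param acc_binned a binned [accumulated_image()] (see [bin_counts()]).
#' @param mol a [molecule_label_spec()] carrying both the 34S and 127I label
#'   counts of the conjugate.
#' @param ratio_ave average sulfur ratio used for the ASO map. Defaults to
#'   the per-image ratio of the binned counts (identical to the unbinned
#'   ratio when no partial blocks were dropped).
#' @param sigma_k selection threshold in units of the ligand-value standard
#'   deviation.
#' @param min_c mask floor on binned `13C12C` counts.
#' @param threshold_rule `"k-sd"` (literal `value > k * sd`, default) or
#'   `"mean-plus-k-sd"`.
#' @return a `data.frame` of class `roi_table` with columns `bin_row`,
#'   `bin_col`, `ligand_value`, `aso_value`, `ligand_norm`, `aso_norm`,
#'   `selected`, `coupling`, and attributes `bin_size_nm`, `sigma_ligand`,
#'   `sigma_k`, `ratio_ave_used`.
#' @export
build_roi_table <- function(acc_binned, mol, ratio_ave = NULL, sigma_k = 3,
                            min_c = 1L,
                            threshold_rule = c("k-sd", "mean-plus-k-sd")) {
  stopifnot(inherits(acc_binned, "accumulated_image"),
            inherits(mol, "molecule_label_spec"))
  threshold_rule <- match.arg(threshold_rule)
  if (is.null(ratio_ave)) ratio_ave <- mean_sulfur_ratio(acc_binned)
  aso <- aso_signal_map(acc_binned, mol, ratio_ave = ratio_ave, min_c = min_c)
  lig <- ligand_signal_map(acc_binned, mol, min_c = min_c)
  mask <- aso$mask & lig$mask
  if (!any(mask)) stop("no valid bins")
  nb <- dim(mask)
  lv <- lig$values; av <- aso$values
  sigma <- stats::sd(lv[mask])
  if (is.na(sigma)) sigma <- 0
  thr <- if (threshold_rule == "k-sd") sigma_k * sigma
         else mean(lv[mask]) + sigma_k * sigma
  degenerate <- sigma == 0
  if (degenerate) {
    message("degenerate ligand distribution: zero variance; selecting positive bins")
    thr <- 0
  }
  selected <- mask & !is.na(lv) & lv > thr
  max_l <- max(lv[mask]); max_a <- max(av[mask])
  tab <- data.frame(
    bin_row = as.vector(row(mask)), bin_col = as.vector(col(mask)),
    ligand_value = as.vector(lv), aso_value = as.vector(av),
    ligand_norm = if (max_l > 0) as.vector(lv) / max_l else NA_real_,
    aso_norm = if (max_a > 0) as.vector(av) / max_a else NA_real_,
    selected = as.vector(selected),
    coupling = "n/a", stringsAsFactors = FALSE)
  tab$coupling[tab$selected] <-
    ifelse(tab$aso_value[tab$selected] > 0, "coupled", "decoupled")
  attr(tab, "bin_size_nm") <- acc_binned$pixel_size_nm
  attr(tab, "sigma_ligand") <- sigma
  attr(tab, "sigma_k") <- sigma_k
  attr(tab, "ratio_ave_used") <- ratio_ave
  attr(tab, "degenerate") <- degenerate
  class(tab) <- c("roi_table", "data.frame")
  tab
}

#' Classify a selected ROI as coupled or decoupled conjugate
#'
#' A ligand-selected ROI with strictly positive excess-34S (ASO) signal
#' contains the intact ligand-drug conjugate ("coupled"); a non-positive ASO
#' signal marks ligand without drug ("decoupled"). The rule depends only on
#' the sign, so it is invariant under any positive rescaling of the ASO map.
#'
#' @param roi one row of a [build_roi_table()] table (or any list with
#'   `selected` and `aso_value`).
#' @return `"coupled"` or `"decoupled"`.
#' @export
classify_coupling <- function(roi) {
  if (!isTRUE(all(roi$selected)))
    stop("classify_coupling is defined only for selected ROIs")
  ifelse(roi$aso_value > 0, "coupled", "decoupled")
}

#' Coupled/decoupled counts over selected ROIs
#'
#' @param table a [build_roi_table()] result.
#' @param per_cell_masks optional integer label matrix in bin coordinates
#'   (same dimensions as the binned image, 0 = no cell) assigning bins to
#'   cells; counts are then also reported per cell.
#' @param collapse one of `"bins"` (each selected bin is one ROI, default)
#'   or `"components"` (adjacent selected bins are merged into one ROI per
#'   connected structure, classified by the sign of its summed ASO value) --
#'   use the latter when one endosome can straddle several bins and ROIs
#'   should count structures, not bins.
#' @return list of class `coupling_summary` with `n_coupled`, `n_decoupled`,
#'   `fraction_coupled` (`NA` when nothing is selected) and optionally a
#'   `per_cell` data.frame.
#' @export
coupling_summary <- function(table, per_cell_masks = NULL,
                             collapse = c("bins", "components")) {
  stopifnot(inherits(table, "roi_table"))
  collapse <- match.arg(collapse)
  sel <- table[table$selected, , drop = FALSE]
  if (collapse == "components" && nrow(sel) > 0L) {
    nbr <- max(table$bin_row); nbc <- max(table$bin_col)
    m <- matrix(0L, nbr, nbc)
    m[cbind(sel$bin_row, sel$bin_col)] <- 1L
    lab <- EBImage::bwlabel(m)
    comp <- lab[cbind(sel$bin_row, sel$bin_col)]
    agg <- tapply(sel$aso_value, comp, sum)
    sel <- data.frame(bin_row = tapply(sel$bin_row, comp, function(x) x[1]),
                      bin_col = tapply(sel$bin_col, comp, function(x) x[1]),
                      aso_value = as.numeric(agg),
                      coupling = ifelse(agg > 0, "coupled", "decoupled"),
                      stringsAsFactors = FALSE)
  }
  n_c <- sum(sel$coupling == "coupled")
  n_d <- sum(sel$coupling == "decoupled")
  out <- list(n_coupled = n_c, n_decoupled = n_d,
              fraction_coupled = if (n_c + n_d > 0) n_c / (n_c + n_d) else NA_real_)
  if (!is.null(per_cell_masks)) {
    lab <- per_cell_masks[cbind(sel$bin_row, sel$bin_col)]
    cells <- sort(unique(lab[lab > 0]))
    out$per_cell <- do.call(rbind, lapply(cells, function(cl) {
      s <- sel[lab == cl, , drop = FALSE]
      data.frame(cell = cl,
                 n_coupled = sum(s$coupling == "coupled"),
                 n_decoupled = sum(s$coupling == "decoupled"))
    }))
  }
  class(out) <- "coupling_summary"
  out
}

#' @export
print.coupling_summary <- function(x, ...) {
  cat(sprintf("coupling_summary: %d coupled, %d decoupled (fraction %.3g)\n",
              x$n_coupled, x$n_decoupled, x$fraction_coupled))
  if (!is.null(x$per_cell)) print(x$per_cell)
  invisible(x)
}

#' Expected number of pixels above a Gaussian threshold by chance
#'
#' For a ratio image in which essentially every pixel registers a
#' measurement, chance alone puts a predictable number of pixels above any
#' sigma threshold: `n_pixels * (1 - pnorm(k_sigma))`. For a 256 x 256 image
#' (~65000 pixels) about 1.04e4 pixels exceed 1 sigma, which is why per-pixel
#' thresholding cannot isolate sparse enrichment and binning is required.
#'
#' @param n_pixels number of pixels carrying a measurement.
#' @param k_sigma one-sided threshold in standard deviations.
#' @return expected exceedance count.
#' @export
expected_exceedance_count <- function(n_pixels, k_sigma) {
  stopifnot(n_pixels >= 1)
  n_pixels * (1 - stats::pnorm(k_sigma))
}

label_components <- function(mask, min_area_px) {
  lab <- EBImage::bwlabel(mask * 1)
  if (max(lab) > 0 && min_area_px > 1) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(sizes >= min_area_px)
    lab[!(lab %in% keep)] <- 0L
    ## relabel sequentially
    if (length(keep)) lab[lab > 0] <- match(lab[lab > 0], keep)
  }
  lab
}

#' Hotspot ROI analysis with sulfur-dense-body exclusion
#'
#' Detects 34S hotspots as connected components above a percentile threshold
#' of the 34S/32S ratio image, and sulfur-dense bodies as components above a
#' percentile of the raw 32S image. Ratio hotspots that merely track dense
#' endogenous sulfur (overlapping a 32S hotspot by more than
#' `max_overlap_frac` of their area) are excluded; each retained hotspot is
#' annotated with its mean excess-34S (ASO) signal, ready for per-ROI
#' box-plot statistics.
#'
#' @param acc an [accumulated_image()] with `34S`, `32S`, `13C12C` channels.
#' @param mol a [molecule_label_spec()] for the ASO scaling (default 15
#'   labels).
#' @param ratio_ave average sulfur ratio (default per-image).
#' @param threshold_percentile percentile (0-100) defining hotspots in each
#'   source image (default 99).
#' @param min_area_px minimum component area in pixels (default 3).
#' @param max_overlap_frac ratio-hotspot overlap fraction with any 32S
#'   hotspot above which it is excluded (default 0: any overlap excludes).
#' @param min_denom count floor for the ratio image mask.
#' @return list of class `hotspot_roi_set`: `rois` data.frame (`id`,
#'   `source`, `area_px`, `overlap_frac`, `aso_stat`), and `labels`, a list
#'   of label matrices (`s34_ratio` retained hotspots, `s32` dense bodies).
#' @export
hotspot_rois <- function(acc, mol = molecule_label_spec("ASO", n_s34_labels = 15L),
                         ratio_ave = NULL, threshold_percentile = 99,
                         min_area_px = 3L, max_overlap_frac = 0,
                         min_denom = 1L) {
  stopifnot(inherits(acc, "accumulated_image"))
  if (is.null(ratio_ave)) ratio_ave <- mean_sulfur_ratio(acc)
  rmap <- ratio_map(acc, "34S", "32S", min_denom = min_denom)
  rv <- rmap$values
  rthr <- stats::quantile(rv[rmap$mask], threshold_percentile / 100, names = FALSE)
  rmask <- !is.na(rv) & rv > rthr
  rlab <- label_components(rmask, min_area_px)

  s32 <- channel_image(acc, "32S")
  sthr <- stats::quantile(s32, threshold_percentile / 100, names = FALSE)
  slab <- label_components(s32 > sthr, min_area_px)

  aso <- aso_signal_map(acc, mol, ratio_ave = ratio_ave, min_c = min_denom)
  n_r <- max(rlab)
  rois <- NULL
  if (n_r > 0) {
    rois <- do.call(rbind, lapply(seq_len(n_r), function(id) {
      px <- rlab == id
      ov <- mean(slab[px] > 0)
      data.frame(id = id, source = "34S/32S", area_px = sum(px),
                 overlap_frac = ov,
                 aso_stat = mean(aso$values[px], na.rm = TRUE))
    }))
    drop <- rois$overlap_frac > max_overlap_frac
    rlab[rlab %in% rois$id[drop]] <- 0L
    rois <- rois[!drop, , drop = FALSE]
    if (nrow(rois)) {
      rlab[rlab > 0] <- match(rlab[rlab > 0], rois$id)
      rois$id <- seq_len(nrow(rois))
    }
  }
  if (is.null(rois) || nrow(rois) == 0L) {
    warning("no hotspot ROIs retained after filtering")
    rois <- data.frame(id = integer(), source = character(),
                       area_px = integer(), overlap_frac = numeric(),
                       aso_stat = numeric())
  }
  structure(list(rois = rois,
                 labels = list(s34_ratio = rlab, s32 = slab),
                 threshold_percentile = threshold_percentile,
                 ratio_ave_used = ratio_ave),
            class = "hotspot_roi_set")
}

#' @export
print.hotspot_roi_set <- function(x, ...) {
  cat(sprintf("hotspot_roi_set: %d retained 34S/32S ROI(s), %d 32S dense bod(ies)\n",
              nrow(x$rois), max(x$labels$s32)))
  if (nrow(x$rois)) print(utils::head(x$rois, 10))
  invisible(x)
}

#' Count-weighted scaled signal of labelled ROIs
#'
#' Recomputes the per-molecule scaled signal of each ROI from its summed
#' counts (the Poisson-optimal aggregate, as used for binned ROIs) rather
#' than averaging per-pixel ratios: for ASO,
#' `(sum34 - ratio_ave * sum32) / (N_labels * sumC)`; for ligand,
#' `sumI / (N_labels * sumC)`.
#'
#' @param acc an [accumulated_image()].
#' @param label_mask integer ROI label matrix (0 = background).
#' @param mol a [molecule_label_spec()].
#' @param kind `"ASO"` or `"LIGAND"`.
#' @param ratio_ave average sulfur ratio (default per-image).
#' @return data.frame with `id`, `area_px`, `signal`.
#' @export
roi_aggregate_signal <- function(acc, label_mask, mol,
                                 kind = c("ASO", "LIGAND"), ratio_ave = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(acc, "accumulated_image"),
            inherits(mol, "molecule_label_spec"))
  if (kind == "ASO" && is.null(ratio_ave)) ratio_ave <- mean_sulfur_ratio(acc)
  cc <- channel_image(acc, "13C12C")
  ids <- sort(unique(label_mask[label_mask > 0]))
  empty <- data.frame(id = integer(), area_px = integer(), signal = numeric())
  if (!length(ids)) return(empty)
  do.call(rbind, lapply(ids, function(id) {
    px <- label_mask == id
    den <- sum(cc[px])
    sig <- if (den == 0) NA_real_ else if (kind == "ASO") {
      (sum(channel_image(acc, "34S")[px]) -
         ratio_ave * sum(channel_image(acc, "32S")[px])) /
        (mol$n_s34_labels * den)
    } else {
      sum(channel_image(acc, "127I")[px]) / (mol$n_i127_labels * den)
    }
    data.frame(id = id, area_px = sum(px), signal = sig)
  }))
}

#' Per-ROI statistics over a manual or ground-truth label mask
#'
#' Mirrors manually drawn ROIs: computes the mean (and pixel count) of a
#' signal map over each label of an integer label image.
#'
#' @param map a [signal_map()].
#' @param label_mask integer matrix, 0 = background.
#' @return data.frame with `id`, `area_px`, `mean_signal`.
#' @export
roi_stats_from_mask <- function(map, label_mask) {
  stopifnot(inherits(map, "signal_map"),
            all(dim(label_mask) == dim(map$values)))
  ids <- sort(unique(label_mask[label_mask > 0]))
  do.call(rbind, c(list(data.frame(id = integer(), area_px = integer(),
                                   mean_signal = numeric())),
    lapply(ids, function(id) {
      px <- label_mask == id
      data.frame(id = id, area_px = sum(px),
                 mean_signal = mean(map$values[px], na.rm = TRUE))
    })))
}
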