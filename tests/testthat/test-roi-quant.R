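make_roi_table <- function(aso_values, selected = rep(TRUE, length(aso_values)),
                           ligand = abs(aso_values) + 1) {
  n <- length(aso_values)
  tab <- data.frame(bin_row = seq_len(n), bin_col = rep(1L, n),
                    ligand_value = ligand, aso_value = aso_values,
                    ligand_norm = ligand / max(ligand),
                    aso_norm = aso_values / max(aso_values),
                    selected = selected, coupling = "n/a",
                    stringsAsFactors = FALSE)
  tab$coupling[tab$selected] <-
    ifelse(tab$aso_value[tab$selected] > 0, "coupled", "decoupled")
  attr(tab, "bin_size_nm") <- 468.75
  attr(tab, "sigma_ligand") <- stats::sd(ligand)
  attr(tab, "sigma_k") <- 3
  class(tab) <- c("roi_table", "data.frame")
  tab
}

test_that("physical binning uses the rounded integer factor and block sums", {
  acc <- accumulated_image(array(0L, dim = c(1, 256, 256)), channel_spec("32S"),
                           pixel_size_nm = 78.125)
  b <- bin_counts(acc, 468)
  expect_equal(attr(b, "bin_factor"), 6L)
  expect_equal(dim(b$counts), c(1L, 42L, 42L))
  expect_equal(b$pixel_size_nm, 468.75)

  ones <- accumulated_image(array(1L, dim = c(1, 6, 6)), channel_spec("32S"), 100)
  b3 <- bin_counts(ones, 300)
  expect_true(all(b3$counts == 9L))
  expect_equal(dim(b3$counts), c(1L, 2L, 2L))

  expect_identical(bin_counts(ones, 100)$counts, ones$counts)  # k = 1 identity

  set.seed(6)
  m <- matrix(rpois(144, 10), 12, 12)
  acc <- accumulated_image(array(m, dim = c(1, 12, 12)), channel_spec("32S"), 100)
  expect_equal(sum(bin_counts(acc, 300)$counts), sum(m))  # divisible: conserved
})

test_that("binned signals are count-weighted aggregates, not ratio means", {
  ## heteroscedastic 2x2 block: aggregate and mean-of-ratios must differ
  s34 <- matrix(c(10L, 0L, 0L, 0L), 2, 2)
  s32 <- matrix(c(100L, 10L, 10L, 10L), 2, 2)
  cc <- matrix(c(100L, 2L, 2L, 2L), 2, 2)
  acc <- make_test_acc(`34S` = s34, `32S` = s32, `13C12C` = cc,
                       pixel_size_nm = 100)
  mol <- molecule_label_spec("x", 15L)
  binned <- bin_counts(acc, 200)
  agg <- aso_signal_map(binned, mol, ratio_ave = 0.045)$values[1, 1]
  expect_equal(agg, (sum(s34) - 0.045 * sum(s32)) / (15 * sum(cc)))
  per_px <- aso_signal_map(acc, mol, ratio_ave = 0.045)$values
  expect_false(isTRUE(all.equal(agg, mean(per_px))))

  ## uniform image: aggregate equals the per-pixel value
  u34 <- matrix(5L, 2, 2); u32 <- matrix(100L, 2, 2); ucc <- matrix(50L, 2, 2)
  uacc <- make_test_acc(`34S` = u34, `32S` = u32, `13C12C` = ucc,
                        pixel_size_nm = 100)
  uagg <- aso_signal_map(bin_counts(uacc, 200), mol, ratio_ave = 0.045)$values[1, 1]
  upx <- aso_signal_map(uacc, mol, ratio_ave = 0.045)$values
  expect_equal(uagg, mean(upx))
})

test_that("3-sigma selection picks exactly the bright ligand structures", {
  p <- scene_params(image_px = 128L, field_of_view_um = 10, n_planes = 6L,
                    n_endosomes = 5L, endosome_conc_uM = 2000,
                    coupling_fraction = 1, seed = 15)
  truth <- make_scene(p)
  acc <- accumulate(simulate_stack(truth))
  binned <- bin_counts(acc)
  tab <- build_roi_table(binned, p$conjugate)
  k <- attr(binned, "bin_factor")
  ## ground-truth bins touched by any endosome
  touched <- sims34:::block_sum((truth$masks$endosome > 0) * 1L, k) > 0
  sel <- tab[tab$selected, ]
  expect_gt(nrow(sel), 0)
  expect_true(all(touched[cbind(sel$bin_row, sel$bin_col)]))
  ## every endosome contributes at least one selected bin
  lab_binned <- sims34:::block_sum(truth$masks$endosome, k)
  for (id in truth$endosomes$id) {
    ctr_bin <- ceiling(truth$endosomes[id, c("centroid_row", "centroid_col")] / k)
    expect_true(any(sel$bin_row == ctr_bin[[1]] & sel$bin_col == ctr_bin[[2]]))
  }
  expect_equal(max(tab$ligand_norm[!is.na(tab$ligand_norm)]), 1)
})

test_that("raising the selection threshold never adds ROIs", {
  p <- tiny_params(endosome_conc_uM = 500, seed = 8)
  binned <- bin_counts(accumulate(simulate_stack(make_scene(p))))
  prev <- NULL
  for (k in c(1, 2, 3, 5, 10)) {
    sel <- which(build_roi_table(binned, p$conjugate, sigma_k = k)$selected)
    if (!is.null(prev)) expect_true(all(sel %in% prev))
    prev <- sel
  }
})

test_that("a zero-variance ligand image is flagged and handled", {
  cc <- matrix(50L, 4, 4)
  acc <- make_test_acc(`34S` = matrix(1L, 4, 4), `32S` = matrix(20L, 4, 4),
                       `13C12C` = cc, `127I` = matrix(10L, 4, 4),
                       pixel_size_nm = 468.75)
  mol <- molecule_label_spec("x", 15L, 2L)
  expect_message(tab <- build_roi_table(acc, mol, ratio_ave = 0.045),
                 "degenerate")
  expect_true(attr(tab, "degenerate"))
  expect_true(all(tab$selected))  # all positive ligand bins
})

test_that("coupling classification follows the strict sign rule", {
  tab <- make_roi_table(c(0.002, -0.001, 0))
  expect_equal(classify_coupling(tab[1, ]), "coupled")
  expect_equal(classify_coupling(tab[2, ]), "decoupled")
  expect_equal(classify_coupling(tab[3, ]), "decoupled")  # tie -> decoupled
  unsel <- make_roi_table(0.5, selected = FALSE)
  expect_error(classify_coupling(unsel[1, ]), "selected")
})

test_that("classification is invariant under positive rescaling of the ASO map", {
  set.seed(3)
  vals <- rnorm(40)
  base <- make_roi_table(vals)$coupling
  for (scale in c(1e-6, 0.5, 7, 1e4))
    expect_identical(make_roi_table(vals * scale)$coupling, base)
})

test_that("coupling summaries count selected ROIs, optionally per cell", {
  tab <- make_roi_table(c(1, 2, 3, -1))
  s <- coupling_summary(tab)
  expect_equal(s$n_coupled, 3L)
  expect_equal(s$n_decoupled, 1L)
  expect_equal(s$fraction_coupled, 0.75)

  masks <- matrix(0L, 4, 1)
  masks[1:2, 1] <- 1L; masks[3:4, 1] <- 2L
  s2 <- coupling_summary(tab, per_cell_masks = masks)
  expect_equal(sum(s2$per_cell$n_coupled) + sum(s2$per_cell$n_decoupled),
               s2$n_coupled + s2$n_decoupled)

  none <- make_roi_table(c(1, -1), selected = c(FALSE, FALSE))
  s3 <- coupling_summary(none)
  expect_equal(s3$n_coupled + s3$n_decoupled, 0L)
  expect_true(is.na(s3$fraction_coupled))
})

test_that("adjacent selected bins collapse into one ROI per structure", {
  tab <- make_roi_table(c(1, 1, -3, 5))     # bins 1,2 adjacent; 3,4 adjacent
  tab$bin_row <- c(1L, 2L, 5L, 6L)
  s <- coupling_summary(tab, collapse = "components")
  expect_equal(s$n_coupled + s$n_decoupled, 2L)
  expect_equal(s$n_coupled, 2L)             # second component sums to +2
})

test_that("expected chance exceedance matches the Gaussian tail", {
  expect_equal(expected_exceedance_count(65536, 1),
               65536 * (1 - pnorm(1)))
  expect_lt(expected_exceedance_count(1e6, 50), 1e-12)
  set.seed(19)
  for (k in c(0, 1, 2, 3)) {
    reps <- vapply(1:30, function(i) sum(rnorm(1e4) > k), numeric(1))
    mc_sigma <- stats::sd(reps) / sqrt(length(reps))
    expect_lt(abs(mean(reps) - expected_exceedance_count(1e4, k)),
              3 * max(mc_sigma, 1e-3))
  }
})

test_that("hotspot exclusion removes ROIs explained by dense sulfur", {
  ## constructed geometry: one pure 34S hotspot, one pure 32S hotspot
  n <- 32
  s32 <- matrix(100L, n, n); s34 <- matrix(5L, n, n); cc <- matrix(50L, n, n)
  s34[5:8, 5:8] <- 60L                      # enrichment hotspot
  s32[20:23, 20:23] <- 1000L                # dense-sulfur body
  s34[20:23, 20:23] <- 45L                  # still natural ratio
  acc <- make_test_acc(`13C14N` = cc, `34S` = s34, `32S` = s32, `13C12C` = cc)
  rois <- hotspot_rois(acc, threshold_percentile = 95, min_area_px = 3)
  expect_equal(nrow(rois$rois), 1L)
  expect_true(all(rois$labels$s34_ratio[5:8, 5:8] > 0))
  expect_gt(rois$rois$aso_stat, 0)

  ## identical hotspot in both maps -> excluded
  s34b <- matrix(5L, n, n); s32b <- matrix(100L, n, n)
  s34b[5:8, 5:8] <- 500L; s32b[5:8, 5:8] <- 2000L
  accb <- make_test_acc(`13C14N` = cc, `34S` = s34b, `32S` = s32b, `13C12C` = cc)
  expect_warning(roisb <- hotspot_rois(accb, threshold_percentile = 95,
                                       min_area_px = 3), "no hotspot")
  expect_equal(nrow(roisb$rois), 0L)
})

test_that("simulated enriched endosomes survive, dense bodies are excluded", {
  p <- scene_params(image_px = 128L, field_of_view_um = 10, n_planes = 6L,
                    n_endosomes = 4L, n_sulfur_bodies = 2L,
                    sulfur_density_contrast = 1, endosome_conc_uM = 2000,
                    coupling_fraction = 1, seed = 23)
  truth <- make_scene(p)
  acc <- accumulate(simulate_stack(truth))
  rois <- hotspot_rois(acc, threshold_percentile = 96, min_area_px = 10)
  expect_equal(nrow(rois$rois), 4L)
  ## each retained ROI sits on a distinct ground-truth endosome
  ids <- vapply(seq_len(nrow(rois$rois)), function(i) {
    px <- rois$labels$s34_ratio == rois$rois$id[i]
    lab <- truth$masks$endosome[px]
    as.integer(names(sort(table(lab[lab > 0]), decreasing = TRUE))[1])
  }, integer(1))
  expect_setequal(ids, truth$endosomes$id)
  ## the dense bodies were found on the 32S image
  expect_gte(max(rois$labels$s32), 2L)
})

test_that("count-weighted ROI aggregates recover endosome load", {
  p <- tiny_params(endosome_conc_uM = 500, coupling_fraction = 1, seed = 31)
  truth <- make_scene(p)
  acc <- accumulate(simulate_stack(truth))
  agg <- roi_aggregate_signal(acc, truth$masks$endosome, p$conjugate, "ASO",
                              ratio_ave = p$natural_s34_ratio)
  expect_equal(nrow(agg), p$n_endosomes)
  expected <- 500 * p$signal_per_uM_per_label / p$base_yields[["13C12C"]]
  expect_equal(mean(agg$signal), expected, tolerance = 0.15)
  lig <- roi_aggregate_signal(acc, truth$masks$endosome, p$conjugate, "LIGAND")
  expect_true(all(lig$signal > 0))
})
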