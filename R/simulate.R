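#' Parameters of a synthetic NanoSIMS scene
#'
#' Defines the geometry, ion yields and conjugate load of a simulated cell
#' imaged by NanoSIMS. Defaults emulate the study conditions: a 20 um square
#' field at 256 x 256 pixels, 10 accumulated planes, 5 ms dwell, an
#' endogenous sulfur density varying by two orders of magnitude across the
#' cell, the natural 34S/32S abundance at the CDT value, endosomes of a few
#' hundred nm carrying a dual-labelled conjugate at ~100 uM (the
#' endo-lysosomal accumulation estimated from receptor numbers and endosomal
#' volume), and a per-label count yield anchored so that 20 uM sits near
#' 3 sigma above the natural-abundance background at the 468 nm bin scale
#' (the limit-of-detection regime).
#'
#' @param image_px image edge in pixels.
#' @param field_of_view_um square field edge, um.
#' @param n_planes number of sequential planes.
#' @param dwell_ms per-pixel dwell time, ms.
#' @param cell_radius_frac,nucleus_radius_frac cell and nucleus radii as a
#'   fraction of the image edge.
#' @param n_endosomes number of conjugate-containing endosomes.
#' @param endosome_radius_nm endosome radius, nm (structures of ~300-500 nm).
#' @param n_sulfur_bodies number of sulfur-dense organelle mimics at natural
#'   isotope abundance (confound for hotspot analysis).
#' @param sulfur_body_radius_nm radius of sulfur-dense bodies, nm.
#' @param sulfur_density_contrast ratio of highest to lowest endogenous
#'   sulfur density across the cytoplasm (default 100).
#' @param base_yields named expected counts per plane per pixel at unit
#'   density for `13C12C`, `13C14N` and `32S`.
#' @param natural_s34_ratio natural 34S/32S abundance (default CDT).
#' @param conjugate a [molecule_label_spec()] carrying both label counts.
#' @param endosome_conc_uM conjugate concentration inside endosomes, uM.
#' @param coupling_fraction probability that an endosome contains the intact
#'   (coupled) conjugate; decoupled endosomes carry ligand but no excess 34S.
#' @param signal_per_uM_per_label expected label-derived counts per plane per
#'   pixel per uM per label.
#' @param drift_px_per_plane integer `(dy, dx)` cumulative drift per plane.
#' @param seed integer seed fixing all randomness of the scene and sampling.
#' @return validated list of class `scene_params`.
#' @export
scene_params <- function(image_px = 256L, field_of_view_um = 20,
                         n_planes = 10L, dwell_ms = 5,
                         cell_radius_frac = 0.45, nucleus_radius_frac = 0.18,
                         n_endosomes = 12L, endosome_radius_nm = 400,
                         n_sulfur_bodies = 0L, sulfur_body_radius_nm = 500,
                         sulfur_density_contrast = 100,
                         base_yields = c("13C12C" = 20, "13C14N" = 50, "32S" = 5),
                         natural_s34_ratio = CDT_S34_S32,
                         conjugate = molecule_label_spec("127I2-eGLP1-34S15-ASO",
                                                         n_s34_labels = 15L,
                                                         n_i127_labels = 2L),
                         endosome_conc_uM = 100,
                         coupling_fraction = 1,
                         signal_per_uM_per_label = 1.1e-3,
                         drift_px_per_plane = c(0L, 0L),
                         seed = 1L) {
  p <- list(image_px = as.integer(image_px),
            field_of_view_um = field_of_view_um, n_planes = as.integer(n_planes),
            dwell_ms = dwell_ms, cell_radius_frac = cell_radius_frac,
            nucleus_radius_frac = nucleus_radius_frac,
            n_endosomes = as.integer(n_endosomes),
            endosome_radius_nm = endosome_radius_nm,
            n_sulfur_bodies = as.integer(n_sulfur_bodies),
            sulfur_body_radius_nm = sulfur_body_radius_nm,
            sulfur_density_contrast = sulfur_density_contrast,
            base_yields = base_yields, natural_s34_ratio = natural_s34_ratio,
            conjugate = conjugate, endosome_conc_uM = endosome_conc_uM,
            coupling_fraction = coupling_fraction,
            signal_per_uM_per_label = signal_per_uM_per_label,
            drift_px_per_plane = as.integer(drift_px_per_plane),
            seed = as.integer(seed))
  stopifnot(p$image_px >= 8L, p$field_of_view_um > 0, p$n_planes >= 1L,
            p$dwell_ms > 0, p$sulfur_density_contrast >= 1,
            all(p$base_yields >= 0),
            p$natural_s34_ratio > 0, p$natural_s34_ratio < 1,
            p$coupling_fraction >= 0, p$coupling_fraction <= 1,
            p$endosome_conc_uM >= 0, p$signal_per_uM_per_label >= 0,
            all(c("13C12C", "13C14N", "32S") %in% names(p$base_yields)),
            inherits(p$conjugate, "molecule_label_spec"),
            length(p$drift_px_per_plane) == 2L)
  class(p) <- "scene_params"
  p
}

sim_channels <- c("13C12C", "13C14N", "32S", "34S", "127I")

## Bilinear upsampling of a small grid to n x n (smooth random field).
smooth_field <- function(grid, n) {
  g <- nrow(grid)
  xs <- seq(1, g, length.out = n)
  rows <- t(apply(grid, 1, function(r) stats::approx(seq_len(g), r, xout = xs)$y))
  apply(rows, 2, function(cc) stats::approx(seq_len(g), cc, xout = xs)$y)
}

disc_mask <- function(n, cy, cx, r) {
  dy <- matrix(seq_len(n), n, n) - cy
  dx <- matrix(seq_len(n), n, n, byrow = TRUE) - cx
  dy * dy + dx * dx <= r * r
}

place_discs <- function(n_discs, r, cy, cx, cell_r, nuc_r, occupied_centers,
                        occupied_r, n) {
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(centers) < n_discs) {
    tries <- tries + 1L
    if (tries > 2000L * max(n_discs, 1L))
      stop("cannot place endosomes: geometry too crowded")
    y <- stats::runif(1, 1, n); x <- stats::runif(1, 1, n)
    dc <- sqrt((y - cy)^2 + (x - cx)^2)
    if (dc > cell_r - r - 1 || dc < nuc_r + r + 1) next
    all_c <- rbind(centers, occupied_centers)
    all_r <- c(rep(r, nrow(centers)), occupied_r)
    if (nrow(all_c) > 0) {
      dd <- sqrt((all_c[, 1] - y)^2 + (all_c[, 2] - x)^2)
      if (any(dd < all_r + r + 2)) next
    }
    centers <- rbind(centers, c(y, x))
  }
  centers
}

#' Build the ground truth of a synthetic scene
#'
#' Deterministic given the seed. Per-pixel expected count rates (per plane):
#' the 32S rate follows the endogenous sulfur density field (log-smooth,
#' spanning `sulfur_density_contrast`); the 34S rate is the 32S rate times
#' the natural abundance plus, inside coupled endosomes only, the
#' label-derived term `conc * n_s34_labels * signal_per_uM_per_label`; the
#' 127I rate is `conc * n_i127_labels * signal_per_uM_per_label` in every
#' labelled endosome (coupled or decoupled -- decoupling means the ligand
#' arrived without its drug cargo); the carbon channels track a structural
#' density map of the cell. Sulfur-dense bodies carry elevated sulfur at
#' natural isotope abundance.
#'
#' @param params a [scene_params()].
#' @return list of class `sims_ground_truth` with `rates` (per-channel
#'   matrices), `masks` (`region` 0 background / 1 cytoplasm / 2 nucleus,
#'   `endosome` and `sulfur_body` label matrices), `endosomes` table and
#'   `params`.
#' @export
make_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(params$seed)
  n <- params$image_px
  px_nm <- params$field_of_view_um * 1000 / n
  cy <- cx <- (n + 1) / 2
  cell_r <- params$cell_radius_frac * n
  nuc_r <- params$nucleus_radius_frac * n
  cell <- disc_mask(n, cy, cx, cell_r)
  nucleus <- disc_mask(n, cy, cx, nuc_r)
  region <- matrix(0L, n, n)
  region[cell] <- 1L
  region[nucleus] <- 2L

  ## endogenous sulfur density: smooth log field spanning the contrast range
  f <- smooth_field(matrix(stats::rnorm(64), 8, 8), n)
  f <- (f - min(f)) / max(f - min(f))
  dens <- params$sulfur_density_contrast^f
  s_dens <- matrix(0.05, n, n)
  s_dens[region == 1L] <- dens[region == 1L]
  s_dens[region == 2L] <- dens[region == 2L] / 3

  structure_dens <- matrix(0.02, n, n)
  structure_dens[region == 1L] <- 1
  structure_dens[region == 2L] <- 1.3

  ## sulfur-dense bodies (natural abundance) then endosomes, non-overlapping
  body_r <- params$sulfur_body_radius_nm / px_nm
  endo_r <- params$endosome_radius_nm / px_nm
  body_centers <- place_discs(params$n_sulfur_bodies, body_r, cy, cx,
                              cell_r, nuc_r, matrix(numeric(0), 0, 2),
                              numeric(0), n)
  endo_centers <- place_discs(params$n_endosomes, endo_r, cy, cx,
                              cell_r, nuc_r, body_centers,
                              rep(body_r, nrow(body_centers)), n)
  body_lab <- matrix(0L, n, n)
  if (nrow(body_centers)) for (i in seq_len(nrow(body_centers))) {
    m <- disc_mask(n, body_centers[i, 1], body_centers[i, 2], body_r)
    body_lab[m] <- i
    s_dens[m] <- params$sulfur_density_contrast * 3
  }
  endo_lab <- matrix(0L, n, n)
  if (nrow(endo_centers)) for (i in seq_len(nrow(endo_centers))) {
    m <- disc_mask(n, endo_centers[i, 1], endo_centers[i, 2], endo_r)
    endo_lab[m] <- i
  }
  is_coupled <- if (params$n_endosomes > 0)
    stats::rbinom(params$n_endosomes, 1L, params$coupling_fraction) == 1L
  else logical(0)

  y <- params$base_yields
  s <- params$signal_per_uM_per_label
  conc <- params$endosome_conc_uM
  mol <- params$conjugate
  r32 <- s_dens * y[["32S"]]
  r34 <- r32 * params$natural_s34_ratio
  r127 <- matrix(0, n, n)
  if (params$n_endosomes > 0) {
    coupled_px <- endo_lab > 0 & matrix(c(FALSE, is_coupled)[endo_lab + 1L], n, n)
    r34[coupled_px] <- r34[coupled_px] + conc * mol$n_s34_labels * s
    if (mol$n_i127_labels > 0)
      r127[endo_lab > 0] <- conc * mol$n_i127_labels * s
  }
  rates <- list("13C12C" = structure_dens * y[["13C12C"]],
                "13C14N" = structure_dens * y[["13C14N"]],
                "32S" = r32, "34S" = r34, "127I" = r127)
  endosomes <- data.frame(
    id = seq_len(params$n_endosomes),
    centroid_row = if (nrow(endo_centers)) endo_centers[, 1] else numeric(0),
    centroid_col = if (nrow(endo_centers)) endo_centers[, 2] else numeric(0),
    radius_px = rep(endo_r, params$n_endosomes),
    conc_uM = rep(conc, params$n_endosomes),
    is_coupled = is_coupled)
  structure(list(rates = rates,
                 masks = list(region = region, endosome = endo_lab,
                              sulfur_body = body_lab),
                 endosomes = endosomes,
                 pixel_size_nm = px_nm,
                 params = params),
            class = "sims_ground_truth")
}

#' Uniform-slab standard scene of known label concentration
#'
#' Ground truth for a calibration standard: a homogeneous material at a
#' fixed sulfur density carrying the conjugate labels uniformly at the given
#' concentration (0 for a blank). Mimics the excess-34S expected in
#' drug-containing organelles.
#'
#' @param params a [scene_params()] (geometry parameters are ignored; yields,
#'   labels and signal scale are used).
#' @param conc_uM label concentration of the slab, uM (0 = blank).
#' @param standard_density sulfur density of the slab matrix, in the same
#'   units as the cellular density field (default 20, a representative
#'   mid-cell value).
#' @return a `sims_ground_truth` with uniform rates and no endosomes.
#' @export
make_standard_scene <- function(params, conc_uM, standard_density = 20) {
  stopifnot(inherits(params, "scene_params"), conc_uM >= 0)
  n <- params$image_px
  y <- params$base_yields
  mol <- params$conjugate
  s <- params$signal_per_uM_per_label
  r32 <- matrix(standard_density * y[["32S"]], n, n)
  r34 <- r32 * params$natural_s34_ratio + conc_uM * mol$n_s34_labels * s
  r127 <- matrix(conc_uM * mol$n_i127_labels * s, n, n)
  rates <- list("13C12C" = matrix(y[["13C12C"]], n, n),
                "13C14N" = matrix(y[["13C14N"]], n, n),
                "32S" = r32, "34S" = r34, "127I" = r127)
  structure(list(rates = rates,
                 masks = list(region = matrix(1L, n, n),
                              endosome = matrix(0L, n, n),
                              sulfur_body = matrix(0L, n, n)),
                 endosomes = data.frame(id = integer(), centroid_row = numeric(),
                                        centroid_col = numeric(),
                                        radius_px = numeric(), conc_uM = numeric(),
                                        is_coupled = logical()),
                 pixel_size_nm = params$field_of_view_um * 1000 / n,
                 params = params),
            class = "sims_ground_truth")
}

#' Sample an ion-count stack from a ground-truth scene
#'
#' Per plane, channel and pixel, counts are independent Poisson draws at the
#' scene's expected rate; the optional stage drift is applied cumulatively
#' (plane p is shifted by `(p-1) * drift_px_per_plane` with zero-filled
#' borders) before sampling, emulating the raw, unaligned acquisition.
#'
#' @param truth a [make_scene()] / [make_standard_scene()] ground truth.
#' @param seed seed for the count sampling (default derived from the scene
#'   seed, so scene construction and sampling use distinct streams).
#' @return an [ion_count_stack()] with channels
#'   `13C12C, 13C14N, 32S, 34S, 127I`.
#' @export
simulate_stack <- function(truth, seed = truth$params$seed + 1L) {
  stopifnot(inherits(truth, "sims_ground_truth"))
  p <- truth$params
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  n <- p$image_px
  counts <- array(0L, dim = c(p$n_planes, length(sim_channels), n, n))
  drift <- p$drift_px_per_plane
  for (pl in seq_len(p$n_planes)) {
    off <- (pl - 1L) * drift
    for (ci in seq_along(sim_channels)) {
      r <- truth$rates[[sim_channels[ci]]]
      if (any(off != 0L)) r <- shift_zero(r, off[1], off[2])
      counts[pl, ci, , ] <- stats::rpois(n * n, as.vector(r))
    }
  }
  ion_count_stack(counts, channel_spec(sim_channels), p$field_of_view_um,
                  p$dwell_ms)
}

#' Per-endosome ground-truth table
#'
#' @param truth a [make_scene()] result.
#' @return `data.frame` with one row per endosome: `id`, centroid, radius,
#'   `conc_uM`, `is_coupled`.
#' @export
ground_truth_table <- function(truth) {
  stopifnot(inherits(truth, "sims_ground_truth"))
  truth$endosomes
}

#' Closed-form limit of detection implied by the generator
#'
#' Analytic LOD of the simulated measurement at the binned-ROI scale: the
#' Poisson standard deviation of a blank bin's excess-34S value is
#' `sqrt(lambda34 + r^2 * lambda32) / (N_labels * lambdaC)` (bin totals over
#' `bin_factor^2` pixels and all planes), the per-uM response is
#' `signal_per_uM_per_label / yield_13C12C`, and the LOD is
#' `k_sigma * sd / slope`.
#'
#' @param params a [scene_params()].
#' @param bin_factor pixels per bin edge.
#' @param standard_density sulfur density of the blank matrix.
#' @param k_sigma detection multiplier.
#' @return list with `lod_uM`, `slope`, `background_sd`.
#' @export
generator_lod <- function(params, bin_factor = 6L, standard_density = 20,
                          k_sigma = 3) {
  stopifnot(inherits(params, "scene_params"))
  y <- params$base_yields
  area <- bin_factor^2
  pl <- params$n_planes
  l32 <- standard_density * y[["32S"]] * pl * area
  l34 <- l32 * params$natural_s34_ratio
  lC <- y[["13C12C"]] * pl * area
  nl <- params$conjugate$n_s34_labels
  sd_bg <- sqrt(l34 + params$natural_s34_ratio^2 * l32) / (nl * lC)
  slope <- params$signal_per_uM_per_label / y[["13C12C"]]
  list(lod_uM = k_sigma * sd_bg / slope, slope = slope, background_sd = sd_bg)
}
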