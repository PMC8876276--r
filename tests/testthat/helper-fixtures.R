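## Shared fixtures: all inputs are generated in code at test time.

## A small random ion-count stack with the five standard channels.
make_test_stack <- function(n = 16L, planes = 2L, lambda = 5, seed = 11L,
                            channels = c("13C12C", "13C14N", "32S", "34S", "127I"),
                            fov_um = n * 78.125 / 1000) {
  set.seed(seed)
  counts <- array(rpois(planes * length(channels) * n * n, lambda),
                  dim = c(planes, length(channels), n, n))
  ion_count_stack(counts, channel_spec(channels), fov_um, dwell_time_ms = 5)
}

## An accumulated image built directly from per-channel matrices.
make_test_acc <- function(..., pixel_size_nm = 78.125) {
  chans <- list(...)
  n <- nrow(chans[[1]])
  counts <- array(0L, dim = c(length(chans), n, ncol(chans[[1]])))
  for (i in seq_along(chans)) counts[i, , ] <- chans[[i]]
  accumulated_image(counts, channel_spec(names(chans)), pixel_size_nm)
}

## Small, fast scene: same 78.125 nm pixel size as the full 20 um field.
tiny_params <- function(...) {
  args <- list(image_px = 64L, field_of_view_um = 5, n_planes = 4L,
               n_endosomes = 4L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(scene_params, args)
}

## Exhaustive integer-offset alignment oracle: the (dy, dx) within +/- w
## maximising the per-pixel overlap cross-correlation (normalised by the
## overlap area, so large image means do not favour the null shift).
exhaustive_shift_oracle <- function(ref, img, w = 5L) {
  best <- c(0L, 0L); best_v <- -Inf
  n <- nrow(ref)
  for (dy in -w:w) for (dx in -w:w) {
    n_overlap <- (n - abs(dy)) * (ncol(ref) - abs(dx))
    v <- sum(ref * sims34:::shift_zero(img, dy, dx)) / n_overlap
    if (v > best_v) { best_v <- v; best <- c(dy, dx) }
  }
  best
}

## Cyclic roll used to construct known drifts.
roll_mat <- function(m, dy, dx) sims34:::roll2(m, dy, dx)
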