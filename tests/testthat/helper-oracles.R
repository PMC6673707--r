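# Independent oracles and small fixture builders shared across tests.

# Brute-force Chebyshev distance (in voxels) from every voxel to a seed
# mask: direct minimum over seed voxels, no morphology involved.
brute_chebyshev <- function(seed) {
  d <- dim(seed)
  seeds <- which(seed, arr.ind = TRUE)
  co <- arrayInd(seq_len(prod(d)), d)
  dist <- rep(Inf, prod(d))
  for (r in seq_len(nrow(seeds))) {
    dist <- pmin(dist, pmax(abs(co[, 1] - seeds[r, 1]),
                            abs(co[, 2] - seeds[r, 2]),
                            abs(co[, 3] - seeds[r, 3])))
  }
  array(dist, d)
}

# Random blob mask: a few random voxels dilated a random number of steps.
random_blob <- function(shape, n_seeds = 3, max_grow = 1) {
  a <- array(FALSE, shape)
  idx <- sample(prod(shape), n_seeds)
  a[idx] <- TRUE
  for (k in seq_len(sample(0:max_grow, 1))) a <- penumbra:::dilate_binary(a)
  a
}

# An all-tract, all-NAWM world around a given lesion mask: every voxel is
# tract, NAWM is everything except the lesion.
world_around <- function(lesion_arr, grid = NULL) {
  shape <- dim(lesion_arr)
  if (is.null(grid)) grid <- volume_grid(shape)
  tract <- mask_volume(array(TRUE, shape), grid)
  wmh <- mask_volume(lesion_arr, grid)
  nawm <- mask_volume(!lesion_arr, grid)
  partition_tract(tract, wmh, nawm)
}

# Shell-record table with planted values, for model-level tests that do
# not need any geometry.
planted_records <- function(n_participants, distances = c(0, 2, 4, 6, 8, 10),
                            b0 = 0.3, b1 = 0.024,
                            sd_int = 0, sd_slope = 0, sd_resid = 0,
                            tract = "t1", type = "tract_wmh") {
  d <- expand.grid(participant = sprintf("p%02d", seq_len(n_participants)),
                   distance_mm = distances, stringsAsFactors = FALSE)
  d$tract <- tract
  d$wmh_type <- type
  logd <- log(d$distance_mm + 1)
  pi_ <- as.integer(factor(d$participant))
  bi <- stats::rnorm(n_participants, 0, sd_int)[pi_]
  bs <- stats::rnorm(n_participants, 0, sd_slope)[pi_]
  d$mean_fa <- b0 + bi + (b1 + bs) * logd +
    stats::rnorm(nrow(d), 0, sd_resid)
  d$mean_md <- 8e-4
  d$n_voxels <- 50L
  d$excluded_csf <- FALSE
  d
}

# Minimal zero-noise phantom built by hand: a lesion fully inside a tract
# box inside an all-NAWM domain, with maps planted via synthesize_maps.
handmade_phantom <- function(shape = c(24, 24, 24),
                             fa_slope = 0.024, md_slope = -0.085e-4) {
  grid <- volume_grid(shape)
  domain <- array(FALSE, shape)
  domain[3:(shape[1] - 2), 3:(shape[2] - 2), 3:(shape[3] - 2)] <- TRUE
  tract <- array(FALSE, shape)
  tract[5:(shape[1] - 4), 5:(shape[2] - 4), 5:(shape[3] - 4)] <- TRUE
  c0 <- round(shape / 2)
  lesion <- array(FALSE, shape)
  lesion[(c0[1] - 1):(c0[1] + 1), (c0[2] - 1):(c0[2] + 1), c0[3]] <- TRUE
  wmh <- mask_volume(lesion, grid)
  nawm <- mask_volume(domain & !lesion, grid)
  truth <- list(list(type = "intersecting", gap_steps = NA_real_,
                     voxels = which(lesion)))
  params <- list(
    gradient_params = list(fa_at_wmh = 0.30, fa_slope = fa_slope,
                           md_at_wmh = 9e-4, md_slope = md_slope,
                           fa_asymptote = 1, md_asymptote = 1e-9,
                           nearby_offset_fa = 0.015,
                           nearby_offset_md = -0.012e-4,
                           fa_nearby_slope_delta = 0,
                           md_nearby_slope_delta = 0),
    noise_sd = list(fa = 0, md = 0), csf_fraction = 0,
    participant_effects = NULL, tract_effects = NULL, tract_masks = NULL)
  maps <- synthesize_maps(wmh, nawm, truth, params, seed = 1)
  list(grid = grid,
       participant = list(id = "p1",
                          tract_masks = list(t1 = mask_volume(tract, grid)),
                          wmh_mask = wmh, nawm_mask = nawm,
                          fa = maps$fa, md = maps$md))
}
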