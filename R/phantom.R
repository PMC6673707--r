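# Synthetic phantom cohort generator.
#
# Emulates the per-participant imaging bundle the analysis consumes: tract
# posterior-probability maps, a whole-brain WMH mask, a NAWM mask, and FA /
# MD parametric maps, with a KNOWN planted structure:
#
#   outcome(voxel) = beta0 + beta1 * log(d_mm + 1)
#                    + participant intercept + participant slope * log(d+1)
#                    + tract intercept + tract slope * log(d+1)
#                    + nearby offset (voxels whose closest lesion is a
#                      non-intersecting one) + Gaussian voxel noise
#
# where d_mm is the Chebyshev voxel distance to the nearest WMH voxel times
# the 2 mm voxel size, capped at 10 mm (the planted curve is frozen at its
# 10 mm level beyond the modelled range). Chebyshev distance is used so the
# planted gradient is exactly aligned with the 26-connected shell geometry:
# with zero noise and zero random effects, downstream shell means recover
# the planted curve to machine precision.

derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + (p %% 1000003) * 104729) %% 2147483629
  as.integer(s + 1)
}

default_tract_specs <- function(grid_shape, n_tracts = 2, radius_mm = 4,
                                voxel_mm = 2) {
  ys <- round(seq(0.3, 0.7, length.out = max(n_tracts, 2)) * grid_shape[2L])
  ys <- ys[seq_len(n_tracts)]
  z <- round(grid_shape[3L] / 2)
  # keep the >0.01 probability support (radius ~1.95 x nominal) inside the
  # brain box, which is inset 2 voxels from the grid border
  inset <- ceiling(1.95 * radius_mm / voxel_mm) + 3L
  lapply(seq_len(n_tracts), function(t) {
    list(name = sprintf("tract%02d", t),
         control_points = rbind(c(inset, ys[t], z),
                                c(grid_shape[1L] - inset + 1L, ys[t], z)),
         radius_mm = radius_mm)
  })
}

#' Phantom cohort configuration
#'
#' Collects every knob of the synthetic cohort with validated defaults.
#' Gradient defaults plant the effect sizes used throughout the validation
#' suite: an FA log-distance slope of 0.024 per unit log(mm+1) rising from
#' 0.30 inside the lesion, an MD slope of -0.085e-4 mm^2/s falling from
#' 9.0e-4 mm^2/s, and nearby-lesion offsets of +0.015 (FA) and -0.012e-4
#' mm^2/s (MD). Random-effect SDs and voxel noise defaults are chosen so
#' that shell means (tens to hundreds of voxels) carry realistic
#' between-participant and between-tract variation without drowning the
#' planted gradient; see the methods vignette for the reasoning.
#'
#' @param n_participants number of participants.
#' @param grid_shape 3 integers (default 64x64x40).
#' @param voxel_size_mm voxel size, must be isotropic (default 2 mm).
#' @param tract_specs list of `list(name, control_points, radius_mm)`;
#'   control points are voxel coordinates (rows of a matrix). Default: two
#'   straight parallel tubes along the x axis.
#' @param lesion_plan list with `n_intersecting`, `n_nearby` (per tract),
#'   `semi_axes_range_mm`, `nearby_gap_range_mm`, `min_separation_vox`
#'   (Chebyshev separation enforced between lesions so planted
#'   nearest-lesion types stay unambiguous), `max_attempts`.
#' @param gradient_params list with `fa_at_wmh`, `fa_slope`, `md_at_wmh`,
#'   `md_slope`, `fa_asymptote`, `md_asymptote`, `nearby_offset_fa`,
#'   `nearby_offset_md`, `fa_nearby_slope_delta`, `md_nearby_slope_delta`.
#'   MD quantities are in natural mm^2/s units.
#' @param random_effects per outcome (`fa`, `md`): SDs of participant and
#'   tract random intercepts and log-distance slopes.
#' @param noise_sd per-voxel Gaussian residual SD per outcome.
#' @param csf_fraction fraction of the non-NAWM brain-border rim given
#'   CSF-like MD above 1e-3 mm^2/s.
#' @param brain_margin_vox background margin around the brain box.
#' @param seed integer seed; the whole cohort is a pure function of this
#'   configuration.
#' @return A validated `phantom_config` list.
#' @export
phantom_config <- function(n_participants = 10,
                           grid_shape = c(64, 64, 40),
                           voxel_size_mm = c(2, 2, 2),
                           tract_specs = NULL,
                           lesion_plan = list(),
                           gradient_params = list(),
                           random_effects = list(),
                           noise_sd = list(),
                           csf_fraction = 0.1,
                           brain_margin_vox = 2,
                           seed = 1) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L))
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (diff(range(voxel_size_mm)) > 1e-6)
    stop("phantom grids must be isotropic")
  if (is.null(tract_specs))
    tract_specs <- default_tract_specs(grid_shape, 2,
                                       voxel_mm = voxel_size_mm[1L])
  plan <- utils::modifyList(list(
    n_intersecting = 1L, n_nearby = 1L,
    semi_axes_range_mm = c(2, 5),
    nearby_gap_range_mm = c(2, 6),
    min_separation_vox = 12L,
    contain_intersecting = TRUE,
    max_attempts = 500L
  ), lesion_plan)
  gp <- utils::modifyList(list(
    fa_at_wmh = 0.30, fa_slope = 0.024,
    md_at_wmh = 9.0e-4, md_slope = -0.085e-4,
    fa_asymptote = 0.60, md_asymptote = 6.5e-4,
    nearby_offset_fa = 0.015, nearby_offset_md = -0.012e-4,
    fa_nearby_slope_delta = 0, md_nearby_slope_delta = 0
  ), gradient_params)
  re <- utils::modifyList(list(
    fa = list(sd_participant_intercept = 0.02, sd_participant_slope = 0.005,
              sd_tract_intercept = 0.02, sd_tract_slope = 0.005),
    md = list(sd_participant_intercept = 0.3e-4, sd_participant_slope = 0.05e-4,
              sd_tract_intercept = 0.3e-4, sd_tract_slope = 0.02e-4)
  ), random_effects)
  ns <- utils::modifyList(list(fa = 0.05, md = 0.5e-4), noise_sd)

  if (n_participants < 1L) stop("n_participants must be >= 1")
  if (gp$fa_at_wmh < 0 || gp$fa_at_wmh > 1 ||
      gp$fa_asymptote < 0 || gp$fa_asymptote > 1)
    stop("fa_at_wmh and fa_asymptote must lie in [0, 1]")
  if (gp$md_at_wmh <= 0 || gp$md_asymptote <= 0)
    stop("MD levels must be positive")
  for (oc in c("fa", "md")) {
    if (any(unlist(re[[oc]]) < 0)) stop("random-effect SDs must be >= 0")
    if (ns[[oc]] < 0) stop("noise SDs must be >= 0")
  }
  if (plan$semi_axes_range_mm[1L] < voxel_size_mm[1L] / 2)
    stop("lesion semi-axes must be at least half a voxel")
  if (csf_fraction < 0 || csf_fraction > 1)
    stop("csf_fraction must lie in [0, 1]")
  fa_end <- gp$fa_at_wmh + gp$fa_slope * log(11)
  if (fa_end < 0 || fa_end > 1)
    warning(sprintf(
      "planted FA reaches %.3f at 10 mm before clipping; check fa_slope",
      fa_end))
  structure(list(
    n_participants = as.integer(n_participants),
    grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
    tract_specs = tract_specs, lesion_plan = plan,
    gradient_params = gp, random_effects = re, noise_sd = ns,
    csf_fraction = csf_fraction,
    brain_margin_vox = as.integer(brain_margin_vox),
    seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Synthetic tract posterior-probability map
#'
#' A smooth tube around a polyline centerline: probability 1 on the
#' centerline (with a small flat core, so centerline voxels stay >= 0.9
#' even for thin, obliquely sampled tubes), Gaussian decay with distance,
#' strictly below 0.01 beyond twice the nominal radius. Deterministic.
#'
#' @param spec `list(name, control_points, radius_mm)`; control points in
#'   voxel coordinates (rows).
#' @param grid an isotropic [volume_grid()].
#' @return A `scalar_volume` probability map in \[0,1\].
#' @export
make_tract_probability_map <- function(spec, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  if (!grid_is_isotropic(grid, 1e-6))
    stop("phantom tract maps require an isotropic grid")
  cp <- spec$control_points
  if (is.null(dim(cp))) cp <- matrix(cp, ncol = 3L, byrow = TRUE)
  if (ncol(cp) != 3L || nrow(cp) < 2L)
    stop("control points must be an n x 3 matrix with n >= 2")
  if (any(cp < 1) || any(sweep(cp, 2L, grid$shape, `>`)))
    stop(sprintf("tract '%s': centerline lies outside the grid", spec$name))
  r <- spec$radius_mm
  vox <- grid$voxel_size_mm[1L]
  if (r < vox / 2) stop("tract radius must be at least half a voxel")

  # densify the polyline at quarter-voxel steps
  pts <- list()
  for (s in seq_len(nrow(cp) - 1L)) {
    a <- cp[s, ]; b <- cp[s + 1L, ]
    n <- max(2L, ceiling(sqrt(sum((b - a)^2)) * 4))
    lam <- seq(0, 1, length.out = n)
    pts[[s]] <- cbind(a[1] + lam * (b[1] - a[1]),
                      a[2] + lam * (b[2] - a[2]),
                      a[3] + lam * (b[3] - a[3]))
  }
  pts <- do.call(rbind, pts)

  d <- grid$shape
  xi <- array(rep(seq_len(d[1L]), times = d[2L] * d[3L]), d)
  yi <- array(rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]), d)
  zi <- array(rep(seq_len(d[3L]), each = d[1L] * d[2L]), d)
  min_d2 <- array(Inf, d)
  for (p in seq_len(nrow(pts))) {
    d2 <- (xi - pts[p, 1L])^2 + (yi - pts[p, 2L])^2 + (zi - pts[p, 3L])^2
    min_d2 <- pmin(min_d2, d2)
  }
  dist_mm <- sqrt(min_d2) * vox
  core <- 0.25 * r
  prob <- exp(-1.6 * (pmax(dist_mm - core, 0) / r)^2)
  scalar_volume(prob, grid)
}

ellipsoid_voxels <- function(center, semi_axes_vox, shape) {
  lo <- pmax(floor(center - semi_axes_vox), 1)
  hi <- pmin(ceiling(center + semi_axes_vox), shape)
  if (any(lo > hi)) return(array(FALSE, shape))
  xs <- lo[1L]:hi[1L]; ys <- lo[2L]:hi[2L]; zs <- lo[3L]:hi[3L]
  gx <- ((xs - center[1L]) / semi_axes_vox[1L])^2
  gy <- ((ys - center[2L]) / semi_axes_vox[2L])^2
  gz <- ((zs - center[3L]) / semi_axes_vox[3L])^2
  box <- outer(outer(gx, gy, `+`), gz, `+`) <= 1
  out <- array(FALSE, shape)
  out[xs, ys, zs] <- box
  out
}

#' Place intersecting and nearby lesions for one tract
#'
#' Ellipsoidal lesions are placed by constrained rejection sampling:
#' intersecting lesions share at least one voxel with the tract (and, with
#' the default `contain_intersecting = TRUE`, lie fully inside it, so
#' shells grown from the tract-WMH carry exactly the planted distance
#' field); nearby
#' lesions share none and sit at a Chebyshev gap (in dilation steps) drawn
#' from the plan's `nearby_gap_range_mm`, so their 2--10 mm contours can
#' reach the tract. Lesions stay inside the brain extent, are pairwise
#' disjoint, and keep at least `min_separation_vox` Chebyshev voxels
#' between each other (also from `avoid`), so that each NAWM voxel within
#' shell range is unambiguously closest to one lesion.
#'
#' @param tract_mask the tract `mask_volume`.
#' @param nawm_extent `mask_volume` of the brain white-matter extent
#'   lesions must stay inside.
#' @param plan lesion plan (see [phantom_config()]).
#' @param seed integer; placement is deterministic given the seed.
#' @param avoid optional `mask_volume` of lesions already placed for other
#'   tracts, honoured by the separation constraint.
#' @return `list(wmh_mask, truth)`; `truth` is a list of
#'   `list(type, gap_steps, voxels)` with voxels as linear indices.
#' @export
place_lesions <- function(tract_mask, nawm_extent, plan, seed, avoid = NULL) {
  stopifnot(inherits(tract_mask, "mask_volume"),
            inherits(nawm_extent, "mask_volume"))
  if (mask_count(tract_mask) == 0L) stop("tract mask is empty")
  grid <- assert_common_grid(list(tract = tract_mask, extent = nawm_extent))
  shape <- grid$shape
  vox <- grid$voxel_size_mm[1L]
  set.seed(seed)

  sep <- plan$min_separation_vox
  domain <- nawm_extent$data
  tract <- tract_mask$data
  tract_idx <- which(tract)
  tract_coords <- which(tract, arr.ind = TRUE)
  placed_coords <- list()                   # lesions to keep separated from
  if (!is.null(avoid) && mask_count(avoid) > 0L) {
    placed_coords[[1L]] <- which(avoid$data, arr.ind = TRUE)
  }
  wmh <- array(FALSE, shape)
  truth <- list()

  separated <- function(lesion_coords) {
    for (pc in placed_coords) {
      if (min_cheby_between(lesion_coords, pc) < sep) return(FALSE)
    }
    TRUE
  }
  add_lesion <- function(lesion, lesion_coords, type, gap_steps) {
    wmh <<- wmh | lesion
    placed_coords[[length(placed_coords) + 1L]] <<- lesion_coords
    truth[[length(truth) + 1L]] <<- list(type = type, gap_steps = gap_steps,
                                         voxels = which(lesion))
  }
  draw_axes <- function() {
    stats::runif(3L, plan$semi_axes_range_mm[1L],
                 plan$semi_axes_range_mm[2L]) / vox
  }

  for (j in seq_len(plan$n_intersecting)) {
    placed <- FALSE
    for (att in seq_len(plan$max_attempts)) {
      center <- arrayInd(sample(tract_idx, 1L), shape)[1L, ]
      lesion <- ellipsoid_voxels(center, draw_axes(), shape)
      if (!any(lesion)) next
      if (any(lesion & !domain)) next
      if (!any(lesion & tract)) next
      # contained in the tract: keeps shell distance (grown from
      # tract-WMH) identical to the planted distance (from the whole
      # lesion), so zero-noise recovery is exact
      if (plan$contain_intersecting && any(lesion & !tract)) next
      lc <- which(lesion, arr.ind = TRUE)
      if (!separated(lc)) next
      add_lesion(lesion, lc, "intersecting", NA_real_)
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf(
        "lesion placement failed: could not place intersecting lesion %d within the brain extent / separation constraints after %d attempts",
        j, plan$max_attempts))
  }

  gap_lo <- max(1L, ceiling(plan$nearby_gap_range_mm[1L] / vox))
  gap_hi <- max(gap_lo, floor(plan$nearby_gap_range_mm[2L] / vox))
  surface <- tract & dilate_binary(!tract, 26)
  surf_idx <- which(surface)
  dirs <- rbind(c(0, 0, 1), c(0, 0, -1), c(0, 1, 0), c(0, -1, 0))
  for (j in seq_len(plan$n_nearby)) {
    placed <- FALSE
    for (att in seq_len(plan$max_attempts)) {
      anchor <- arrayInd(sample(surf_idx, 1L), shape)[1L, ]
      g <- sample(gap_lo:gap_hi, 1L)
      dir <- dirs[sample(nrow(dirs), 1L), ]
      axes <- draw_axes()
      off <- g + ceiling(sum(abs(dir) * axes))
      center <- anchor + dir * off
      if (any(center < 1) || any(center > shape)) next
      lesion <- ellipsoid_voxels(center, axes, shape)
      if (!any(lesion)) next
      if (any(lesion & !domain)) next
      lc <- which(lesion, arr.ind = TRUE)
      gap <- min_cheby_between(lc, tract_coords)
      if (!is.finite(gap) || gap < gap_lo || gap > gap_hi) next
      if (!separated(lc)) next
      add_lesion(lesion, lc, "nearby", gap)
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf(
        "lesion placement failed: could not place nearby lesion %d with gap in [%d, %d] voxels under the separation constraints after %d attempts",
        j, gap_lo, gap_hi, plan$max_attempts))
  }
  list(wmh_mask = mask_volume(wmh, grid), truth = truth)
}

#' Synthesize FA and MD maps with a planted penumbra gradient
#'
#' See the module header for the planted model. The distance field is the
#' Chebyshev voxel distance to the nearest WMH voxel (times the voxel
#' size), capped at 10 mm; inside WMH the expected outcome is `beta0` (plus
#' any intercept random effects). Voxels whose nearest lesion is a nearby
#' (non-intersecting) one additionally receive the nearby offset and slope
#' delta; ties go to the intersecting lesion. A `csf_fraction` of the
#' brain-border rim (outside NAWM and WMH) receives CSF-like MD above
#' 1e-3 mm^2/s. FA is clipped to \[0,1\], MD to >= 0.
#'
#' @param wmh_mask,nawm_mask `mask_volume`s on one grid (disjoint).
#' @param truth lesion list from [place_lesions()] (possibly concatenated
#'   over tracts), used to split the distance field by lesion type.
#' @param params list with `gradient_params`, `noise_sd`, `csf_fraction`
#'   (as in [phantom_config()]) plus `participant_effects` and
#'   `tract_effects` (realized draws: per outcome, `c(intercept, slope)`;
#'   tract effects as a named list keyed by tract name) and `tract_masks`
#'   (named list of `mask_volume`s for assigning tract effects; voxels in
#'   several tracts take the first, in list order).
#' @param seed integer; maps are bit-identical given identical inputs.
#' @param max_steps distance cap in dilation steps (default 5 = 10 mm).
#' @return `list(fa = scalar_volume, md = scalar_volume)`.
#' @export
synthesize_maps <- function(wmh_mask, nawm_mask, truth, params, seed,
                            max_steps = 5L) {
  grid <- assert_common_grid(list(wmh = wmh_mask, nawm = nawm_mask))
  shape <- grid$shape
  vox <- grid$voxel_size_mm[1L]
  wmh <- wmh_mask$data
  nawm <- nawm_mask$data
  if (any(wmh & nawm)) stop("WMH and NAWM masks overlap")
  domain <- wmh | nawm
  set.seed(seed)

  types <- vapply(truth, function(l) l$type, character(1))
  seed_of <- function(keep) {
    m <- array(FALSE, shape)
    for (l in truth[keep]) m[l$voxels] <- TRUE
    m
  }
  steps_int <- chebyshev_steps(seed_of(types == "intersecting"), max_steps)
  steps_near <- chebyshev_steps(seed_of(types == "nearby"), max_steps)
  steps <- pmin(steps_int, steps_near)
  nearest_nearby <- (steps_near < steps_int) & !wmh
  d_mm <- pmin(steps, max_steps) * vox
  logd <- log(d_mm + 1)

  gp <- params$gradient_params
  pe <- params$participant_effects
  te <- params$tract_effects
  tract_masks <- params$tract_masks

  synth_one <- function(outcome) {
    if (outcome == "fa") {
      b0 <- gp$fa_at_wmh; b1 <- gp$fa_slope
      off <- gp$nearby_offset_fa; sdel <- gp$fa_nearby_slope_delta
      asym <- gp$fa_asymptote
    } else {
      b0 <- gp$md_at_wmh; b1 <- gp$md_slope
      off <- gp$nearby_offset_md; sdel <- gp$md_nearby_slope_delta
      asym <- gp$md_asymptote
    }
    mu <- b0 + b1 * logd
    mu <- if (b1 >= 0) pmin(mu, asym) else pmax(mu, asym)
    mu <- mu + nearest_nearby * (off + sdel * logd)
    if (!is.null(pe)) {
      mu <- mu + pe[[outcome]][1L] + pe[[outcome]][2L] * logd
    }
    if (!is.null(te) && length(te) > 0L) {
      assigned <- array(FALSE, shape)
      for (tn in names(tract_masks)) {
        sel <- tract_masks[[tn]]$data & !assigned
        eff <- te[[tn]][[outcome]]
        mu[sel] <- mu[sel] + eff[1L] + eff[2L] * logd[sel]
        assigned <- assigned | tract_masks[[tn]]$data
      }
    }
    mu
  }

  border <- dilate_binary(domain, 26) & !domain
  border_idx <- which(border)
  n_csf <- round(params$csf_fraction * length(border_idx))
  csf_idx <- if (n_csf > 0L) sample(border_idx, n_csf) else integer()

  fa <- synth_one("fa")
  md <- synth_one("md")
  if (params$noise_sd$fa > 0)
    fa <- fa + array(stats::rnorm(prod(shape), 0, params$noise_sd$fa), shape)
  if (params$noise_sd$md > 0)
    md <- md + array(stats::rnorm(prod(shape), 0, params$noise_sd$md), shape)
  fa[!domain] <- 0
  md[!domain] <- 0
  if (length(csf_idx) > 0L) {
    md[csf_idx] <- stats::runif(length(csf_idx), 1.05e-3, 2.5e-3)
    fa[csf_idx] <- stats::runif(length(csf_idx), 0, 0.15)
  }
  fa <- pmin(pmax(fa, 0), 1)
  md <- pmax(md, 0)
  list(fa = scalar_volume(fa, grid), md = scalar_volume(md, grid))
}

#' Simulate a phantom cohort in memory
#'
#' Draws tract-level random effects once for the cohort and participant
#' effects per participant (crossed, not nested), places lesions per tract
#' with cross-tract separation, and synthesizes FA/MD maps. The result is a
#' pure function of the configuration.
#'
#' @param config a [phantom_config()].
#' @return `list(config, grid, tract_probs, tract_masks, participants,
#'   truth)`; `participants` is a list of
#'   `list(id, wmh_mask, nawm_mask, fa, md)`, `truth` a per-participant
#'   list of lesion entries (with tract and type), plus the realized
#'   random-effect draws.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  grid <- volume_grid(config$grid_shape, config$voxel_size_mm)
  shape <- grid$shape

  tract_probs <- list()
  tract_masks <- list()
  for (spec in config$tract_specs) {
    pm <- make_tract_probability_map(spec, grid)
    tract_probs[[spec$name]] <- pm
    tract_masks[[spec$name]] <- binarize_tract(pm, 0.01)
  }

  m <- config$brain_margin_vox
  domain <- array(FALSE, shape)
  domain[(m + 1L):(shape[1L] - m), (m + 1L):(shape[2L] - m),
         (m + 1L):(shape[3L] - m)] <- TRUE
  for (tn in names(tract_masks)) {
    if (any(tract_masks[[tn]]$data & !domain))
      stop(sprintf("tract '%s' extends outside the brain extent", tn))
  }
  domain_mask <- mask_volume(domain, grid)

  set.seed(derive_seed(config$seed, 1))
  re <- config$random_effects
  tract_effects <- list()
  for (tn in names(tract_masks)) {
    tract_effects[[tn]] <- list(
      fa = c(stats::rnorm(1, 0, re$fa$sd_tract_intercept),
             stats::rnorm(1, 0, re$fa$sd_tract_slope)),
      md = c(stats::rnorm(1, 0, re$md$sd_tract_intercept),
             stats::rnorm(1, 0, re$md$sd_tract_slope)))
  }
  participant_effects <- lapply(seq_len(config$n_participants), function(i) {
    list(fa = c(stats::rnorm(1, 0, re$fa$sd_participant_intercept),
                stats::rnorm(1, 0, re$fa$sd_participant_slope)),
         md = c(stats::rnorm(1, 0, re$md$sd_participant_intercept),
                stats::rnorm(1, 0, re$md$sd_participant_slope)))
  })

  participants <- list()
  truth_all <- list()
  for (i in seq_len(config$n_participants)) {
    pid <- sprintf("participant_%02d", i)
    wmh <- array(FALSE, shape)
    placed <- NULL
    truth_i <- list()
    for (t in seq_along(config$tract_specs)) {
      tn <- config$tract_specs[[t]]$name
      pl <- place_lesions(tract_masks[[tn]], domain_mask, config$lesion_plan,
                          seed = derive_seed(config$seed, 2, i, t),
                          avoid = placed)
      wmh <- wmh | pl$wmh_mask$data
      placed <- mask_volume(wmh, grid)
      for (l in pl$truth) {
        l$tract <- tn
        truth_i[[length(truth_i) + 1L]] <- l
      }
    }
    nawm <- mask_volume(domain & !wmh, grid)
    wmh_m <- mask_volume(wmh, grid)
    maps <- synthesize_maps(
      wmh_m, nawm, truth_i,
      params = list(gradient_params = config$gradient_params,
                    noise_sd = config$noise_sd,
                    csf_fraction = config$csf_fraction,
                    participant_effects = participant_effects[[i]],
                    tract_effects = tract_effects,
                    tract_masks = tract_masks),
      seed = derive_seed(config$seed, 3, i))
    participants[[pid]] <- list(id = pid, wmh_mask = wmh_m, nawm_mask = nawm,
                                fa = maps$fa, md = maps$md)
    truth_all[[pid]] <- truth_i
  }
  list(config = config, grid = grid, tract_probs = tract_probs,
       tract_masks = tract_masks, participants = participants,
       truth = list(lesions = truth_all,
                    participant_effects = participant_effects,
                    tract_effects = tract_effects,
                    seed = config$seed))
}

truth_to_json <- function(truth, config) {
  lesions <- lapply(truth$lesions, function(pl) {
    lapply(pl, function(l) {
      list(tract = l$tract, type = l$type,
           gap_steps = if (is.na(l$gap_steps)) NULL else l$gap_steps,
           voxels = as.integer(l$voxels))
    })
  })
  list(
    seed = config$seed,
    grid_shape = config$grid_shape,
    voxel_size_mm = config$voxel_size_mm,
    gradient_params = config$gradient_params,
    random_effects = config$random_effects,
    noise_sd = config$noise_sd,
    participant_effects = truth$participant_effects,
    tract_effects = truth$tract_effects,
    lesions = lesions
  )
}

#' Generate a phantom cohort on disk
#'
#' Writes one directory per participant containing
#' `tract_<name>.nii.gz` (posterior-probability maps), `wmh_mask.nii.gz`,
#' `nawm_mask.nii.gz`, `fa.nii.gz`, `md.nii.gz`, plus a shared
#' `ground_truth.json` ledger with the planted parameters, realized
#' random-effect draws and lesion voxel sets. Regenerating with the same
#' configuration is byte-identical.
#'
#' @param config a [phantom_config()].
#' @param out_dir output directory (created if missing).
#' @return The in-memory cohort from [simulate_cohort()], invisibly.
#' @export
generate_cohort <- function(config, out_dir) {
  cohort <- simulate_cohort(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (pid in names(cohort$participants)) {
    p <- cohort$participants[[pid]]
    pdir <- file.path(out_dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    for (tn in names(cohort$tract_probs)) {
      write_volume(cohort$tract_probs[[tn]],
                   file.path(pdir, sprintf("tract_%s.nii.gz", tn)))
    }
    write_volume(p$wmh_mask, file.path(pdir, "wmh_mask.nii.gz"))
    write_volume(p$nawm_mask, file.path(pdir, "nawm_mask.nii.gz"))
    write_volume(p$fa, file.path(pdir, "fa.nii.gz"))
    write_volume(p$md, file.path(pdir, "md.nii.gz"))
  }
  jsonlite::write_json(truth_to_json(cohort$truth, config),
                       file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cohort)
}

#' Load a cohort directory written by [generate_cohort()]
#'
#' Reads each participant bundle back into the in-memory layout consumed by
#' [assemble_table()]. Tract names are taken from the `tract_*.nii(.gz)`
#' file names.
#'
#' @param dir cohort directory.
#' @param tract_threshold binarization threshold for the tract maps.
#' @return `list(tract_masks, participants)` as in [simulate_cohort()].
#' @export
load_cohort <- function(dir, tract_threshold = 0.01) {
  if (!dir.exists(dir)) stop(sprintf("cohort directory '%s' does not exist", dir))
  pdirs <- sort(list.dirs(dir, recursive = FALSE))
  if (length(pdirs) == 0L) stop(sprintf("no participant directories in '%s'", dir))
  participants <- list()
  tract_masks <- NULL
  for (pdir in pdirs) {
    pid <- basename(pdir)
    tfiles <- sort(list.files(pdir, pattern = "^tract_.*\\.nii(\\.gz)?$",
                              full.names = TRUE))
    tm <- list()
    for (tf in tfiles) {
      tn <- sub("^tract_", "", sub("\\.nii(\\.gz)?$", "", basename(tf)))
      tm[[tn]] <- binarize_tract(read_volume(tf, "probability"),
                                 tract_threshold)
    }
    find1 <- function(stem) {
      for (ext in c(".nii.gz", ".nii")) {
        f <- file.path(pdir, paste0(stem, ext))
        if (file.exists(f)) return(f)
      }
      stop(sprintf("participant '%s': missing %s volume", pid, stem))
    }
    participants[[pid]] <- list(
      id = pid,
      tract_masks = tm,
      wmh_mask = read_volume(find1("wmh_mask"), "mask"),
      nawm_mask = read_volume(find1("nawm_mask"), "mask"),
      fa = read_volume(find1("fa"), "scalar"),
      md = read_volume(find1("md"), "scalar"))
    if (is.null(tract_masks)) tract_masks <- tm
  }
  list(tract_masks = tract_masks, participants = participants)
}
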