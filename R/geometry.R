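# Tract-lesion geometry: tract binarization, WMH/NAWM partition, distance
# shells around tract-intersecting WMH, and nearby (non-intersecting) WMH
# handling with the contour exclusion rules.

#' Binarize a tract posterior-probability map
#'
#' Voxels with posterior probability strictly greater than the threshold
#' (default 1%) become tract voxels. The comparison is strict: a voxel at
#' exactly the threshold is background.
#'
#' @param prob_map a `scalar_volume` with values in \[0,1\].
#' @param threshold probability threshold in (0,1); default 0.01.
#' @return A `mask_volume`.
#' @export
binarize_tract <- function(prob_map, threshold = 0.01) {
  stopifnot(inherits(prob_map, "scalar_volume"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("`threshold` must be a single value in (0, 1)")
  rng <- range(prob_map$data, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 1)
    stop(sprintf("probability map has values in [%g, %g], outside [0, 1]",
                 rng[1L], rng[2L]))
  d <- prob_map$data > threshold
  d[is.na(d)] <- FALSE
  mask_volume(d, prob_map$grid)
}

#' Partition a tract against the WMH and NAWM masks
#'
#' Splits a tract mask into its intersection with the whole-brain WMH mask
#' (tract-WMH) and with the NAWM mask (tract-NAWM), and computes the
#' percentage of lesioned tract volume,
#' `%WMHvol = 100 * |tract-WMH| / (|tract-WMH| + |tract-NAWM|)`.
#' Tract voxels in neither mask (e.g. CSF-adjacent) belong to neither part.
#' If the tract meets neither mask, `pct_wmh_vol` is `NA`.
#'
#' @param tract_mask,wmh_mask,nawm_mask `mask_volume`s on one grid.
#' @param tract_name identifier carried into downstream records.
#' @return A `tract_partition` object with fields `tract_name`,
#'   `tract_mask`, `tract_wmh`, `tract_nawm`, `pct_wmh_vol`.
#' @export
partition_tract <- function(tract_mask, wmh_mask, nawm_mask,
                            tract_name = "tract") {
  grid <- assert_common_grid(list(tract = tract_mask, wmh = wmh_mask,
                                  nawm = nawm_mask))
  tw <- tract_mask$data & wmh_mask$data
  tn <- tract_mask$data & nawm_mask$data
  n_tw <- sum(tw)
  n_tn <- sum(tn)
  pct <- if (n_tw + n_tn > 0L) 100 * n_tw / (n_tw + n_tn) else NA_real_
  structure(
    list(tract_name = tract_name,
         tract_mask = tract_mask,
         tract_wmh = mask_volume(tw, grid),
         tract_nawm = mask_volume(tn, grid),
         pct_wmh_vol = pct),
    class = "tract_partition"
  )
}

#' @export
print.tract_partition <- function(x, ...) {
  cat(sprintf("<tract_partition '%s': |tract|=%d, |tract-WMH|=%d, |tract-NAWM|=%d, %%WMHvol=%s>\n",
              x$tract_name, mask_count(x$tract_mask), mask_count(x$tract_wmh),
              mask_count(x$tract_nawm),
              if (is.na(x$pct_wmh_vol)) "NA" else
                sprintf("%.2f%%", x$pct_wmh_vol)))
  invisible(x)
}

new_shell_set <- function(source_type, seed_mask, shells) {
  structure(list(source_type = source_type, seed_mask = seed_mask,
                 shells = shells),
            class = "shell_set")
}

# Core shell construction: shell k = (dil^k(seed) \ dil^{k-1}(seed))
# restricted to `restrict`, minus `exclude`.
build_shells_core <- function(seed, restrict, exclude, n_shells, step_mm,
                              connectivity, grid, source_type,
                              allow_anisotropic = FALSE) {
  if (!grid_is_isotropic(grid) && !allow_anisotropic)
    stop("shell construction requires an isotropic grid (or allow_anisotropic = TRUE)")
  step <- if (grid_is_isotropic(grid)) grid$voxel_size_mm[1L] else
    max(grid$voxel_size_mm[1:2])
  if (abs(step - step_mm) > 1e-3)
    warning(sprintf("voxel size %.4g mm differs from nominal shell step %.4g mm; distances are labelled in voxel steps x %.4g mm",
                    step, step_mm, step_mm))
  shells <- vector("list", n_shells)
  bb <- mask_bbox(seed, n_shells + 1L)    # dilations cannot escape this box
  if (is.null(bb)) {
    empty <- mask_volume(array(FALSE, grid$shape), grid)
    for (k in seq_len(n_shells)) {
      shells[[k]] <- list(distance_mm = k * step_mm, mask = empty)
    }
    return(new_shell_set(source_type, mask_volume(seed, grid), shells))
  }
  prev <- crop_bbox(seed, bb)
  restrict_c <- crop_bbox(restrict, bb)
  exclude_c <- if (is.null(exclude)) NULL else crop_bbox(exclude, bb)
  blank <- array(FALSE, grid$shape)
  for (k in seq_len(n_shells)) {
    cur <- dilate_binary(prev, connectivity)
    shell <- cur & !prev & restrict_c
    if (!is.null(exclude_c)) shell <- shell & !exclude_c
    shells[[k]] <- list(distance_mm = k * step_mm,
                        mask = mask_volume(paste_bbox(blank, shell, bb), grid))
    prev <- cur
  }
  new_shell_set(source_type, mask_volume(seed, grid), shells)
}

#' Build distance shells around the tract-WMH
#'
#' The tract-WMH mask is dilated one voxel (2 mm) at a time; each dilation
#' minus the previous one is a contour at about `2k` mm from the lesion
#' edge, and only its voxels inside the tract-NAWM are kept. An empty
#' tract-WMH yields a shell set whose shells are all empty, flagged
#' `no_lesion`.
#'
#' @param partition a `tract_partition`.
#' @param n_shells number of shells (default 5, i.e. 2--10 mm).
#' @param connectivity structuring element: 26 (default), 18 or 6.
#' @param step_mm nominal shell step in mm (default 2).
#' @param allow_anisotropic override the isotropic-grid requirement.
#' @return A `shell_set` with `source_type = "tract_wmh"`; shells are
#'   pairwise disjoint, contained in the tract-NAWM, and never intersect
#'   the seed.
#' @export
build_tract_wmh_shells <- function(partition, n_shells = 5, connectivity = 26,
                                   step_mm = 2, allow_anisotropic = FALSE) {
  stopifnot(inherits(partition, "tract_partition"))
  grid <- partition$tract_wmh$grid
  ss <- build_shells_core(partition$tract_wmh$data,
                          partition$tract_nawm$data,
                          exclude = NULL,
                          n_shells = n_shells, step_mm = step_mm,
                          connectivity = connectivity, grid = grid,
                          source_type = "tract_wmh",
                          allow_anisotropic = allow_anisotropic)
  ss$no_lesion <- mask_count(partition$tract_wmh) == 0L
  ss
}

#' Identify nearby (non-intersecting) WMH components for a tract
#'
#' A nearby-WMH is a connected component of the whole-brain WMH mask that
#' shares no voxel with the tract but whose 2--10 mm contours can reach the
#' tract's NAWM (operationally: its `n_shells`-step dilation intersects the
#' tract-NAWM). A component sharing even one voxel with the tract is
#' intersecting, never nearby; the same physical lesion may be nearby for
#' one tract and intersecting for another.
#'
#' @param wmh_mask whole-brain WMH `mask_volume`.
#' @param partition the tract's `tract_partition` (supplies both the tract
#'   mask for the disjointness test and the tract-NAWM for eligibility).
#' @param component_connectivity connectivity for component labelling
#'   (default 26).
#' @param n_shells reach of the eligibility dilation (default 5 steps).
#' @param connectivity structuring element for the eligibility dilation.
#' @param labels optional precomputed label array from an earlier call
#'   (performance; must come from the same `wmh_mask`).
#' @return List of `mask_volume`s, one per eligible component, ordered by
#'   component centroid (lexicographic voxel order).
#' @export
find_nearby_wmh <- function(wmh_mask, partition, component_connectivity = 26,
                            n_shells = 5, connectivity = 26, labels = NULL) {
  stopifnot(inherits(wmh_mask, "mask_volume"),
            inherits(partition, "tract_partition"))
  assert_common_grid(list(wmh = wmh_mask, tract = partition$tract_mask))
  if (is.null(labels)) {
    labels <- label_components(wmh_mask$data, component_connectivity)
  }
  k <- max(labels)
  out <- list()
  if (k == 0L) return(out)
  tract <- partition$tract_mask$data
  nawm <- partition$tract_nawm$data
  for (i in seq_len(k)) {
    comp <- labels == i
    if (any(comp & tract)) next              # intersecting, not nearby
    bb <- mask_bbox(comp, n_shells)
    reach <- crop_bbox(comp, bb)
    nawm_c <- crop_bbox(nawm, bb)
    hit <- FALSE
    for (s in seq_len(n_shells)) {
      reach <- dilate_binary(reach, connectivity)
      if (any(reach & nawm_c)) { hit <- TRUE; break }
    }
    if (hit) out[[length(out) + 1L]] <- mask_volume(comp, wmh_mask$grid)
  }
  out
}

#' Build distance shells around a nearby-WMH component
#'
#' Same construction as [build_tract_wmh_shells()] but seeded from one
#' nearby lesion component, and with every voxel already belonging to a
#' tract-WMH contour excluded, so the measured regions are never connected
#' to an intersecting lesion. The lesion itself is never measured (there is
#' no distance-0 entry for nearby lesions).
#'
#' @param nearby_component one component from [find_nearby_wmh()].
#' @param partition the tract's `tract_partition`.
#' @param tract_wmh_shell_union `mask_volume` union of all tract-WMH shells
#'   for the same tract, or NULL when the tract has no intersecting lesion.
#' @inheritParams build_tract_wmh_shells
#' @return A `shell_set` with `source_type = "nearby"`.
#' @export
build_nearby_shells <- function(nearby_component, partition,
                                tract_wmh_shell_union = NULL,
                                n_shells = 5, connectivity = 26, step_mm = 2,
                                allow_anisotropic = FALSE) {
  stopifnot(inherits(nearby_component, "mask_volume"),
            inherits(partition, "tract_partition"))
  grid <- nearby_component$grid
  exclude <- if (is.null(tract_wmh_shell_union)) NULL else
    tract_wmh_shell_union$data
  build_shells_core(nearby_component$data,
                    partition$tract_nawm$data,
                    exclude = exclude,
                    n_shells = n_shells, step_mm = step_mm,
                    connectivity = connectivity, grid = grid,
                    source_type = "nearby",
                    allow_anisotropic = allow_anisotropic)
}

#' Union of the shells in a shell set
#' @param shell_set a `shell_set`.
#' @return A `mask_volume` equal to the union of all shell masks.
#' @export
shell_union <- function(shell_set) {
  stopifnot(inherits(shell_set, "shell_set"))
  grid <- shell_set$seed_mask$grid
  u <- array(FALSE, dim = grid$shape)
  for (sh in shell_set$shells) u <- u | sh$mask$data
  mask_volume(u, grid)
}

#' Tract partition summary for a cohort
#'
#' One row per participant x tract with the voxel counts and %WMHvol;
#' the geometry-stage QC table.
#'
#' @param cohort as in [assemble_table()].
#' @param options a [geometry_options()] list.
#' @return data.frame (participant, tract, n_tract, n_tract_wmh,
#'   n_tract_nawm, pct_wmh_vol).
#' @export
partition_summary <- function(cohort, options = geometry_options()) {
  rows <- list()
  for (pid in names(cohort$participants)) {
    p <- cohort$participants[[pid]]
    tm <- if (is.null(p$tract_masks)) cohort$tract_masks else p$tract_masks
    for (tn in names(tm)) {
      part <- partition_tract(tm[[tn]], p$wmh_mask, p$nawm_mask, tn)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p$id, tract = tn,
        n_tract = mask_count(part$tract_mask),
        n_tract_wmh = mask_count(part$tract_wmh),
        n_tract_nawm = mask_count(part$tract_nawm),
        pct_wmh_vol = part$pct_wmh_vol, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(data.frame())
  do.call(rbind, rows)
}

#' Write labelled shell volumes for visual QC
#'
#' For each participant and tract, writes one NIfTI in which tract-WMH
#' shell k carries label k and nearby shells (all components pooled)
#' carry label 10 + k; the tract-WMH seed itself is label -1.
#'
#' @param cohort as in [assemble_table()].
#' @param out_dir output directory (one file per participant x tract).
#' @param options a [geometry_options()] list.
#' @return Invisible vector of written paths.
#' @export
save_shell_qc <- function(cohort, out_dir, options = geometry_options()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  for (pid in names(cohort$participants)) {
    p <- cohort$participants[[pid]]
    tm <- if (is.null(p$tract_masks)) cohort$tract_masks else p$tract_masks
    labels <- label_components(p$wmh_mask$data,
                               options$component_connectivity)
    for (tn in names(tm)) {
      part <- partition_tract(tm[[tn]], p$wmh_mask, p$nawm_mask, tn)
      lab <- array(0, dim = part$tract_mask$grid$shape)
      tw_union <- NULL
      if (mask_count(part$tract_wmh) > 0L) {
        ss <- build_tract_wmh_shells(part, n_shells = options$n_shells,
                                     connectivity = options$dilation_connectivity,
                                     step_mm = options$shell_step_mm)
        tw_union <- shell_union(ss)
        lab[part$tract_wmh$data] <- -1
        for (k in seq_along(ss$shells))
          lab[ss$shells[[k]]$mask$data] <- k
      }
      comps <- find_nearby_wmh(p$wmh_mask, part,
                               component_connectivity = options$component_connectivity,
                               n_shells = options$n_shells,
                               connectivity = options$dilation_connectivity,
                               labels = labels)
      for (comp in comps) {
        ns <- build_nearby_shells(comp, part, tw_union,
                                  n_shells = options$n_shells,
                                  connectivity = options$dilation_connectivity,
                                  step_mm = options$shell_step_mm)
        for (k in seq_along(ns$shells))
          lab[ns$shells[[k]]$mask$data] <- 10 + k
      }
      f <- file.path(out_dir, sprintf("%s_%s_shells.nii.gz", p$id, tn))
      write_volume(scalar_volume(lab, part$tract_mask$grid), f)
      written <- c(written, f)
    }
  }
  invisible(written)
}
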