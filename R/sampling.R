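# Shell sampling: turn geometry + FA/MD maps into the long analysis table.

#' Mean of a scalar map over a mask region
#'
#' @param region a `mask_volume`.
#' @param scalar a `scalar_volume` on the same grid.
#' @return `list(mean, n_voxels)`; `mean` is `NA` when the region is empty.
#'   A non-finite scalar value inside the region is an error naming the
#'   offending voxel.
#' @export
shell_mean <- function(region, scalar) {
  assert_common_grid(list(region = region, scalar = scalar))
  idx <- which(region$data)
  if (length(idx) == 0L) return(list(mean = NA_real_, n_voxels = 0L))
  vals <- scalar$data[idx]
  bad <- which(!is.finite(vals))
  if (length(bad) > 0L) {
    v <- arrayInd(idx[bad[1L]], region$grid$shape)[1L, ]
    stop(sprintf("non-finite scalar value at voxel (%d, %d, %d) inside region",
                 v[1L], v[2L], v[3L]))
  }
  list(mean = mean(vals), n_voxels = length(idx))
}

shell_record <- function(participant, tract, wmh_type, distance_mm,
                         n_voxels, mean_fa, mean_md) {
  data.frame(participant = participant, tract = tract, wmh_type = wmh_type,
             distance_mm = distance_mm, n_voxels = as.integer(n_voxels),
             mean_fa = mean_fa, mean_md = mean_md, excluded_csf = FALSE,
             stringsAsFactors = FALSE)
}

# Geometry + sampling for one participant. Components of the WMH mask are
# labelled once and reused across tracts. Per-tract, per-distance nearby
# shells from different components are pooled by voxel-count-weighted mean
# (the per-component table is available via `per_component = TRUE`).
analyze_participant <- function(participant, options = geometry_options()) {
  tract_masks <- participant$tract_masks
  wmh <- participant$wmh_mask
  nawm <- participant$nawm_mask
  fa <- participant$fa
  md <- participant$md
  assert_common_grid(c(list(wmh = wmh, nawm = nawm, fa = fa, md = md),
                       tract_masks))
  labels <- label_components(wmh$data, options$component_connectivity)
  recs <- list()
  comp_recs <- list()
  for (tn in names(tract_masks)) {
    part <- partition_tract(tract_masks[[tn]], wmh, nawm, tract_name = tn)
    has_lesion <- mask_count(part$tract_wmh) > 0L
    tw_union <- NULL
    if (has_lesion) {
      ss <- build_tract_wmh_shells(part, n_shells = options$n_shells,
                                   connectivity = options$dilation_connectivity,
                                   step_mm = options$shell_step_mm,
                                   allow_anisotropic = options$allow_anisotropic)
      tw_union <- shell_union(ss)
      m0f <- shell_mean(part$tract_wmh, fa)
      m0m <- shell_mean(part$tract_wmh, md)
      recs[[length(recs) + 1L]] <- shell_record(
        participant$id, tn, "tract_wmh", 0, m0f$n_voxels, m0f$mean, m0m$mean)
      for (sh in ss$shells) {
        mf <- shell_mean(sh$mask, fa)
        mm <- shell_mean(sh$mask, md)
        recs[[length(recs) + 1L]] <- shell_record(
          participant$id, tn, "tract_wmh", sh$distance_mm,
          mf$n_voxels, mf$mean, mm$mean)
      }
    }
    comps <- find_nearby_wmh(wmh, part,
                             component_connectivity = options$component_connectivity,
                             n_shells = options$n_shells,
                             connectivity = options$dilation_connectivity,
                             labels = labels)
    if (length(comps) > 0L) {
      dists <- options$shell_step_mm * seq_len(options$n_shells)
      acc_n <- stats::setNames(numeric(length(dists)), dists)
      acc_fa <- acc_md <- stats::setNames(rep(0, length(dists)), dists)
      for (ci in seq_along(comps)) {
        ns <- build_nearby_shells(comps[[ci]], part, tw_union,
                                  n_shells = options$n_shells,
                                  connectivity = options$dilation_connectivity,
                                  step_mm = options$shell_step_mm,
                                  allow_anisotropic = options$allow_anisotropic)
        for (sh in ns$shells) {
          mf <- shell_mean(sh$mask, fa)
          mm <- shell_mean(sh$mask, md)
          key <- as.character(sh$distance_mm)
          if (mf$n_voxels > 0L) {
            acc_n[key] <- acc_n[key] + mf$n_voxels
            acc_fa[key] <- acc_fa[key] + mf$n_voxels * mf$mean
            acc_md[key] <- acc_md[key] + mf$n_voxels * mm$mean
          }
          comp_recs[[length(comp_recs) + 1L]] <- data.frame(
            participant = participant$id, tract = tn, component = ci,
            distance_mm = sh$distance_mm, n_voxels = mf$n_voxels,
            mean_fa = mf$mean, mean_md = mm$mean, stringsAsFactors = FALSE)
        }
      }
      for (di in seq_along(dists)) {
        n <- acc_n[di]
        recs[[length(recs) + 1L]] <- shell_record(
          participant$id, tn, "nearby", dists[di], n,
          if (n > 0) acc_fa[di] / n else NA_real_,
          if (n > 0) acc_md[di] / n else NA_real_)
      }
    }
  }
  records <- if (length(recs) > 0L) do.call(rbind, recs) else empty_records()
  attr(records, "per_component") <-
    if (length(comp_recs) > 0L) do.call(rbind, comp_recs) else NULL
  records
}

#' Geometry/sampling options
#'
#' @param shell_step_mm nominal shell step (default 2 mm).
#' @param n_shells number of shells (default 5, distances 2--10 mm).
#' @param dilation_connectivity structuring element for dilations
#'   (default 26).
#' @param component_connectivity connectivity for WMH component labelling
#'   (default 26).
#' @param tract_threshold tract-probability binarization threshold.
#' @param allow_anisotropic allow anisotropic grids (see [dilate_step()]).
#' @return Options list.
#' @export
geometry_options <- function(shell_step_mm = 2, n_shells = 5,
                             dilation_connectivity = 26,
                             component_connectivity = 26,
                             tract_threshold = 0.01,
                             allow_anisotropic = FALSE) {
  list(shell_step_mm = shell_step_mm, n_shells = n_shells,
       dilation_connectivity = dilation_connectivity,
       component_connectivity = component_connectivity,
       tract_threshold = tract_threshold,
       allow_anisotropic = allow_anisotropic)
}

#' Assemble the long-format shell table for a cohort
#'
#' One record per participant x tract x WMH type x distance:
#' distances 0 (the tract-WMH region itself), 2, ..., 10 mm for tracts with
#' an intersecting lesion, and 2, ..., 10 mm for tracts with at least one
#' eligible nearby lesion (nearby lesions are never measured at distance
#' 0). Empty shells are retained with `n_voxels = 0` and missing means;
#' the model stage drops them. Rows are ordered by (participant, tract,
#' type, distance), with `tract_wmh` before `nearby`.
#'
#' @param cohort list with `participants`, each
#'   `list(id, tract_masks, wmh_mask, nawm_mask, fa, md)` (as produced by
#'   [simulate_cohort()] -- whose shared `tract_masks` are injected
#'   automatically -- or [load_cohort()]).
#' @param options a [geometry_options()] list.
#' @return Shell-record data.frame; the per-component nearby table is
#'   attached as attribute `"per_component"`.
#' @export
assemble_table <- function(cohort, options = geometry_options()) {
  parts <- cohort$participants
  out <- list()
  comp <- list()
  for (pid in names(parts)) {
    p <- parts[[pid]]
    if (is.null(p$tract_masks)) p$tract_masks <- cohort$tract_masks
    r <- analyze_participant(p, options)
    pc <- attr(r, "per_component")
    if (!is.null(pc)) comp[[length(comp) + 1L]] <- pc
    out[[length(out) + 1L]] <- r
  }
  records <- if (length(out) > 0L) do.call(rbind, out) else empty_records()
  if (nrow(records) > 0L) {
    type_rank <- match(records$wmh_type, c("tract_wmh", "nearby"))
    ord <- order(records$participant, records$tract, type_rank,
                 records$distance_mm)
    records <- records[ord, , drop = FALSE]
    rownames(records) <- NULL
  }
  attr(records, "per_component") <-
    if (length(comp) > 0L) do.call(rbind, comp) else NULL
  records
}

#' Flag CSF-contaminated records
#'
#' Records (contours) whose mean MD exceeds the threshold (strictly; the
#' boundary value is retained) are flagged `excluded_csf = TRUE`. Flagged
#' records stay in the table but are dropped from model input for both FA
#' and MD analyses -- the contour, not the MD value, is contaminated.
#' Idempotent and order-independent.
#'
#' @param records shell-record data.frame.
#' @param md_threshold exclusion threshold in mm^2/s (default 1e-3).
#' @return The records with `excluded_csf` set.
#' @export
apply_csf_exclusion <- function(records, md_threshold = 1e-3) {
  records <- validate_records(records)
  records$excluded_csf <- !is.na(records$mean_md) &
    records$mean_md > md_threshold
  records
}

# Records eligible as model input: empty shells always dropped;
# CSF-flagged records dropped for both outcomes under the default
# "contour" scope, or for MD only under "md_only" (sensitivity option).
model_input <- function(records, outcome = "both",
                        exclusion_scope = c("contour", "md_only")) {
  exclusion_scope <- match.arg(exclusion_scope)
  records <- validate_records(records)
  drop_csf <- records$excluded_csf
  if (exclusion_scope == "md_only" && identical(outcome, "fa"))
    drop_csf <- rep(FALSE, nrow(records))
  records[!drop_csf & records$n_voxels > 0L &
            !is.na(records$mean_fa) & !is.na(records$mean_md), , drop = FALSE]
}
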