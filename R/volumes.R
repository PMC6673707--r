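#' Voxel-grid contract shared by all volumes
#'
#' A `volume_grid` records the array shape, the voxel size in mm, and a 4x4
#' affine mapping 0-based voxel indices to world coordinates in mm. Every
#' volume in a pipeline run must live on one common grid (the inputs are
#' assumed co-registered and resampled upstream); the geometry code relies
#' on that, and on the "one dilation step = one voxel = 2 mm" convention,
#' which only holds on isotropic grids.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size_mm numeric vector of length 3, voxel edge lengths in mm
#'   (all > 0).
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices to mm.
#'   Defaults to `diag(c(voxel_size_mm, 1))`. Its upper-left 3x3 block must
#'   be non-singular.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, voxel_size_mm = c(2, 2, 2), affine = NULL) {
  shape <- as.integer(shape)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be 3 positive integers")
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be 3 positive reals")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || any(!is.finite(affine)))
    stop("`affine` must be a finite 4x4 matrix")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
    stop("`affine` upper-left 3x3 block is singular")
  structure(
    list(shape = shape, voxel_size_mm = voxel_size_mm, affine = affine),
    class = "volume_grid"
  )
}

#' @export
format.volume_grid <- function(x, ...) {
  sprintf("<volume_grid %s, voxel %s mm%s>",
          paste(x$shape, collapse = "x"),
          paste(signif(x$voxel_size_mm, 4), collapse = "x"),
          if (grid_is_isotropic(x)) "" else " [anisotropic]")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

grid_is_isotropic <- function(grid, tol = 1e-3) {
  diff(range(grid$voxel_size_mm)) <= tol
}

grids_equal <- function(a, b, voxel_tol = 1e-3) {
  identical(a$shape, b$shape) &&
    all(abs(a$voxel_size_mm - b$voxel_size_mm) <= voxel_tol)
}

#' Binary mask on a voxel grid
#'
#' @param data 3-D array whose values are exactly 0 or 1 (logical arrays are
#'   accepted and coerced).
#' @param grid a [volume_grid()] whose shape matches `dim(data)`.
#' @return An object of class `mask_volume`; `data` is stored as a logical
#'   array.
#' @export
mask_volume <- function(data, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  if (is.logical(data)) {
    d <- data
  } else {
    v <- as.numeric(data)
    if (any(!(v %in% c(0, 1))))
      stop("mask data must contain only 0 and 1")
    d <- array(v == 1, dim = dim(data))
  }
  if (!identical(as.integer(dim(d)), grid$shape))
    stop("mask data shape does not match grid shape")
  structure(list(grid = grid, data = d), class = "mask_volume")
}

#' Scalar (floating point) map on a voxel grid
#'
#' Used for FA and MD parametric maps and for tract posterior-probability
#' maps. FA is dimensionless in \[0,1\]; MD is in mm^2/s.
#'
#' @param data 3-D numeric array of finite values (NA allowed outside the
#'   brain).
#' @param grid a [volume_grid()] whose shape matches `dim(data)`.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  d <- array(as.numeric(data), dim = dim(data))
  if (!identical(as.integer(dim(d)), grid$shape))
    stop("scalar data shape does not match grid shape")
  if (any(is.infinite(d)))
    stop("scalar data contains non-finite (infinite) values")
  structure(list(grid = grid, data = d), class = "scalar_volume")
}

#' Number of foreground voxels in a mask
#' @param mask a `mask_volume`.
#' @return Integer count of 1-voxels.
#' @export
mask_count <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  sum(mask$data)
}

#' Enforce the common-grid contract
#'
#' All downstream geometry assumes every volume of a participant lives on
#' one grid. Shapes must match exactly; voxel sizes must agree within
#' `voxel_tol` mm (default 1e-3, absorbing header rounding).
#'
#' @param volumes non-empty list of `mask_volume` / `scalar_volume`.
#' @param voxel_tol absolute tolerance on voxel size agreement, mm.
#' @return The shared grid (that of the first volume), invisibly classed as
#'   `volume_grid`.
#' @export
assert_common_grid <- function(volumes, voxel_tol = 1e-3) {
  if (!is.list(volumes) || length(volumes) == 0L)
    stop("`volumes` must be a non-empty list")
  nm <- names(volumes)
  if (is.null(nm)) nm <- as.character(seq_along(volumes))
  ref <- volumes[[1L]]$grid
  for (i in seq_along(volumes)) {
    g <- volumes[[i]]$grid
    if (!identical(g$shape, ref$shape))
      stop(sprintf(
        "grid mismatch: volume '%s' has shape (%s), expected (%s)",
        nm[i], paste(g$shape, collapse = ","),
        paste(ref$shape, collapse = ",")))
    dv <- abs(g$voxel_size_mm - ref$voxel_size_mm)
    if (any(dv > voxel_tol))
      stop(sprintf(
        "grid mismatch: volume '%s' has voxel size (%s) mm, expected (%s) mm",
        nm[i], paste(signif(g$voxel_size_mm, 6), collapse = ","),
        paste(signif(ref$voxel_size_mm, 6), collapse = ",")))
  }
  ref
}
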