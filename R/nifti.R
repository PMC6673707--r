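# Minimal NIfTI-1 reader/writer.
#
# Only what the pipeline needs: single-file .nii / .nii.gz, 3-D images,
# datatypes uint8/int8/int16/uint16/int32/float32/float64, scl_slope/inter
# scaling, sform (preferred) or qform affines, both endiannesses on read.
# The pre-installed R stack ships no NIfTI package, so this codec is part of
# the package and is cross-checked against nibabel in the test suite.

.nifti_datatypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

read_nifti_raw <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  con <- gzfile(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr_bytes <- readBin(con, "raw", n = 348L)
  if (length(hdr_bytes) < 348L)
    stop(sprintf("cannot read '%s': truncated NIfTI header", path))
  endian <- "little"
  sz <- readBin(hdr_bytes[1:4], "integer", size = 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr_bytes[1:4], "integer", size = 4L, endian = endian)
    if (sz != 348L)
      stop(sprintf("cannot read '%s': not a NIfTI-1 file (sizeof_hdr != 348)",
                   path))
  }
  dim_    <- readBin(hdr_bytes[41:56], "integer", n = 8L, size = 2L,
                     endian = endian)
  datatype <- readBin(hdr_bytes[71:72], "integer", n = 1L, size = 2L,
                      endian = endian)
  pixdim  <- readBin(hdr_bytes[77:108], "double", n = 8L, size = 4L,
                     endian = endian)
  vox_offset <- readBin(hdr_bytes[109:112], "double", n = 1L, size = 4L,
                        endian = endian)
  scl_slope <- readBin(hdr_bytes[113:116], "double", n = 1L, size = 4L,
                       endian = endian)
  scl_inter <- readBin(hdr_bytes[117:120], "double", n = 1L, size = 4L,
                       endian = endian)
  qform_code <- readBin(hdr_bytes[253:254], "integer", n = 1L, size = 2L,
                        endian = endian)
  sform_code <- readBin(hdr_bytes[255:256], "integer", n = 1L, size = 2L,
                        endian = endian)
  quat <- readBin(hdr_bytes[257:280], "double", n = 6L, size = 4L,
                  endian = endian)
  srow <- readBin(hdr_bytes[281:328], "double", n = 12L, size = 4L,
                  endian = endian)
  magic <- rawToChar(hdr_bytes[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop(sprintf("cannot read '%s': bad NIfTI magic '%s'", path, magic))

  ndim <- dim_[1L]
  if (ndim < 3L)
    stop(sprintf("cannot read '%s': need a 3-D image, found %d-D", path, ndim))
  shape <- dim_[2:4]
  extra <- if (ndim > 3L) prod(pmax(dim_[5:(1L + ndim)], 1L)) else 1L
  if (extra != 1L)
    stop(sprintf("cannot read '%s': 4-D+ images are not supported", path))

  spec <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(spec))
    stop(sprintf("cannot read '%s': unsupported NIfTI datatype code %d",
                 path, datatype))
  skip <- round(vox_offset) - 348L
  if (skip > 0L) invisible(readBin(con, "raw", n = skip))
  n <- prod(shape)
  vals <- readBin(con, spec$what, n = n, size = spec$size, endian = endian,
                  signed = spec$signed)
  if (length(vals) < n)
    stop(sprintf("cannot read '%s': truncated data section", path))
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }

  affine <- NULL
  if (sform_code > 0L) {
    affine <- rbind(matrix(srow, nrow = 3L, byrow = TRUE), c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    b <- quat[1L]; c_ <- quat[2L]; d <- quat[3L]
    a <- sqrt(max(0, 1 - b^2 - c_^2 - d^2))
    R <- matrix(c(
      a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d),   2 * (b * d + a * c_),
      2 * (b * c_ + a * d),   a^2 + c_^2 - b^2 - d^2, 2 * (c_ * d - a * b),
      2 * (b * d - a * c_),   2 * (c_ * d + a * b),   a^2 + d^2 - b^2 - c_^2
    ), nrow = 3L, byrow = TRUE)
    qfac <- if (pixdim[1L] < 0) -1 else 1
    sc <- c(pixdim[2:3], pixdim[4L] * qfac)
    affine <- rbind(cbind(sweep(R, 2L, sc, `*`), quat[4:6]), c(0, 0, 0, 1))
  }
  voxel <- pixdim[2:4]
  if (any(!is.finite(voxel)) || any(voxel <= 0)) {
    if (!is.null(affine)) {
      voxel <- sqrt(colSums(affine[1:3, 1:3]^2))
    } else {
      stop(sprintf("cannot read '%s': invalid pixdim and no affine", path))
    }
  }
  grid <- volume_grid(shape, voxel, affine)
  list(grid = grid, data = array(vals, dim = shape))
}

#' Read a NIfTI volume as a typed mask / scalar / probability map
#'
#' @param path path to a `.nii` or `.nii.gz` NIfTI-1 file.
#' @param kind one of `"mask"` (values > 0.5 become 1, the rest 0 --- this
#'   only absorbs interpolation dust, masks are expected binary),
#'   `"scalar"` (values returned unmodified), or `"probability"` (values
#'   validated to lie in \[0,1\]).
#' @return A [mask_volume()] for `kind = "mask"`, otherwise a
#'   [scalar_volume()].
#' @export
read_volume <- function(path, kind = c("mask", "scalar", "probability")) {
  kind <- match.arg(kind)
  v <- read_nifti_raw(path)
  if (!grid_is_isotropic(v$grid))
    warning(sprintf(
      "'%s' has anisotropic voxels (%s mm); geometry operations will refuse this grid unless allow_anisotropic is set",
      path, paste(signif(v$grid$voxel_size_mm, 4), collapse = "x")))
  if (kind == "mask") {
    return(mask_volume(v$data > 0.5, v$grid))
  }
  if (kind == "probability") {
    rng <- range(v$data, na.rm = TRUE)
    if (rng[1L] < 0 || rng[2L] > 1)
      stop(sprintf(
        "probability map '%s' has values in [%g, %g], outside [0, 1]",
        path, rng[1L], rng[2L]))
  }
  scalar_volume(v$data, v$grid)
}

#' Write a volume as NIfTI-1
#'
#' Masks are written as uint8, scalar maps as float64 (so MD values around
#' 1e-3 mm^2/s round-trip exactly). The grid affine is stored as the sform;
#' `.gz` paths are gzip-compressed.
#'
#' @param volume a `mask_volume` or `scalar_volume`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  is_mask <- inherits(volume, "mask_volume")
  if (!is_mask && !inherits(volume, "scalar_volume"))
    stop("`volume` must be a mask_volume or scalar_volume")
  grid <- volume$grid
  datatype <- if (is_mask) 2L else 64L
  bitpix <- if (is_mask) 8L else 64L

  hdr <- raw(348L)
  put <- function(hdr, off, values, what, size) {
    b <- writeBin(values, raw(), size = size, endian = "little")
    hdr[(off + 1L):(off + length(b))] <- b
    hdr
  }
  hdr <- put(hdr, 0L, 348L, "integer", 4L)
  hdr <- put(hdr, 40L, as.integer(c(3L, grid$shape, 1L, 1L, 1L, 1L)),
             "integer", 2L)
  hdr <- put(hdr, 70L, datatype, "integer", 2L)
  hdr <- put(hdr, 72L, bitpix, "integer", 2L)
  hdr <- put(hdr, 76L, c(1, grid$voxel_size_mm, 1, 1, 1, 1), "double", 4L)
  hdr <- put(hdr, 108L, 352, "double", 4L)          # vox_offset
  hdr <- put(hdr, 112L, c(1, 0), "double", 4L)      # scl_slope, scl_inter
  hdr[124L] <- as.raw(2L)                           # xyzt_units: mm
  hdr <- put(hdr, 252L, c(0L, 1L), "integer", 2L)   # qform 0, sform 1
  hdr <- put(hdr, 280L, as.numeric(t(grid$affine[1:3, ])), "double", 4L)
  hdr[345:347] <- charToRaw("n+1")

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(hdr, con)
  writeBin(raw(4L), con)                            # pad to vox_offset 352
  if (is_mask) {
    writeBin(as.integer(volume$data), con, size = 1L, endian = "little")
  } else {
    writeBin(as.numeric(volume$data), con, size = 8L, endian = "little")
  }
  invisible(path)
}
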