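# Binary morphology on 3-D logical arrays.
#
# All geometry in this package is voxel-based: one 26-connected dilation
# step grows a region by exactly 1 in Chebyshev (chessboard) distance,
# which on the 2 mm isotropic dMRI grid is the "dilate by 2 mm (1 voxel)"
# operation the shell construction is built on. The 26-connectivity
# structuring element (3x3x3 cube) is separable, so it is applied as three
# 1-D passes; 6- and 18-connectivity use explicit neighbour shifts.

shift_array <- function(a, s, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  idx <- vector("list", 3L)
  src <- vector("list", 3L)
  for (i in 1:3) {
    if (s[i] >= 0) {
      n <- d[i] - s[i]
      if (n <= 0L) return(out)
      idx[[i]] <- seq_len(n) + s[i]
      src[[i]] <- seq_len(n)
    } else {
      n <- d[i] + s[i]
      if (n <= 0L) return(out)
      idx[[i]] <- seq_len(n)
      src[[i]] <- seq_len(n) - s[i]
    }
  }
  out[idx[[1L]], idx[[2L]], idx[[3L]]] <- a[src[[1L]], src[[2L]], src[[3L]]]
  out
}

conn_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6"  = ord == 1,
                 "18" = ord >= 1 & ord <= 2,
                 "26" = ord >= 1,
                 stop("connectivity must be 6, 18 or 26"))
  off[keep, , drop = FALSE]
}

# One-voxel binary dilation; separable fast path for the 26-neighbourhood.
dilate_binary <- function(a, connectivity = 26) {
  if (connectivity == 26) {
    out <- a
    for (ax in 1:3) {
      s <- c(0L, 0L, 0L)
      s[ax] <- 1L
      out <- out | shift_array(out, s) | shift_array(out, -s)
    }
    return(out)
  }
  off <- conn_offsets(connectivity)
  out <- a
  for (r in seq_len(nrow(off))) out <- out | shift_array(a, off[r, ])
  out
}

# Bounding box of a mask expanded by `pad`, clipped to the array.
mask_bbox <- function(a, pad = 0L) {
  idx <- which(a, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  d <- dim(a)
  lo <- pmax(apply(idx, 2L, min) - pad, 1L)
  hi <- pmin(apply(idx, 2L, max) + pad, d)
  list(lo = lo, hi = hi)
}

crop_bbox <- function(a, bb) {
  a[bb$lo[1L]:bb$hi[1L], bb$lo[2L]:bb$hi[2L], bb$lo[3L]:bb$hi[3L],
    drop = FALSE]
}

paste_bbox <- function(full, sub, bb) {
  full[bb$lo[1L]:bb$hi[1L], bb$lo[2L]:bb$hi[2L], bb$lo[3L]:bb$hi[3L]] <- sub
  full
}

# Chebyshev distance transform in dilation steps, capped at max_steps.
# Voxels never reached within the cap keep Inf. Work is confined to the
# seed bounding box padded by the cap (everything outside is Inf anyway).
chebyshev_steps <- function(seed, max_steps) {
  dist <- array(Inf, dim(seed))
  if (max_steps < 1L || !any(seed)) {
    dist[seed] <- 0
    return(dist)
  }
  bb <- mask_bbox(seed, max_steps)
  s <- crop_bbox(seed, bb)
  sub <- array(Inf, dim(s))
  sub[s] <- 0
  cur <- s
  for (k in seq_len(max_steps)) {
    nxt <- dilate_binary(cur, 26)
    sub[nxt & !cur] <- k
    cur <- nxt
  }
  paste_bbox(dist, sub, bb)
}

# Min Chebyshev distance (in voxels) between two voxel coordinate sets
# (arr.ind matrices). Exact, vectorized; intended for small `from` sets.
min_cheby_between <- function(from_idx, to_idx) {
  if (nrow(from_idx) == 0L || nrow(to_idx) == 0L) return(Inf)
  best <- Inf
  for (r in seq_len(nrow(from_idx))) {
    d <- pmax(abs(to_idx[, 1L] - from_idx[r, 1L]),
              abs(to_idx[, 2L] - from_idx[r, 2L]),
              abs(to_idx[, 3L] - from_idx[r, 3L]))
    best <- min(best, min(d))
    if (best == 0L) break
  }
  best
}

# Connected-component labelling by iterated minimum-label propagation.
# Returns an integer array (0 = background), components relabelled 1..K in
# order of centroid (lexicographic over the three axes, ties by smallest
# linear index) so the output is deterministic.
label_components <- function(mask, connectivity = 26) {
  full_dim <- dim(mask)
  bb <- mask_bbox(mask, 0L)
  if (is.null(bb)) return(array(0L, full_dim))
  mask_full <- mask
  mask <- crop_bbox(mask, bb)
  d <- dim(mask)
  lab <- array(Inf, d)
  lab[mask] <- which(as.vector(mask))
  off <- conn_offsets(connectivity)
  repeat {
    cand <- lab
    for (r in seq_len(nrow(off))) {
      cand <- pmin(cand, shift_array(lab, off[r, ], fill = Inf))
    }
    cand[!mask] <- Inf
    if (identical(cand, lab)) break
    lab <- cand
  }
  roots <- sort(unique(lab[is.finite(lab)]))
  out <- array(0L, d)
  if (length(roots) > 0L) {
    cent <- matrix(NA_real_, nrow = length(roots), ncol = 3L)
    for (i in seq_along(roots)) {
      ind <- which(lab == roots[i], arr.ind = TRUE)
      # centroid in full-grid coordinates (bbox offset added)
      cent[i, ] <- colMeans(ind) + (bb$lo - 1L)
    }
    ord <- order(cent[, 1L], cent[, 2L], cent[, 3L], roots)
    for (rank in seq_along(ord)) {
      out[lab == roots[ord[rank]]] <- rank
    }
  }
  paste_bbox(array(0L, full_dim), out, bb)
}

#' Dilate a mask by one voxel
#'
#' One morphological dilation step with the chosen structuring element.
#' With the default 26-connectivity (3x3x3 cube) one step adds exactly one
#' voxel of Chebyshev distance, i.e. 2 mm along any axis on the 2 mm
#' isotropic grid. Anisotropic grids are refused unless
#' `allow_anisotropic = TRUE`, because "one step = step_mm" has no single
#' meaning there.
#'
#' @param mask a `mask_volume`.
#' @param connectivity 6, 18 or 26 (default).
#' @param allow_anisotropic set TRUE to dilate on an anisotropic grid
#'   anyway (a warning reports the voxel dimensions used).
#' @return The dilated `mask_volume` (a superset of the input).
#' @export
dilate_step <- function(mask, connectivity = 26, allow_anisotropic = FALSE) {
  stopifnot(inherits(mask, "mask_volume"))
  if (!grid_is_isotropic(mask$grid)) {
    if (!allow_anisotropic)
      stop(sprintf(
        "grid is anisotropic (voxel %s mm); one dilation step is only a fixed mm distance on isotropic grids. Pass allow_anisotropic = TRUE to override.",
        paste(signif(mask$grid$voxel_size_mm, 4), collapse = "x")))
    warning(sprintf(
      "dilating on an anisotropic grid (voxel %s mm); reported distances use the maximum in-plane voxel dimension",
      paste(signif(mask$grid$voxel_size_mm, 4), collapse = "x")))
  }
  mask_volume(dilate_binary(mask$data, connectivity), mask$grid)
}
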