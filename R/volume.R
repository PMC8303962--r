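#' Axis-aligned 3-D scalar volume
#'
#' A minimal CT-style volume: a 3-D numeric array with per-axis spacing
#' (mm/voxel) and the world coordinate (mm) of the center of voxel
#' `[1, 1, 1]` (0-based index (0,0,0)). Axis order is fixed as (x, y, z)
#' with x fastest, and the world<->voxel mapping is affine diagonal:
#' `world = origin + index * spacing`. Oblique direction matrices are not
#' representable; readers reject them loudly.
#'
#' @param voxels 3-D numeric array.
#' @param spacing positive 3-vector, mm per voxel.
#' @param origin world coordinate (mm) of the first voxel center.
#' @return An object of class `volume`.
#' @export
new_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3-D array")
  if (any(dim(voxels) < 1L)) stop("volume grid must be non-empty")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be a finite 3-vector")
  if (any(!is.finite(voxels))) stop("all voxels must be finite")
  voxels <- array(as.numeric(voxels), dim(voxels))   # strip foreign classes
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("volume %d x %d x %d, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @rdname new_volume
#' @param volume a `volume`.
#' @export
volume_center <- function(volume) {
  stopifnot(inherits(volume, "volume"))
  volume$origin + (dim(volume$voxels) - 1) / 2 * volume$spacing
}

#' World coordinates of every voxel center
#'
#' @param volume a `volume`.
#' @return An n-by-3 matrix in grid order (x fastest).
#' @export
voxel_world_coords <- function(volume) {
  stopifnot(inherits(volume, "volume"))
  d <- dim(volume$voxels)
  xs <- volume$origin[1] + (seq_len(d[1]) - 1) * volume$spacing[1]
  ys <- volume$origin[2] + (seq_len(d[2]) - 1) * volume$spacing[2]
  zs <- volume$origin[3] + (seq_len(d[3]) - 1) * volume$spacing[3]
  cbind(rep(xs, times = d[2] * d[3]),
        rep(rep(ys, each = d[1]), times = d[3]),
        rep(zs, each = d[1] * d[2]))
}

#' Trilinear sampling of a volume at world points
#'
#' Linear interpolation on the eight surrounding voxels. Points outside the
#' hull of voxel centers are defined (not an error) and return `fill`;
#' the returned vector carries a logical `inbounds` attribute marking them.
#'
#' @param volume a `volume`.
#' @param points n-by-3 matrix of world coordinates (mm) or a 3-vector.
#' @param fill value returned outside the grid (default 0: the background
#'   after bone thresholding).
#' @return Numeric vector of sampled values with attribute `inbounds`.
#' @export
sample_trilinear <- function(volume, points, fill = 0) {
  stopifnot(inherits(volume, "volume"))
  vec <- is.null(dim(points))
  pts <- if (vec) matrix(as.numeric(points), 1, 3) else as.matrix(points)
  if (ncol(pts) != 3L) stop("points must be n x 3")
  res <- cpp_sample_trilinear(as.vector(volume$voxels), dim(volume$voxels),
                              volume$spacing, volume$origin, pts, fill)
  structure(res$values, inbounds = res$inbounds)
}

#' Resample a volume through a rigid transform
#'
#' Pull-back resampling onto a reference grid: each output voxel at world
#' position `p` takes the value of the moving volume at `T^-1 p`, sampled
#' trilinearly. This realizes "apply transform T to the moving image" for
#' intensity-based registration.
#'
#' @param moving a `volume` to transform.
#' @param transform a [rigid_transform()].
#' @param reference a `volume` defining the output grid (defaults to the
#'   moving volume's own grid).
#' @param fill out-of-bounds fill value.
#' @return A `volume` on the reference grid; attribute `inbounds` is a
#'   logical array marking voxels whose pull-back sample fell inside the
#'   moving volume.
#' @export
resample_rigid <- function(moving, transform, reference = moving, fill = 0) {
  stopifnot(inherits(moving, "volume"), inherits(transform, "rigid_transform"),
            inherits(reference, "volume"))
  pts <- voxel_world_coords(reference)
  q <- apply_points(invert_transform(transform), pts)
  vals <- sample_trilinear(moving, q, fill = fill)
  d <- dim(reference$voxels)
  out <- new_volume(array(as.numeric(vals), d), reference$spacing, reference$origin)
  attr(out, "inbounds") <- array(attr(vals, "inbounds"), d)
  out
}

#' Downsample a volume by an integer factor (block mean)
#'
#' Used by the registration pyramid. Trailing voxels that do not fill a
#' complete block are dropped; spacing is multiplied by the factor and the
#' origin moved to the center of the first block so world coordinates of
#' block centers are preserved.
#'
#' @param volume a `volume`.
#' @param factor integer >= 1.
#' @return A `volume`.
#' @export
downsample_volume <- function(volume, factor) {
  stopifnot(inherits(volume, "volume"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  if (factor == 1L) return(volume)
  d <- dim(volume$voxels)
  nd <- d %/% factor
  if (any(nd < 2L)) stop("volume too small for this pyramid factor")
  v <- volume$voxels[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                     seq_len(nd[3] * factor), drop = FALSE]
  dim(v) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  v <- apply(v, c(2, 4, 6), mean)
  new_volume(v, volume$spacing * factor,
             volume$origin + (factor - 1) / 2 * volume$spacing)
}

#' Separable Gaussian blur of a volume
#'
#' @param volume a `volume`.
#' @param sigma_vox standard deviation in voxels (scalar or per-axis).
#' @return A blurred `volume`; `sigma_vox = 0` returns the input unchanged.
#' @export
gaussian_blur_volume <- function(volume, sigma_vox) {
  stopifnot(inherits(volume, "volume"))
  sigma <- rep(as.numeric(sigma_vox), length.out = 3)
  if (any(sigma < 0)) stop("blur sigma must be non-negative")
  if (all(sigma == 0)) return(volume)
  v <- volume$voxels
  for (ax in 1:3) {
    if (sigma[ax] == 0) next
    r <- max(1L, ceiling(3 * sigma[ax]))
    k <- exp(-((-r:r)^2) / (2 * sigma[ax]^2))
    k <- k / sum(k)
    v <- convolve_axis(v, k, ax)
  }
  new_volume(v, volume$spacing, volume$origin)
}

# 1-D convolution along one axis with edge replication
convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  r <- (length(kernel) - 1L) / 2L
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  pad_top <- m[rep(1L, r), , drop = FALSE]
  pad_bot <- m[rep(nrow(m), r), , drop = FALSE]
  mp <- rbind(pad_top, m, pad_bot)
  out <- matrix(0, nrow = nrow(m), ncol = ncol(m))
  for (j in seq_along(kernel)) {
    out <- out + kernel[j] * mp[j:(j + nrow(m) - 1L), , drop = FALSE]
  }
  a <- array(out, da)
  aperm(a, order(perm))
}
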