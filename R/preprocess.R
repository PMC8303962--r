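#' Detect the maximal head ellipse across axial slices
#'
#' Each axial slice is thresholded at `foreground_hu`, the largest connected
#' component is taken and an ellipse fitted to it from its second-order
#' moments (for a filled ellipse the principal variances are a^2/4 and
#' b^2/4, so the fit is exact in the continuum limit). The fitted ellipse of
#' maximal area across slices is returned. This drives the crop that removes
#' the scanner bed while keeping the whole head.
#'
#' @param volume a CT `volume` in Hounsfield units.
#' @param foreground_hu threshold separating head from air (default -200 HU).
#' @param min_voxels smallest component size considered a real foreground.
#' @return An object of class `ellipse2d`: in-plane `center` (mm),
#'   semi-axes `a >= b` (mm), `angle` (radians) and the detection `slice`.
#' @export
detect_max_ellipse <- function(volume, foreground_hu = -200, min_voxels = 100) {
  stopifnot(inherits(volume, "volume"))
  d <- dim(volume$voxels)
  sp <- volume$spacing
  best <- NULL
  for (k in seq_len(d[3])) {
    mask <- volume$voxels[, , k] >= foreground_hu
    if (sum(mask) < min_voxels) next
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab[lab > 0])
    if (length(sizes) == 0 || max(sizes) < min_voxels) next
    comp <- lab == which.max(sizes)
    idx <- which(comp, arr.ind = TRUE)
    xy <- cbind(volume$origin[1] + (idx[, 1] - 1) * sp[1],
                volume$origin[2] + (idx[, 2] - 1) * sp[2])
    ctr <- colMeans(xy)
    cv <- stats::cov(xy) * (nrow(xy) - 1) / nrow(xy)
    # discrete pixels carry their own spread; add the pixel variance
    cv <- cv + diag(sp[1:2]^2 / 12)
    eg <- eigen(cv, symmetric = TRUE)
    a <- 2 * sqrt(eg$values[1])
    b <- 2 * sqrt(eg$values[2])
    ang <- atan2(eg$vectors[2, 1], eg$vectors[1, 1])
    if (ang <= -pi / 2) ang <- ang + pi
    if (ang > pi / 2) ang <- ang - pi
    if (is.null(best) || a * b > best$a * best$b)
      best <- structure(list(center = ctr, a = a, b = b, angle = ang, slice = k),
                        class = "ellipse2d")
  }
  if (is.null(best))
    stop("empty scene: no axial slice has a foreground component of at least ",
         min_voxels, " voxels above ", foreground_hu, " HU")
  best
}

#' @export
print.ellipse2d <- function(x, ...) {
  cat(sprintf("ellipse2d: center (%.2f, %.2f) mm, a = %.2f mm, b = %.2f mm, angle = %.2f deg (slice %d)\n",
              x$center[1], x$center[2], x$a, x$b, x$angle / DEG, x$slice))
  invisible(x)
}

#' Crop a volume to an expanded elliptical cylinder
#'
#' Voxels outside the detected ellipse scaled by `expand` (on both
#' semi-axes) and extruded through all slices are replaced by `fill_hu`;
#' the grid shape is unchanged. The default 1.2 expansion keeps a 20%
#' safety margin around the head.
#'
#' @param volume a `volume`.
#' @param ellipse an `ellipse2d` from [detect_max_ellipse()].
#' @param expand semi-axis scale factor (> 0).
#' @param fill_hu replacement value for voxels outside the cylinder.
#' @return A `volume` of identical shape.
#' @export
crop_elliptical_cylinder <- function(volume, ellipse, expand = 1.2,
                                     fill_hu = -1000) {
  stopifnot(inherits(volume, "volume"), inherits(ellipse, "ellipse2d"))
  if (!is.finite(expand) || expand <= 0) stop("expand must be > 0")
  d <- dim(volume$voxels)
  sp <- volume$spacing
  xs <- volume$origin[1] + (seq_len(d[1]) - 1) * sp[1] - ellipse$center[1]
  ys <- volume$origin[2] + (seq_len(d[2]) - 1) * sp[2] - ellipse$center[2]
  X <- matrix(xs, d[1], d[2])
  Y <- matrix(ys, d[1], d[2], byrow = TRUE)
  ca <- cos(ellipse$angle); sa <- sin(ellipse$angle)
  U <- X * ca + Y * sa
  V <- -X * sa + Y * ca
  inside <- (U / (ellipse$a * expand))^2 + (V / (ellipse$b * expand))^2 <= 1
  v <- volume$voxels
  for (k in seq_len(d[3])) {
    slice <- v[, , k]
    slice[!inside] <- fill_hu
    v[, , k] <- slice
  }
  new_volume(v, volume$spacing, volume$origin)
}

#' Remove non-rigid soft tissue by HU thresholding
#'
#' Voxels with `HU < hu_min` are set to `background`; voxels at or above the
#' threshold keep their original HU (the boundary is inclusive: HU = 100
#' survives the default threshold). The default background of 0 matches the
#' out-of-bounds fill used during registration resampling.
#'
#' @param volume a CT `volume` in Hounsfield units.
#' @param hu_min bone threshold (default 100 HU).
#' @param background replacement value for sub-threshold voxels.
#' @return A `volume`.
#' @export
threshold_bone <- function(volume, hu_min = 100, background = 0) {
  stopifnot(inherits(volume, "volume"))
  v <- volume$voxels
  v[v < hu_min] <- background
  new_volume(v, volume$spacing, volume$origin)
}

#' Full CT preprocessing pipeline for rigid registration
#'
#' Max-ellipse detection, elliptical-cylinder crop with a 20% margin, then
#' bone thresholding, with a JSON-serializable report of what was removed.
#'
#' @inheritParams detect_max_ellipse
#' @inheritParams crop_elliptical_cylinder
#' @inheritParams threshold_bone
#' @return A list with elements `volume` (the preprocessed `volume`),
#'   `ellipse`, and `report` (voxel counts before/after each stage).
#' @export
preprocess_ct <- function(volume, foreground_hu = -200, expand = 1.2,
                          hu_min = 100, fill_hu = -1000, background = 0) {
  ellipse <- detect_max_ellipse(volume, foreground_hu = foreground_hu)
  cropped <- crop_elliptical_cylinder(volume, ellipse, expand = expand,
                                      fill_hu = fill_hu)
  bone <- threshold_bone(cropped, hu_min = hu_min, background = background)
  report <- list(
    ellipse = list(center_mm = ellipse$center, a_mm = ellipse$a,
                   b_mm = ellipse$b, angle_deg = ellipse$angle / DEG,
                   slice = ellipse$slice),
    expand = expand, hu_min = hu_min,
    voxels_total = length(volume$voxels),
    voxels_inside_cylinder = sum(cropped$voxels != fill_hu |
                                   volume$voxels == fill_hu),
    voxels_bone = sum(bone$voxels != background))
  list(volume = bone, ellipse = ellipse, report = report)
}
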