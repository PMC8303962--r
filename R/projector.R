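#' Pinhole C-arm projection geometry
#'
#' The X-ray imaging system is modeled as a pinhole camera. In the canonical
#' (AP) view frame the source sits at `isocenter - sid * x`, the detector
#' plane is perpendicular to x at `isocenter + (sdd - sid) * x`, and the
#' detector axes are u = y (in-plane horizontal) and v = z (cranio-caudal).
#' A second view is obtained by composing the fixed inter-view transform
#' from [lat_view_transform()] before the pose pull-back, so the AP and LAT
#' rays share a single pose of the volume.
#'
#' @param sid source-to-isocenter distance (mm).
#' @param sdd source-to-detector distance (mm); must exceed `sid` so the
#'   detector lies behind the isocenter relative to the source.
#' @param detector_px detector size in pixels, `(nu, nv)`.
#' @param pixel_spacing detector pixel spacing (mm), `(u, v)`.
#' @param isocenter world position (mm) of the imaging isocenter.
#' @param view view tag, `"ap"` or `"lat"` (or a custom label).
#' @param view_transform a [rigid_transform()] mapping the canonical view
#'   frame to this view's frame (identity for AP,
#'   `lat_view_transform(angle, isocenter)` for LAT).
#' @param step ray-march step (mm); `NULL` selects half the smallest voxel
#'   spacing at render time.
#' @return An object of class `projection_geometry`.
#' @export
projection_geometry <- function(sid = 1000, sdd = 1500,
                                detector_px = c(256, 256),
                                pixel_spacing = c(1, 1),
                                isocenter = c(0, 0, 0),
                                view = "ap",
                                view_transform = NULL,
                                step = NULL) {
  if (!is.finite(sid) || sid <= 0 || !is.finite(sdd) || sdd <= 0)
    stop("source distances must be positive")
  if (sdd <= sid)
    stop("invalid geometry: detector (sdd) must lie beyond the isocenter (sid)")
  detector_px <- as.integer(detector_px)
  if (length(detector_px) != 2L || any(detector_px < 1L))
    stop("detector_px must be two positive integers")
  pixel_spacing <- rep(as.numeric(pixel_spacing), length.out = 2)
  if (any(pixel_spacing <= 0)) stop("pixel spacing must be positive")
  if (!is.null(step) && (!is.finite(step) || step <= 0))
    stop("ray-march step must be positive")
  if (is.null(view_transform)) view_transform <- rigid_transform(diag(4))
  stopifnot(inherits(view_transform, "rigid_transform"))
  structure(list(sid = sid, sdd = sdd, detector_px = detector_px,
                 pixel_spacing = pixel_spacing,
                 isocenter = as.numeric(isocenter), view = view,
                 view_transform = view_transform, step = step),
            class = "projection_geometry")
}

#' @rdname projection_geometry
#' @param angle_deg inter-view angle for the second view (degrees).
#' @param geometry an AP `projection_geometry` to derive the second view from.
#' @export
lat_geometry <- function(geometry, angle_deg = 90) {
  stopifnot(inherits(geometry, "projection_geometry"))
  geometry$view <- "lat"
  geometry$view_transform <- lat_view_transform(angle_deg, geometry$isocenter)
  geometry
}

# source and per-pixel detector positions in the canonical (AP) frame; the
# view transform is folded into the pull-back at render time, per the
# biplanar imaging model
geometry_rays <- function(geometry) {
  g <- geometry
  src <- g$isocenter + c(-g$sid, 0, 0)
  det_center <- g$isocenter + c(g$sdd - g$sid, 0, 0)
  nu <- g$detector_px[1]; nv <- g$detector_px[2]
  us <- (seq_len(nu) - (nu + 1) / 2) * g$pixel_spacing[1]
  vs <- (seq_len(nv) - (nv + 1) / 2) * g$pixel_spacing[2]
  dst <- cbind(det_center[1],
               det_center[2] + rep(us, times = nv),
               det_center[3] + rep(vs, each = nu))
  list(src = src, dst = dst)
}

#' DRR image container
#'
#' @param pixels nu-by-nv matrix of line integrals (intensity * mm).
#' @param pixel_spacing detector pixel spacing (mm).
#' @param view view tag.
#' @return An object of class `drr_image`.
#' @export
drr_image <- function(pixels, pixel_spacing = c(1, 1), view = "ap") {
  pixels <- as.matrix(pixels)
  if (any(!is.finite(pixels))) stop("DRR pixels must be finite")
  structure(list(pixels = pixels,
                 pixel_spacing = rep(as.numeric(pixel_spacing), length.out = 2),
                 view = view),
            class = "drr_image")
}

#' @export
print.drr_image <- function(x, ...) {
  cat(sprintf("drr_image [%s] %d x %d px, spacing (%g, %g) mm, range [%g, %g]\n",
              x$view, nrow(x$pixels), ncol(x$pixels),
              x$pixel_spacing[1], x$pixel_spacing[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Render a perspective DRR by ray casting
#'
#' For every detector pixel the segment from the X-ray source to the pixel
#' is marched in uniform steps, accumulating trilinearly interpolated volume
#' samples times the step length -- a midpoint-rule approximation of the
#' line integral of the volume posed at `pose`. The volume is pulled back
#' through the inverse of (view transform composed with pose), so the same
#' pose feeds both views of a biplanar acquisition.
#'
#' @param volume a `volume`.
#' @param pose a [pose6()]; rotation center defaults to the volume's
#'   world-space center.
#' @param geometry a [projection_geometry()].
#' @param center rotation center (mm) for the pose.
#' @return A [drr_image()]. A geometry whose rays all miss the volume yields
#'   an all-zero image, not an error.
#' @export
render_drr <- function(volume, pose = pose6(), geometry = projection_geometry(),
                       center = NULL) {
  stopifnot(inherits(volume, "volume"), inherits(geometry, "projection_geometry"))
  pose <- as_pose6(pose)
  if (is.null(center)) center <- volume_center(volume)
  step <- geometry$step %||% (0.5 * min(volume$spacing))
  Tpose <- pose_to_matrix(pose, center = center)
  rays <- geometry_rays(geometry)
  # sample J((V o T)^-1 p): canonical rays pulled back through the view
  # transform and then the pose
  Minv <- invert_transform(compose(geometry$view_transform, Tpose))
  src <- apply_points(Minv, rays$src)
  dst <- apply_points(Minv, rays$dst)
  vals <- cpp_render_rays(as.vector(volume$voxels), dim(volume$voxels),
                          volume$spacing, volume$origin, src, dst, step)
  drr_image(matrix(vals, geometry$detector_px[1], geometry$detector_px[2]),
            pixel_spacing = geometry$pixel_spacing, view = geometry$view)
}

#' Render the AP/LAT biplanar pair at a shared pose
#'
#' @inheritParams render_drr
#' @param geom_ap,geom_lat AP and LAT [projection_geometry()] objects; by
#'   default the LAT view is the AP geometry rotated by `angle_deg`.
#' @param angle_deg inter-view angle used when `geom_lat` is derived.
#' @return A list with elements `ap` and `lat`, both [drr_image()].
#' @export
render_biplanar <- function(volume, pose = pose6(),
                            geom_ap = projection_geometry(),
                            geom_lat = NULL, angle_deg = 90, center = NULL) {
  if (is.null(geom_lat)) geom_lat <- lat_geometry(geom_ap, angle_deg)
  list(ap = render_drr(volume, pose, geom_ap, center = center),
       lat = render_drr(volume, pose, geom_lat, center = center))
}

#' Reconstruction supervision losses
#'
#' `reconstruction_loss` is the mean squared voxel difference between a
#' generated volume and the ground truth. `perspective_projection_loss`
#' renders the generated volume in both views with the same ray caster used
#' for DRRs and averages the two image MSEs.
#' `total_generator_loss` combines the adversarial, reconstruction and
#' projection terms with balance weights (defaults 0.1, 10, 10).
#'
#' @param generated,truth `volume`s on the same grid.
#' @return A scalar loss.
#' @export
reconstruction_loss <- function(generated, truth) {
  stopifnot(inherits(generated, "volume"), inherits(truth, "volume"))
  if (!identical(dim(generated$voxels), dim(truth$voxels)))
    stop("volumes must share a grid")
  mean((generated$voxels - truth$voxels)^2)
}

#' @rdname reconstruction_loss
#' @param ap_image,lat_image target [drr_image()]s.
#' @param geom_ap,geom_lat the two [projection_geometry()]s.
#' @export
perspective_projection_loss <- function(generated, ap_image, lat_image,
                                        geom_ap = projection_geometry(),
                                        geom_lat = NULL) {
  stopifnot(inherits(ap_image, "drr_image"), inherits(lat_image, "drr_image"))
  if (is.null(geom_lat)) geom_lat <- lat_geometry(geom_ap)
  rend <- render_biplanar(generated, pose6(), geom_ap, geom_lat)
  if (!identical(dim(rend$ap$pixels), dim(ap_image$pixels)) ||
      !identical(dim(rend$lat$pixels), dim(lat_image$pixels)))
    stop("target images do not match the detector geometry")
  0.5 * (mean((ap_image$pixels - rend$ap$pixels)^2) +
           mean((lat_image$pixels - rend$lat$pixels)^2))
}

#' @rdname reconstruction_loss
#' @param l_lsgan,l_rl,l_rpl adversarial, reconstruction and perspective
#'   projection loss values.
#' @param eps balance weights for the three terms.
#' @export
total_generator_loss <- function(l_lsgan, l_rl, l_rpl, eps = c(0.1, 10, 10)) {
  stopifnot(is.finite(l_lsgan), is.finite(l_rl), is.finite(l_rpl),
            length(eps) == 3L, all(is.finite(eps)))
  eps[1] * l_lsgan + eps[2] * l_rl + eps[3] * l_rpl
}

#' Contrast ("X-ray energy") variants of a DRR
#'
#' Monotone gamma remapping after min-max normalization to `[0, 1]`,
#' emulating radiographs acquired at different X-ray energies: gamma 0.5
#' (`"low"` contrast), 1.0 (`"mid"`, the identity on the normalized image)
#' and 2.0 (`"high"`). Pixel ordering is preserved exactly.
#'
#' @param image a [drr_image()].
#' @param level `"low"`, `"mid"` or `"high"`.
#' @return A [drr_image()] with normalized, gamma-adjusted pixels.
#' @export
contrast_adjust <- function(image, level = c("mid", "low", "high")) {
  stopifnot(inherits(image, "drr_image"))
  level <- match.arg(level)
  gamma <- c(low = 0.5, mid = 1.0, high = 2.0)[[level]]
  px <- image$pixels
  rng <- range(px)
  n <- if (diff(rng) > 0) (px - rng[1]) / diff(rng) else px * 0
  drr_image(n^gamma, image$pixel_spacing, image$view)
}
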