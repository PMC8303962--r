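#' Landmark set
#'
#' Named 3-D world coordinates (mm) of anatomical targets, e.g. the two
#' foramen ovale centers plus additional bone landmarks used for target
#' registration error.
#'
#' @param coords n-by-3 numeric matrix of world coordinates (mm).
#' @param names optional landmark names.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(coords, names = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1L || ncol(coords) != 3L || any(!is.finite(coords)))
    stop("landmarks must be a non-empty n x 3 matrix of finite coordinates")
  rownames(coords) <- names %||% rownames(coords) %||%
    paste0("lm", seq_len(nrow(coords)))
  structure(list(coords = coords), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("landmark_set with", nrow(x$coords), "landmarks\n")
  print(signif(x$coords, 6))
  invisible(x)
}

#' Synthetic head phantom with skull-base canal landmarks
#'
#' Emulates the gross structure of a head CT: an ellipsoidal high-HU shell
#' (skull, ~1200 HU) enclosing soft tissue (~40 HU) in air (-1000 HU), with
#' two small low-HU canals carved through the skull base whose centers stand
#' in for the foramen ovale landmarks, plus ten additional landmarks sampled
#' on the shell. Shape jitter and additive Gaussian HU noise are seeded, so
#' the phantom is deterministic per seed.
#'
#' @param seed integer seed controlling jitter, noise and landmark sampling.
#' @param shape grid size in voxels (all axes >= 32).
#' @param spacing voxel spacing (mm).
#' @param shell_hu,tissue_hu,air_hu,canal_hu intensities of the compartments.
#' @param noise_sd additive Gaussian noise (HU).
#' @param n_extra number of additional shell landmarks.
#' @return A list with elements `volume` (a [new_volume()]) and `landmarks`
#'   (a [landmark_set()]; the first two are the canal centers).
#' @export
make_phantom <- function(seed = 1, shape = c(64, 64, 64), spacing = c(2, 2, 2),
                         shell_hu = 1200, tissue_hu = 40, air_hu = -1000,
                         canal_hu = -200, noise_sd = 10, n_extra = 10) {
  shape <- as.integer(rep(shape, length.out = 3))
  if (any(shape < 32L)) stop("phantom shape must be at least 32 voxels per axis")
  spacing <- rep(as.numeric(spacing), length.out = 3)
  withr::with_seed(as.integer(seed), {
    extent <- (shape - 1) * spacing
    ctr <- extent / 2
    # skull outer semi-axes: distinctly unequal, as in a real cranium
    # (front-back length > height > width), so every rotation axis is
    # identifiable from the shell alone; +-3% seeded jitter
    semi <- c(0.34, 0.44, 0.38) * mean(extent) * runif(3, 0.97, 1.03)
    thick <- 5
    d <- shape
    xs <- (seq_len(d[1]) - 1) * spacing[1] - ctr[1]
    ys <- (seq_len(d[2]) - 1) * spacing[2] - ctr[2]
    zs <- (seq_len(d[3]) - 1) * spacing[3] - ctr[3]
    X2 <- array(rep((xs / semi[1])^2, times = d[2] * d[3]), d)
    Y2 <- array(rep(rep((ys / semi[2])^2, each = d[1]), times = d[3]), d)
    Z2 <- array(rep((zs / semi[3])^2, each = d[1] * d[2]), d)
    r_out <- X2 + Y2 + Z2
    si <- semi - thick
    X2i <- array(rep((xs / si[1])^2, times = d[2] * d[3]), d)
    Y2i <- array(rep(rep((ys / si[2])^2, each = d[1]), times = d[3]), d)
    Z2i <- array(rep((zs / si[3])^2, each = d[1] * d[2]), d)
    r_in <- X2i + Y2i + Z2i
    v <- array(air_hu, d)
    v[r_out <= 1] <- shell_hu
    v[r_in <= 1] <- tissue_hu
    shell <- r_out <= 1 & r_in > 1
    # two vertical canals through the skull base (z below center)
    canal_r <- 2.5
    canal_xy <- rbind(c(-0.35 * semi[1], 0.2 * semi[2]),
                      c(0.35 * semi[1], 0.2 * semi[2]))
    Xg <- array(rep(xs, times = d[2] * d[3]), d)
    Yg <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
    Zg <- array(rep(zs, each = d[1] * d[2]), d)
    fo <- matrix(0, 2, 3)
    for (j in 1:2) {
      cyl <- (Xg - canal_xy[j, 1])^2 + (Yg - canal_xy[j, 2])^2 <= canal_r^2
      carve <- cyl & shell & Zg < 0
      if (!any(carve)) stop("phantom canal does not intersect the skull base")
      v[carve] <- canal_hu
      fo[j, ] <- c(mean(Xg[carve]), mean(Yg[carve]), mean(Zg[carve])) + ctr
    }
    shell_left <- shell & v == shell_hu
    idx <- which(shell_left)
    pick <- sample(idx, n_extra)
    extra <- cbind(Xg[pick], Yg[pick], Zg[pick]) + matrix(ctr, n_extra, 3, byrow = TRUE)
    v <- v + array(rnorm(length(v), 0, noise_sd), d)
    lm <- landmark_set(rbind(fo, extra),
                       names = c("fo_left", "fo_right", paste0("bone", seq_len(n_extra))))
    list(volume = new_volume(v, spacing, c(0, 0, 0)), landmarks = lm)
  })
}

#' Sample a random pose from the benchmark perturbation range
#'
#' Each rotation angle is uniform on (-rot_range, +rot_range) degrees and
#' each translation uniform on (-trans_range, +trans_range) mm, matching the
#' benchmark's augmentation ranges (defaults 10 degrees, 20 mm).
#'
#' @param seed integer seed.
#' @param rot_range_deg,trans_range_mm half-ranges (> 0).
#' @return A [pose6()].
#' @export
sample_pose <- function(seed, rot_range_deg = 10, trans_range_mm = 20) {
  if (rot_range_deg <= 0 || trans_range_mm <= 0) stop("ranges must be positive")
  withr::with_seed(as.integer(seed), {
    r <- runif(3, -rot_range_deg, rot_range_deg)
    t <- runif(3, -trans_range_mm, trans_range_mm)
    pose_from_degrees(r[1], r[2], r[3], t[1], t[2], t[3])
  })
}

#' Extreme corner pose of the perturbation range
#'
#' All rotation magnitudes at 10 degrees and translations at 20 mm, with
#' caller-chosen signs -- the construction used for held-out test cases.
#'
#' @param signs numeric 6-vector of +-1.
#' @param rot_deg,trans_mm magnitudes.
#' @return A [pose6()].
#' @export
extreme_pose <- function(signs = rep(1, 6), rot_deg = 10, trans_mm = 20) {
  signs <- as.numeric(signs)
  if (length(signs) != 6L || any(abs(signs) != 1))
    stop("signs must be six values of +1 or -1")
  pose_from_degrees(signs[1] * rot_deg, signs[2] * rot_deg, signs[3] * rot_deg,
                    signs[4] * trans_mm, signs[5] * trans_mm, signs[6] * trans_mm)
}

#' Build one benchmark case: biplanar DRRs with ground truth
#'
#' Renders the AP/LAT DRR pair of a (preprocessed) CT posed at `pose`, with
#' the second view at `angle_deg`, applies the contrast variant, and packages
#' the ground-truth pose and landmarks. Rendering is deterministic, so
#' re-running with the same inputs reproduces byte-identical raw DRR grids.
#'
#' @param ct a preprocessed `volume`.
#' @param landmarks a [landmark_set()] in the CT's world frame.
#' @param pose ground-truth [pose6()].
#' @param angle_deg inter-view angle (degrees).
#' @param contrast `"low"`, `"mid"` or `"high"`.
#' @param geometry AP [projection_geometry()]; the isocenter defaults to the
#'   CT's world center.
#' @param seed case seed recorded for provenance.
#' @param id case identifier.
#' @return An object of class `benchmark_case`.
#' @export
generate_case <- function(ct, landmarks, pose, angle_deg = 90,
                          contrast = "mid", geometry = NULL, seed = NA_integer_,
                          id = NULL) {
  stopifnot(inherits(ct, "volume"), inherits(landmarks, "landmark_set"))
  pose <- as_pose6(pose)
  if (is.null(geometry))
    geometry <- projection_geometry(isocenter = volume_center(ct))
  pair <- render_biplanar(ct, pose, geometry, angle_deg = angle_deg)
  structure(list(
    id = id %||% sprintf("case_seed%s", seed),
    drr_ap = contrast_adjust(pair$ap, contrast),
    drr_lat = contrast_adjust(pair$lat, contrast),
    drr_ap_raw = pair$ap, drr_lat_raw = pair$lat,
    pose_gt = pose, angle_deg = angle_deg, contrast = contrast,
    landmarks = landmarks, seed = seed,
    euler_convention = "extrinsic x-y-z (R = Rz * Ry * Rx)",
    geometry = geometry), class = "benchmark_case")
}

#' Simulate the output of a learned biplanar-to-CT reconstruction
#'
#' Stands in for a trained reconstruction network so the 3-D/3-D
#' registration stage can be exercised end to end: the ground-truth anatomy
#' is placed at the (unknown, to the registrar) pose by rigid resampling,
#' then degraded by Gaussian blur, a multiplicative intensity perturbation
#' and additive noise scaled to the clean copy's dynamic range. With
#' `blur_sigma = 0`, `noise_frac = 0`, `intensity_scale = 1` the output is
#' exactly the clean transformed copy.
#'
#' @param ct a `volume` (typically preprocessed).
#' @param pose the [pose6()] at which the anatomy sits.
#' @param blur_sigma Gaussian blur sigma in voxels.
#' @param noise_frac additive noise SD as a fraction of the clean copy's
#'   dynamic range.
#' @param intensity_scale global multiplicative gain.
#' @param seed noise seed.
#' @param center rotation center; default the CT's world center.
#' @return A `volume` on the CT grid.
#' @export
pseudo_reconstruct <- function(ct, pose, blur_sigma = 1, noise_frac = 0.05,
                               intensity_scale = 1, seed = 1, center = NULL) {
  stopifnot(inherits(ct, "volume"))
  if (blur_sigma < 0 || noise_frac < 0)
    stop("blur sigma and noise fraction must be non-negative")
  pose <- as_pose6(pose)
  if (is.null(center)) center <- volume_center(ct)
  out <- resample_rigid(ct, pose_to_matrix(pose, center), ct)
  if (blur_sigma > 0) out <- gaussian_blur_volume(out, blur_sigma)
  if (intensity_scale != 1)
    out <- new_volume(out$voxels * intensity_scale, out$spacing, out$origin)
  if (noise_frac > 0) {
    rng <- diff(range(out$voxels))
    noise <- withr::with_seed(as.integer(seed),
                              array(rnorm(length(out$voxels), 0, noise_frac * rng),
                                    dim(out$voxels)))
    out <- new_volume(out$voxels + noise, out$spacing, out$origin)
  }
  out
}

#' Map the inter-view angle to reconstruction degradation
#'
#' Reconstruction from two views degrades as the views approach each other:
#' the second view then carries mostly redundant information. This is
#' modeled by scaling the simulator's blur and noise by `1 / sin(angle)`
#' (1.0 at 90 degrees, ~1.15 at 60, 2.0 at 30), the simplest monotone
#' information-loss factor that reproduces the expected accuracy ordering
#' across view angles.
#'
#' @param angle_deg inter-view angle in (0, 180).
#' @param base_blur,base_noise degradation at the orthogonal (90 degree)
#'   configuration.
#' @return A list with elements `blur_sigma` and `noise_frac`.
#' @export
angle_degradation <- function(angle_deg, base_blur = 1, base_noise = 0.05) {
  if (angle_deg <= 0 || angle_deg >= 180)
    stop("view angle must lie strictly between 0 and 180 degrees")
  f <- 1 / sin(angle_deg * DEG)
  list(blur_sigma = base_blur * f, noise_frac = base_noise * f)
}

#' Build a seeded benchmark manifest with a train/test split
#'
#' @param n_cases number of cases.
#' @param seed global seed; per-case seeds and the split derive from it.
#' @param split training fraction (default 0.75).
#' @param angle_deg,contrast benchmark variant settings.
#' @param rot_range_deg,trans_range_mm pose sampling ranges.
#' @return A data frame manifest (one row per case) with the ground-truth
#'   pose in degrees/mm, per-case seed and split assignment.
#' @export
build_dataset <- function(n_cases, seed = 1, split = 0.75, angle_deg = 90,
                          contrast = "mid", rot_range_deg = 10,
                          trans_range_mm = 20) {
  if (n_cases < 1) stop("n_cases must be at least 1")
  case_seed <- as.integer(seed) + 7919L * seq_len(n_cases)
  poses <- lapply(case_seed, sample_pose, rot_range_deg = rot_range_deg,
                  trans_range_mm = trans_range_mm)
  n_train <- round(split * n_cases)
  assign <- withr::with_seed(as.integer(seed), sample(seq_len(n_cases)))
  split_lab <- rep("test", n_cases)
  split_lab[assign[seq_len(n_train)]] <- "train"
  pm <- do.call(rbind, lapply(poses, unclass))
  data.frame(
    case_id = sprintf("case_%03d", seq_len(n_cases)),
    seed = case_seed,
    alpha_deg = pm[, 1] / DEG, beta_deg = pm[, 2] / DEG, gamma_deg = pm[, 3] / DEG,
    tx_mm = pm[, 4], ty_mm = pm[, 5], tz_mm = pm[, 6],
    angle_deg = angle_deg, contrast = contrast, split = split_lab,
    euler_convention = "extrinsic x-y-z (R = Rz * Ry * Rx)",
    stringsAsFactors = FALSE)
}

#' Write / read a JSON-lines benchmark manifest
#'
#' @param manifest a data frame from [build_dataset()].
#' @param path output path (`.jsonl`).
#' @return `read_manifest` returns the data frame.
#' @export
write_manifest <- function(manifest, path) {
  lines <- vapply(seq_len(nrow(manifest)), function(i)
    as.character(jsonlite::toJSON(as.list(manifest[i, ]), auto_unbox = TRUE,
                                  digits = NA)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, function(l) as.data.frame(jsonlite::fromJSON(l),
                                                  stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
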