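#' Default run configuration for the end-to-end pipeline
#'
#' A nested list mirroring the YAML config accepted by [run_e2e()] and the
#' command-line entry point. Every field is serialized into the output
#' manifest for provenance.
#'
#' @param n_cases number of benchmark cases.
#' @param seed global integer seed; all per-case seeds derive from it.
#' @param angle_deg inter-view angle.
#' @param contrast contrast variant.
#' @param blur_sigma,noise_frac,intensity_scale pseudo-reconstruction
#'   degradation at 90 degrees; blur and noise are additionally scaled by
#'   the view-angle factor from [angle_degradation()].
#' @param shape,spacing phantom grid.
#' @param detector_px,pixel_spacing,sid,sdd projection geometry.
#' @param registration a [registration_config()] or list of overrides.
#' @param threshold_mm GFR failure threshold.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_cases = 10, seed = 1, angle_deg = 90,
                       contrast = "mid", blur_sigma = 1, noise_frac = 0.05,
                       intensity_scale = 1, shape = c(64, 64, 64),
                       spacing = c(2, 2, 2), detector_px = c(64, 64),
                       pixel_spacing = c(4, 4), sid = 1000, sdd = 1500,
                       registration = registration_config(),
                       threshold_mm = 3) {
  if (n_cases < 1) stop("n_cases must be at least 1")
  if (is.list(registration) && !inherits(registration, "registration_config"))
    registration <- do.call(registration_config, registration)
  structure(list(n_cases = as.integer(n_cases), seed = as.integer(seed),
                 angle_deg = angle_deg, contrast = contrast,
                 blur_sigma = blur_sigma, noise_frac = noise_frac,
                 intensity_scale = intensity_scale,
                 shape = as.integer(rep(shape, length.out = 3)),
                 spacing = rep(as.numeric(spacing), length.out = 3),
                 detector_px = as.integer(rep(detector_px, length.out = 2)),
                 pixel_spacing = rep(as.numeric(pixel_spacing), length.out = 2),
                 sid = sid, sdd = sdd, registration = registration,
                 threshold_mm = threshold_mm),
            class = "run_config")
}

#' @rdname run_config
#' @param path a YAML config file; fields override the defaults.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$registration))
    vals$registration <- do.call(registration_config, vals$registration)
  do.call(run_config, vals)
}

#' Run the full synthetic pipeline: phantom -> DRRs -> reconstruction ->
#' registration -> evaluation
#'
#' For each case a fresh seeded head phantom is generated and preprocessed
#' (ellipse crop + bone threshold); a ground-truth pose is sampled from the
#' benchmark range; biplanar DRRs are rendered at that pose; a pseudo
#' reconstruction of the posed anatomy (degradation scaled by the view
#' angle) is produced as the fixed target; the preprocessed CT is registered
#' to it from the identity initialization; and mTRE/GFR are computed over
#' the phantom landmarks. Rerunning with the same config reproduces the
#' report.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory for volumes, DRRs, manifest and
#'   report.
#' @param verbose print per-case progress.
#' @return An `evaluation_report` with attribute `cases_detail` (per-case
#'   registration results) and `manifest`.
#' @export
run_e2e <- function(config = run_config(), out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  deg <- angle_degradation(config$angle_deg, base_blur = config$blur_sigma,
                           base_noise = config$noise_frac)
  manifest <- build_dataset(config$n_cases, seed = config$seed,
                            angle_deg = config$angle_deg,
                            contrast = config$contrast)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- vector("list", config$n_cases)
  details <- vector("list", config$n_cases)
  for (i in seq_len(config$n_cases)) {
    cs <- manifest$seed[i]
    stage <- "phantom"
    res <- tryCatch({
      ph <- make_phantom(seed = cs, shape = config$shape, spacing = config$spacing)
      stage <- "preprocess"
      pre <- preprocess_ct(ph$volume)
      moving <- pre$volume
      ctr <- volume_center(moving)
      pose_gt <- pose_from_degrees(manifest$alpha_deg[i], manifest$beta_deg[i],
                                   manifest$gamma_deg[i], manifest$tx_mm[i],
                                   manifest$ty_mm[i], manifest$tz_mm[i])
      stage <- "render"
      geom <- projection_geometry(sid = config$sid, sdd = config$sdd,
                                  detector_px = config$detector_px,
                                  pixel_spacing = config$pixel_spacing,
                                  isocenter = ctr)
      case <- generate_case(moving, ph$landmarks, pose_gt,
                            angle_deg = config$angle_deg,
                            contrast = config$contrast, geometry = geom,
                            seed = cs, id = manifest$case_id[i])
      stage <- "reconstruct"
      fixed <- pseudo_reconstruct(moving, pose_gt,
                                  blur_sigma = deg$blur_sigma,
                                  noise_frac = deg$noise_frac,
                                  intensity_scale = config$intensity_scale,
                                  seed = cs)
      stage <- "register"
      reg <- register_volumes(moving, fixed, init = pose6(),
                              config = config$registration, center = ctr)
      if (!is.null(out_dir)) {
        stub <- file.path(out_dir, manifest$case_id[i])
        write_volume(fixed, paste0(stub, "_target.nii.gz"))
        write_drr_png(case$drr_ap, paste0(stub, "_ap.png"))
        write_drr_png(case$drr_lat, paste0(stub, "_lat.png"))
        write_pose_json(reg$pose, paste0(stub, "_pose.json"), center_mm = ctr)
      }
      list(case = list(id = manifest$case_id[i], t_reg = reg$pose,
                       t_gt = pose_gt, landmarks = ph$landmarks, center = ctr),
           reg = reg)
    }, error = function(e) {
      if (!is.null(out_dir))
        write_manifest(manifest[seq_len(i - 1), , drop = FALSE],
                       file.path(out_dir, "partial_manifest.jsonl"))
      stop("pipeline failed at stage '", stage, "' in case ",
           manifest$case_id[i], ": ", conditionMessage(e), call. = FALSE)
    })
    results[[i]] <- res$case
    details[[i]] <- res$reg
    if (verbose)
      message(sprintf("%s: %d iterations, final MSE %.4g",
                      manifest$case_id[i], res$reg$iterations, res$reg$mse))
  }
  report <- evaluate_cases(results, threshold_mm = config$threshold_mm)
  attr(report, "cases_detail") <- details
  attr(report, "manifest") <- manifest
  if (!is.null(out_dir)) {
    write_manifest(manifest, file.path(out_dir, "manifest.jsonl"))
    write_report(report, file.path(out_dir, "report.json"))
    yaml::write_yaml(config_as_list(config), file.path(out_dir, "config.yaml"))
  }
  report
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$registration <- unclass(out$registration)
  out
}

#' Plot methods
#'
#' `autoplot.drr_image` renders a DRR as a raster; `autoplot.registration_result`
#' shows the MSE trajectory over accepted iterations;
#' `autoplot.evaluation_report` shows per-case mTRE against the failure
#' threshold.
#'
#' @param object the object to plot.
#' @param ... unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_point
#'   geom_col geom_hline scale_fill_gradient labs theme_minimal
#' @export
autoplot.drr_image <- function(object, ...) {
  d <- dim(object$pixels)
  df <- data.frame(u = rep(seq_len(d[1]), times = d[2]),
                   v = rep(seq_len(d[2]), each = d[1]),
                   value = as.vector(object$pixels))
  ggplot(df, aes(x = .data$u, y = .data$v, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white") +
    labs(title = paste("DRR,", object$view, "view"), fill = "line\nintegral") +
    theme_minimal()
}

#' @rdname autoplot.drr_image
#' @export
autoplot.registration_result <- function(object, ...) {
  tr <- object$trajectory
  tr$step <- seq_len(nrow(tr))
  ggplot(tr, aes(x = .data$step, y = .data$mse)) +
    geom_line() + geom_point(aes(shape = factor(.data$level))) +
    labs(x = "accepted iterate", y = "MSE", shape = "pyramid\nfactor") +
    theme_minimal()
}

#' @rdname autoplot.drr_image
#' @export
autoplot.evaluation_report <- function(object, ...) {
  df <- object$cases
  ggplot(df, aes(x = .data$id, y = .data$mtre_mm)) +
    geom_col() +
    geom_hline(yintercept = object$threshold_mm, linetype = "dashed") +
    labs(x = NULL, y = "mTRE (mm)") +
    theme_minimal()
}

#' @importFrom ggplot2 .data
#' @export
ggplot2::autoplot
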