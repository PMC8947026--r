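# Pipeline orchestration: filtering -> aponeurosis detection -> fits ->
# elliptic ROI -> fascicle angle -> geometry, per frame; sequence-level
# options (occlusion interpolation, low-pass filtering) on top.

result_columns <- c("frame_index", "alpha_deg", "beta_deg", "phi_deg",
                    "thickness_cm", "fascicle_length_cm",
                    "extrapolated_fraction", "brightness",
                    "interpolated_flag", "method", "time_s", "status")

na_row <- function(frame, cfg, status) {
  data.frame(frame_index = frame$frame_index, alpha_deg = NA_real_,
             beta_deg = NA_real_, phi_deg = NA_real_, thickness_cm = NA_real_,
             fascicle_length_cm = NA_real_, extrapolated_fraction = NA_real_,
             brightness = brightness(frame), interpolated_flag = FALSE,
             method = cfg$apo_method, time_s = frame$timestamp_s,
             status = status)
}

#' Analyse a single frame
#'
#' Runs the full per-frame pipeline and returns one result row. Detection
#' failures do not abort: they yield a row with missing features and the
#' failure message in `status`, so long sequences survive isolated bad
#' frames.
#'
#' @param frame A [pt_frame()].
#' @param cfg A [pt_config()].
#' @param roi_cache Optional `pt_roi` reused in `per_sequence` ellipse mode.
#' @param extrapolate Use the beyond-frame extrapolation construction for
#'   fascicle length.
#' @param keep_fits Attach the aponeurosis fits and ROI as attributes
#'   (`"fits"`, `"roi"`) for overlays and caching.
#' @return A one-row data frame (see [pt_analyze()] for the columns).
#' @export
process_frame <- function(frame, cfg, roi_cache = NULL, extrapolate = FALSE,
                          keep_fits = FALSE) {
  stopifnot(inherits(frame, "pt_frame"), inherits(cfg, "pt_config"))
  out <- tryCatch({
    fas_bin <- fascicle_filter(frame, cfg)
    apo_bin <- aponeurosis_binary(frame, cfg)
    detect <- if (cfg$apo_method == "hough") detect_apo_hough else detect_apo_object
    pts_S <- detect(apo_bin, frame, cfg, "superficial")
    pts_D <- detect(apo_bin, frame, cfg, "deep")
    fit_S <- fit_aponeurosis(pts_S, cfg$o_super, cfg$beta_range_deg)
    fit_D <- fit_aponeurosis(pts_D, cfg$o_deep, cfg$gamma_range_deg)
    roi <- if (!is.null(roi_cache) && cfg$ellipse_mode == "per_sequence") roi_cache
           else build_ellipse(fit_S, fit_D, frame, cfg)
    ang <- estimate_fascicle_angle(fas_bin, roi, cfg)
    geo <- geometry_result(fit_S, fit_D, ang$alpha_deg, frame, cfg,
                           extrapolate = extrapolate)
    row <- data.frame(frame_index = frame$frame_index,
                      alpha_deg = geo$alpha_deg, beta_deg = geo$beta_deg,
                      phi_deg = geo$phi_deg, thickness_cm = geo$thickness_cm,
                      fascicle_length_cm = geo$fascicle_length_cm,
                      extrapolated_fraction = geo$extrapolated_fraction,
                      brightness = brightness(frame),
                      interpolated_flag = FALSE, method = cfg$apo_method,
                      time_s = frame$timestamp_s, status = "ok")
    if (keep_fits) {
      attr(row, "fits") <- list(S = fit_S, D = fit_D)
      attr(row, "roi") <- roi
    }
    row
  }, pt_error = function(e) na_row(frame, cfg, conditionMessage(e)))
  out
}

#' Analyse an ultrasound frame or sequence
#'
#' The main entry point: runs per-frame feature detection (vesselness
#' filtering, aponeurosis inner-edge detection and constrained polynomial
#' fitting, elliptic-ROI weighted-median fascicle angle, trigonometric
#' geometry) over one frame or an ordered sequence, then the optional
#' sequence-level steps in fixed order: occlusion time-interpolation, then
#' zero-phase low-pass filtering. Being a per-frame feature detector the
#' analysis is history-independent: errors do not accumulate over sequence
#' length (no integration drift).
#'
#' @param x A [pt_frame()], a list of frames, or a path (single image file,
#'   directory of frames, or multi-page TIFF; requires `cm_per_px`).
#' @param cfg A [pt_config()].
#' @param cm_per_px Calibration, used only when `x` is a path.
#' @param extrapolate Estimate fascicle length by the beyond-frame
#'   extrapolation construction through the inter-aponeurosis midpoint.
#' @param interpolate Time-interpolate occluded frames (brightness below
#'   `brightness_threshold_rel` of the time-average).
#' @param lowpass Low-pass cut-off in Hz (`NULL` or `cfg$lowpass_cutoff_hz`
#'   default; requires a frame rate from `cfg$frame_rate_hz` or timestamps).
#' @return Object of class `pt_result`: list with `features` (one row per
#'   frame: `frame_index`, `alpha_deg`, `beta_deg`, `phi_deg`,
#'   `thickness_cm`, `fascicle_length_cm`, `extrapolated_fraction`,
#'   `brightness`, `interpolated_flag`, `method`, `time_s`, `status`),
#'   `manifest` (config snapshot, options, per-frame status, package
#'   version) and `config`.
#' @examples
#' ph <- phantom_spec(alpha_true_deg = 25)
#' res <- pt_analyze(render_phantom(ph)$frame, phantom_config(ph))
#' res$features$alpha_deg
#' @export
pt_analyze <- function(x, cfg = pt_config(), cm_per_px = NULL,
                       extrapolate = FALSE, interpolate = FALSE,
                       lowpass = cfg$lowpass_cutoff_hz) {
  frames <- if (inherits(x, "pt_frame")) list(x)
            else if (is.character(x) && length(x) == 1L) {
              if (is.null(cm_per_px))
                pt_stop("pt_validation_error", "cm_per_px is required when x is a path")
              if (dir.exists(x) || grepl("\\.(tif|tiff)$", tolower(x)))
                load_sequence(x, cm_per_px, cfg$frame_rate_hz)
              else list(load_frame(x, cm_per_px))
            } else if (is.list(x) && all(vapply(x, inherits, TRUE, "pt_frame"))) x
            else pt_stop("pt_validation_error",
                         "x must be a pt_frame, a list of pt_frame, or a path")
  if (!length(frames)) pt_stop("pt_validation_error", "no frames to analyse")

  roi_cache <- NULL
  rows <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    row <- process_frame(frames[[i]], cfg, roi_cache = roi_cache,
                         extrapolate = extrapolate,
                         keep_fits = is.null(roi_cache))
    if (is.null(roi_cache) && !is.null(attr(row, "roi")))
      roi_cache <- attr(row, "roi")
    attr(row, "fits") <- NULL; attr(row, "roi") <- NULL
    rows[[i]] <- row
  }
  features <- do.call(rbind, rows)
  if (all(is.na(features$alpha_deg)))
    pt_stop("pt_detection_error", "detection failed on every frame")

  steps <- character(0)
  if (extrapolate) steps <- c(steps, "extrapolate")
  if (interpolate && nrow(features) > 1L) {
    features <- interpolate_occluded(features, cfg$brightness_threshold_rel)
    steps <- c(steps, "interpolate")
  }
  if (!is.null(lowpass) && nrow(features) > 2L) {
    rate <- infer_rate(features, cfg)
    features <- lowpass_features(features, lowpass, rate)
    steps <- c(steps, sprintf("lowpass %.3g Hz", lowpass))
  }
  structure(list(features = features,
                 manifest = list(config = unclass(cfg),
                                 n_frames = nrow(features),
                                 steps = steps,
                                 status = features$status,
                                 version = as.character(utils::packageVersion("pennatrack"))),
                 config = cfg),
            class = "pt_result")
}

infer_rate <- function(features, cfg) {
  if (!is.null(cfg$frame_rate_hz)) return(cfg$frame_rate_hz)
  t <- features$time_s
  if (all(is.finite(t)) && nrow(features) > 1L) {
    dt <- diff(t)
    if (all(dt > 0) && diff(range(dt)) < 1e-9) return(1 / dt[1])
  }
  pt_stop("pt_validation_error",
          "low-pass filtering needs frame_rate_hz or evenly spaced timestamps")
}

#' @export
print.pt_result <- function(x, ...) {
  f <- x$features
  ok <- sum(f$status %in% c("ok", "interpolated"))
  cat(sprintf("<pt_result> %d frame(s), %d valid (%s method%s)\n",
              nrow(f), ok, x$config$apo_method,
              if (length(x$manifest$steps))
                paste0("; steps: ", paste(x$manifest$steps, collapse = ", ")) else ""))
  if (ok) {
    m <- function(v) mean(v[!is.na(v)])
    cat(sprintf("  mean alpha %.2f deg, beta %.2f deg, phi %.2f deg, T %.3f cm, L %.3f cm\n",
                m(f$alpha_deg), m(f$beta_deg), m(f$phi_deg),
                m(f$thickness_cm), m(f$fascicle_length_cm)))
  }
  invisible(x)
}

#' @export
summary.pt_result <- function(object, ...) {
  f <- object$features
  num <- c("alpha_deg", "beta_deg", "phi_deg", "thickness_cm",
           "fascicle_length_cm", "extrapolated_fraction", "brightness")
  stats <- t(vapply(num, function(col) {
    v <- f[[col]][!is.na(f[[col]])]
    if (!length(v)) return(c(mean = NA_real_, sd = NA_real_, min = NA_real_, max = NA_real_))
    c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
      min = min(v), max = max(v))
  }, numeric(4)))
  out <- list(stats = stats, n_frames = nrow(f),
              n_valid = sum(f$status %in% c("ok", "interpolated")),
              n_interpolated = sum(f$interpolated_flag),
              steps = object$manifest$steps)
  class(out) <- "summary.pt_result"
  out
}

#' @export
print.summary.pt_result <- function(x, ...) {
  cat(sprintf("Frames: %d (%d valid, %d interpolated)\n",
              x$n_frames, x$n_valid, x$n_interpolated))
  print(round(x$stats, 4))
  invisible(x)
}

#' @export
as.data.frame.pt_result <- function(x, ...) x$features

#' @export
plot.pt_result <- function(x, features = c("alpha_deg", "phi_deg", "thickness_cm",
                                           "fascicle_length_cm"), ...) {
  f <- x$features
  t <- series_times(f)
  old <- par(mfrow = c(length(features), 1), mar = c(2.5, 4, 1, 1))
  on.exit(par(old))
  labs <- c(alpha_deg = "fascicle angle (deg)", beta_deg = "apo angle (deg)",
            phi_deg = "pennation (deg)", thickness_cm = "thickness (cm)",
            fascicle_length_cm = "fascicle length (cm)")
  for (col in features) {
    plot(t, f[[col]], type = "l", xlab = "", ylab = labs[[col]], ...)
    if (any(f$interpolated_flag))
      points(t[f$interpolated_flag], f[[col]][f$interpolated_flag], col = 2, pch = 16)
  }
  invisible(x)
}

#' Write / read a result table
#'
#' CSV round trip of the per-frame feature table; numeric columns are
#' written at 4-decimal precision.
#'
#' @param x A `pt_result` or its feature data frame.
#' @param path Output CSV path.
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   returns the feature data frame.
#' @export
write_results <- function(x, path) {
  df <- if (inherits(x, "pt_result")) x$features else as.data.frame(x)
  df <- df[, intersect(result_columns, names(df)), drop = FALSE]
  for (col in names(df)) if (is.numeric(df[[col]])) df[[col]] <- round(df[[col]], 4)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) pt_stop("pt_io_error", "no such file: %s", path)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a detection overlay image
#'
#' Saves the frame as PNG with the sampled aponeurosis points and fitted
#' lines burnt in (superficial blue-ish, deep green-ish), for visual
#' inspection of the detection.
#'
#' @param frame A [pt_frame()].
#' @param fits List with elements `S` and `D` (`pt_apo_fit`).
#' @param path Output PNG path.
#' @param points Optional list of `pt_apo_points` to mark.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(frame, fits, path, points = NULL) {
  h <- frame$height_px; w <- frame$width_px
  rgb <- array(frame$pixels, dim = c(h, w, 3))
  paint <- function(rr, cc, col) {
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    for (ch in 1:3) rgb[cbind(rr[ok], cc[ok], ch)] <<- col[ch]
  }
  xs <- seq_len(w)
  paint(round(poly_eval(fits$S$coeffs, xs)), xs, c(0.2, 0.4, 1))
  paint(round(poly_eval(fits$D$coeffs, xs)), xs, c(0.2, 1, 0.4))
  for (p in points) {
    keep <- !is.na(p$ys_px)
    paint(round(p$ys_px[keep]), round(p$xs_px[keep]), c(1, 0.2, 0.2))
  }
  png::writePNG(rgb, path)
  invisible(path)
}
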