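# Overall fascicle angle: elliptic ROI between the fitted aponeuroses,
# Hough transform with rotation de-biasing and ellipse chord-length
# correction, weighted median over the strongest peaks.

#' Elliptic fascicle region of interest
#'
#' Builds the elliptic region spanning between the fitted aponeurosis lines
#' and across the image width: centre `cx` mid-image, horizontal semi-axis
#' `a = width/2 - x_margin`, vertical centre and semi-axis from `S(cx)` and
#' `D(cx)`. The pixel mask is the ellipse interior additionally clipped to
#' lie strictly between the fitted lines, so no aponeurosis pixels leak into
#' the fascicle statistics.
#'
#' @param fit_S,fit_D `pt_apo_fit` objects for the superficial and deep
#'   aponeurosis.
#' @param frame The source [pt_frame()].
#' @param cfg A [pt_config()].
#' @return Object of class `pt_roi`: `center` (x, y), `semi_axis_x`,
#'   `semi_axis_y`, `mask` (logical matrix).
#' @export
build_ellipse <- function(fit_S, fit_D, frame, cfg) {
  h <- frame$height_px; w <- frame$width_px
  cx <- (w + 1) / 2
  a <- w / 2 - cfg$x_margin_px
  xs <- seq_len(w)
  Sx <- poly_eval(fit_S$coeffs, xs)
  Dx <- poly_eval(fit_D$coeffs, xs)
  if (any(Dx <= Sx))
    pt_stop("pt_geometry_error", "fitted aponeurosis lines cross or touch inside the frame")
  Sy <- poly_eval(fit_S$coeffs, cx)
  Dy <- poly_eval(fit_D$coeffs, cx)
  cy <- (Sy + Dy) / 2
  b <- (Dy - Sy) / 2
  if (a <= 0 || b <= 0)
    pt_stop("pt_geometry_error", "degenerate elliptic ROI (semi-axes %.3g, %.3g)", a, b)
  xg <- rep(xs, each = h)
  yg <- rep(seq_len(h), times = w)
  mask <- ((xg - cx) / a)^2 + ((yg - cy) / b)^2 <= 1
  mask <- mask & yg > Sx[xg] & yg < Dx[xg]
  structure(list(center = c(x = cx, y = cy), semi_axis_x = a, semi_axis_y = b,
                 mask = matrix(mask, h, w)),
            class = "pt_roi")
}

#' Chord-length correction of a Hough accumulator
#'
#' Inside an elliptic region, lines at angles aligned with the long axis can
#' collect more votes simply because longer chords fit. Each angle column is
#' divided by the ellipse's maximal chord length at that orientation,
#' `L(theta) = 2ab / sqrt(b^2 cos^2 theta + a^2 sin^2 theta)`, normalised by
#' `max(L)` so corrected values remain comparable across frames. For a
#' circular region the correction is the identity.
#'
#' @param acc A `pt_hough` accumulator.
#' @param roi A `pt_roi`.
#' @return The accumulator with `counts` replaced by corrected (numeric)
#'   values.
#' @export
chord_correction <- function(acc, roi) {
  stopifnot(inherits(acc, "pt_hough"), inherits(roi, "pt_roi"))
  a <- roi$semi_axis_x; b <- roi$semi_axis_y
  th <- deg2rad(acc$theta_deg)
  L <- 2 * a * b / sqrt(b^2 * cos(th)^2 + a^2 * sin(th)^2)
  fac <- L / max(L)
  acc$counts <- sweep(acc$counts * 1.0, 2, fac, "/")
  acc
}

#' Weighted median
#'
#' Sorts angles ascending and returns the smallest angle whose cumulative
#' weight reaches half the total weight.
#'
#' @param angles_deg Numeric vector.
#' @param weights Positive weights of equal length.
#' @return Scalar angle.
#' @export
weighted_median <- function(angles_deg, weights) {
  if (!length(angles_deg)) pt_stop("pt_validation_error", "empty input to weighted_median")
  if (length(angles_deg) != length(weights) || any(weights <= 0))
    pt_stop("pt_validation_error", "weights must be positive and match angles in length")
  o <- order(angles_deg)
  cw <- cumsum(weights[o])
  angles_deg[o][which(cw >= cw[length(cw)] / 2)[1]]
}

#' Estimate the overall fascicle angle
#'
#' Applies the elliptic ROI mask to the binary fascicle image, runs the Hough
#' transform over the eligible fascicle angle range, de-biases the
#' accumulator, applies the chord-length correction, selects the `k_peaks`
#' highest local maxima (3 x 3 accumulator-cell suppression; fewer are used
#' if fewer exist) and returns the weighted median of their angles with the
#' corrected accumulator values as weights. `estimator = "argmax"` instead
#' returns the single most dominant angle; it exists as a reference variant
#' because a lone dominant stripe population can then hijack the estimate,
#' which the weighted median resists.
#'
#' @param fascicle_binary Logical matrix from [fascicle_filter()].
#' @param roi A `pt_roi` from [build_ellipse()].
#' @param cfg A [pt_config()].
#' @param estimator `"weighted_median"` (default) or `"argmax"`.
#' @return Object of class `pt_angle`: `alpha_deg`, `peaks` (data frame of
#'   `theta_deg`, `weight`), `estimator`.
#' @export
estimate_fascicle_angle <- function(fascicle_binary, roi, cfg,
                                    estimator = c("weighted_median", "argmax")) {
  estimator <- match.arg(estimator)
  masked <- fascicle_binary & roi$mask
  if (!any(masked))
    pt_stop("pt_detection_error", "no fascicle pixels inside the elliptic ROI")
  thetas <- theta_axis(cfg$theta_fas_range_deg, cfg$theta_fas_res_deg)
  acc <- hough_lines(masked, thetas)
  acc <- debias_accumulator(acc, masked, cfg$rotation_delta_deg)
  acc <- chord_correction(acc, roi)
  pks <- hough_peaks(acc, cfg$k_peaks)
  if (!length(pks))
    pt_stop("pt_detection_error", "no Hough peaks found in the fascicle ROI")
  ang <- vapply(pks, `[[`, numeric(1), "theta_deg")
  wt <- vapply(pks, `[[`, numeric(1), "value")
  alpha <- if (estimator == "weighted_median") weighted_median(ang, wt) else ang[1]
  structure(list(alpha_deg = alpha,
                 peaks = data.frame(theta_deg = ang, weight = wt),
                 estimator = estimator),
            class = "pt_angle")
}

#' @export
print.pt_angle <- function(x, ...) {
  cat(sprintf("<pt_angle> alpha = %.2f deg (%s over %d peaks)\n",
              x$alpha_deg, x$estimator, nrow(x$peaks)))
  invisible(x)
}
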