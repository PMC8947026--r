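# Muscle geometry: convert aponeurosis fits and fascicle angle into
# pennation angle, muscle thickness and fascicle length, with optional
# beyond-frame extrapolation through the inter-aponeurosis midpoint.

#' Superficial aponeurosis angle
#'
#' The angle beta of the superficial aponeurosis line at the right image
#' border (`x = width - x_margin`), counter-clockwise-positive with up =
#' superficial: `beta = atan(-S'(x))` in degrees (rows grow downward, hence
#' the sign flip).
#'
#' @param fit_S `pt_apo_fit` of the superficial aponeurosis.
#' @param frame The source [pt_frame()].
#' @param x_margin_px Lateral margin in pixels (default 0).
#' @return Angle in degrees.
#' @export
superficial_angle <- function(fit_S, frame, x_margin_px = 0) {
  xr <- frame$width_px - x_margin_px
  rad2deg(atan(-poly_eval(poly_deriv(fit_S$coeffs), xr)))
}

#' Muscle thickness
#'
#' Perpendicular distance from the deep to the superficial aponeurosis line
#' at a horizontal location: `T = |S(x) - D(x)| * cos(beta) * cm_per_px`.
#'
#' @param fit_S,fit_D `pt_apo_fit` objects.
#' @param x_eval_px Horizontal evaluation location (pixels).
#' @param beta_deg Superficial aponeurosis angle (degrees).
#' @param cm_per_px Calibration.
#' @return Thickness in cm.
#' @export
muscle_thickness <- function(fit_S, fit_D, x_eval_px, beta_deg, cm_per_px) {
  Sy <- poly_eval(fit_S$coeffs, x_eval_px)
  Dy <- poly_eval(fit_D$coeffs, x_eval_px)
  if (Dy <= Sy)
    pt_stop("pt_geometry_error", "aponeurosis lines cross at x = %.1f px", x_eval_px)
  abs(Sy - Dy) * cos(deg2rad(beta_deg)) * cm_per_px
}

#' Fascicle length from thickness and pennation angle
#'
#' `L = T / sin(phi)`, valid for pennation angles strictly inside (0, 90)
#' degrees.
#'
#' @param thickness_cm Muscle thickness (cm).
#' @param phi_deg Pennation angle (degrees).
#' @return Fascicle length in cm.
#' @export
fascicle_length <- function(thickness_cm, phi_deg) {
  if (phi_deg <= 0 || phi_deg >= 90)
    pt_stop("pt_geometry_error", "pennation angle %.2f deg outside (0, 90)", phi_deg)
  thickness_cm / sin(deg2rad(phi_deg))
}

#' Extrapolated fascicle geometry
#'
#' Constructs the fascicle of interest as the straight line through the
#' midpoint `M = (w/2, (S(w/2) + D(w/2)) / 2)` at the fascicle angle
#' `alpha`, intersects it with the polynomial extensions of the fitted
#' aponeurosis lines (bracketing outward in half-width steps up to five
#' image widths, first sign change refined by root finding), and reports the
#' Euclidean distance between the intersections as the fascicle length. The
#' construction through the midpoint spreads any beyond-frame extrapolation
#' equally over the left and right sides of the image. The fraction of the
#' fascicle lying outside the frame is reported, with a warning flag once it
#' exceeds `extrap_warn_fraction`.
#'
#' @param fit_S,fit_D `pt_apo_fit` objects.
#' @param alpha_deg Fascicle angle (degrees, inside the eligible range).
#' @param frame The source [pt_frame()].
#' @param cfg A [pt_config()].
#' @return Object of class `pt_geometry`: `alpha_deg`, `beta_deg`,
#'   `phi_deg`, `thickness_cm` (at the configured evaluation location),
#'   `fascicle_length_cm`, `x_eval_px`, `extrapolated_fraction`,
#'   `extrap_warning`, `midpoint_M`, `image_width_px`.
#' @export
extrapolated_geometry <- function(fit_S, fit_D, alpha_deg, frame, cfg) {
  geometry_result(fit_S, fit_D, alpha_deg, frame, cfg, extrapolate = TRUE)
}

# Shared geometry computation. In non-extrapolated mode fascicle length is
# the closed form T / sin(phi) at the evaluation abscissa; the extrapolated
# fraction of the midpoint fascicle is computed in either mode for the
# warning diagnostic.
geometry_result <- function(fit_S, fit_D, alpha_deg, frame, cfg, extrapolate = FALSE) {
  w <- frame$width_px
  beta <- superficial_angle(fit_S, frame, cfg$x_margin_px)
  phi <- alpha_deg - beta
  x_eval <- cfg$x_eval_rel * w
  x_eval <- min(max(x_eval, 1), w)
  thick <- muscle_thickness(fit_S, fit_D, x_eval, beta, frame$cm_per_px)
  if (phi <= 0 || phi >= 90)
    pt_stop("pt_geometry_error", "pennation angle %.2f deg outside (0, 90)", phi)

  xm <- (w + 1) / 2
  ym <- (poly_eval(fit_S$coeffs, xm) + poly_eval(fit_D$coeffs, xm)) / 2
  ta <- tan(deg2rad(alpha_deg))
  gS <- function(x) poly_eval(fit_S$coeffs, x) - (ym - ta * (x - xm))
  gD <- function(x) poly_eval(fit_D$coeffs, x) - (ym - ta * (x - xm))
  # the midpoint-fascicle construction; in non-extrapolated mode an
  # out-of-reach intersection (very flat fascicle) only voids the
  # extrapolated-fraction diagnostic, not the frame
  ext <- tryCatch({
    xs_i <- bracket_root(gS, xm, +1, w)
    xd_i <- bracket_root(gD, xm, -1, w)
    p_s <- c(xs_i, ym - ta * (xs_i - xm))
    p_d <- c(xd_i, ym - ta * (xd_i - xm))
    dx_total <- abs(xs_i - xd_i)
    lo <- min(xs_i, xd_i); hi <- max(xs_i, xd_i)
    dx_inside <- max(0, min(hi, w + 0.5) - max(lo, 0.5))
    list(len_px = sqrt(sum((p_s - p_d)^2)),
         frac = if (dx_total > 0) 1 - dx_inside / dx_total else 0)
  }, pt_extrapolation_error = function(e) {
    if (extrapolate) stop(e)
    list(len_px = NA_real_, frac = NA_real_)
  })
  frac <- ext$frac

  L <- if (extrapolate) ext$len_px * frame$cm_per_px else fascicle_length(thick, phi)
  structure(list(alpha_deg = alpha_deg, beta_deg = beta, phi_deg = phi,
                 thickness_cm = thick, fascicle_length_cm = L,
                 x_eval_px = x_eval,
                 extrapolated_fraction = frac,
                 extrap_warning = isTRUE(frac > cfg$extrap_warn_fraction),
                 midpoint_M = c(x = xm, y = ym),
                 image_width_px = w,
                 extrapolate = extrapolate),
            class = "pt_geometry")
}

# First sign change of g along direction dirn from x0, probed in half-width
# steps out to five image widths, refined by uniroot.
bracket_root <- function(g, x0, dirn, w) {
  step <- 0.5 * w * dirn
  a <- x0; ga <- g(a)
  for (k in 1:10) {
    b <- a + step
    gb <- g(b)
    if (is.finite(ga) && is.finite(gb) && sign(ga) != sign(gb)) {
      r <- stats::uniroot(g, lower = min(a, b), upper = max(a, b),
                          tol = 1e-10 * max(1, w))$root
      return(r)
    }
    a <- b; ga <- gb
  }
  pt_stop("pt_extrapolation_error",
          "no aponeurosis intersection within 5 image widths (direction %+d)", dirn)
}

#' @export
print.pt_geometry <- function(x, ...) {
  cat(sprintf(paste0("<pt_geometry> alpha %.2f deg, beta %.2f deg, phi %.2f deg, ",
                     "T %.3f cm, L %.3f cm (%.0f%% extrapolated%s)\n"),
              x$alpha_deg, x$beta_deg, x$phi_deg, x$thickness_cm,
              x$fascicle_length_cm, 100 * x$extrapolated_fraction,
              if (x$extrap_warning) ", WARNING" else ""))
  invisible(x)
}
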