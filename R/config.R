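#' Algorithm configuration
#'
#' Builds the full set of named parameters steering the analysis pipeline,
#' validated against the geometric assumptions of pennate muscle imaging
#' (superficial aponeurosis above the deep one, fascicles in the first
#' quadrant, fascicles thinner than aponeuroses).
#'
#' @param d_superficial,d_deep Relative depth ranges `c(lo, hi)` (fractions of
#'   image height) in which the superficial and deep aponeuroses are searched.
#'   Must be ordered and non-overlapping: `0 <= sup_lo < sup_hi <= deep_lo <
#'   deep_hi <= 1`.
#' @param sigma_fas_px,sigma_apo_px Vesselness scales (pixels) for fascicles
#'   and aponeuroses. A structure of full thickness about `2*sigma` pixels
#'   responds maximally. Fascicles are thinner, so `sigma_fas_px <
#'   sigma_apo_px` is enforced.
#' @param t_fas,t_apo Thresholds in `[0, 1]`. `t_fas`/`t_apo` are applied to
#'   the max-normalised vesselness response; `t_apo` is additionally applied
#'   to the raw grayscale when building the aponeurosis mask (and when the
#'   aponeurosis vesselness filter is skipped), making both
#'   device-independent.
#' @param theta_apo_res_deg,theta_fas_res_deg Hough angle resolutions
#'   (degrees) for aponeurosis and fascicle line detection.
#' @param theta_fas_range_deg Eligible fascicle angles `c(lo, hi)`, a subset
#'   of (0, 90) degrees (first-quadrant assumption).
#' @param n_apox Number of equidistant horizontal locations at which
#'   aponeurosis inner edges are sampled (`>= 2`).
#' @param x_margin_px Pixels cropped from each lateral border before sampling.
#' @param l_ratio_max Length-ratio threshold in (0, 1) used by the object
#'   detection method to disambiguate the two longest candidate objects.
#' @param o_super,o_deep Polynomial orders (`>= 1`) of the superficial and
#'   deep aponeurosis line fits.
#' @param beta_range_deg,gamma_range_deg Eligible superficial / deep
#'   aponeurosis angle ranges (degrees); they bound both the Hough search and
#'   the fitted lines' slopes.
#' @param k_peaks Number of Hough accumulator peaks entering the
#'   weighted-median fascicle angle (`>= 1`).
#' @param apo_method Aponeurosis detection method, `"hough"` (straight-line,
#'   default) or `"object"` (connected components; handles curved
#'   aponeuroses).
#' @param use_apo_filter Run the aponeurosis vesselness/smoothing chain before
#'   detection. Recommended (and defaulted) for the object method; the Hough
#'   method works on the thresholded raw image and skips it by default.
#' @param ellipse_mode `"per_sequence"` (elliptic fascicle ROI built once from
#'   the first successfully analysed frame) or `"per_image"` (rebuilt every
#'   frame).
#' @param rotation_delta_deg Rotation angle (degrees, not a multiple of 45)
#'   used to de-bias the Hough accumulator at horizontal / vertical / diagonal
#'   angles.
#' @param extrap_warn_fraction Warn when more than this fraction of the
#'   estimated fascicle lies outside the image frame.
#' @param brightness_threshold_rel Occlusion threshold: frames with mean
#'   brightness below this fraction of the sequence's time-average are
#'   time-interpolated when interpolation is enabled.
#' @param lowpass_cutoff_hz Optional low-pass cut-off (Hz) for feature time
#'   series; `NULL` disables filtering.
#' @param frame_rate_hz Optional acquisition frame rate (Hz).
#' @param x_eval_rel Horizontal evaluation location for thickness and fascicle
#'   length, as a fraction of image width (default mid-image).
#' @param frangi_beta,frangi_c Vesselness constants: blob-suppression
#'   `frangi_beta` (default 0.5) and structure sensitivity `frangi_c`
#'   (default `NULL` = half the maximum Hessian norm of each image). Advanced
#'   overrides.
#'
#' @return An object of class `pt_config` (a validated named list).
#' @examples
#' cfg <- pt_config(d_superficial = c(0.05, 0.30), d_deep = c(0.55, 0.95))
#' cfg$sigma_fas_px
#' @export
pt_config <- function(d_superficial = c(0.00, 0.35),
                      d_deep = c(0.55, 1.00),
                      sigma_fas_px = 2,
                      sigma_apo_px = 8,
                      t_fas = 0.2,
                      t_apo = 0.2,
                      theta_apo_res_deg = 0.5,
                      theta_fas_res_deg = 0.5,
                      theta_fas_range_deg = c(5, 80),
                      n_apox = 20,
                      x_margin_px = 10,
                      l_ratio_max = 0.5,
                      o_super = 1,
                      o_deep = 1,
                      beta_range_deg = c(-20, 20),
                      gamma_range_deg = c(-20, 20),
                      k_peaks = 10,
                      apo_method = c("hough", "object"),
                      use_apo_filter = NULL,
                      ellipse_mode = c("per_sequence", "per_image"),
                      rotation_delta_deg = 5,
                      extrap_warn_fraction = 0.5,
                      brightness_threshold_rel = 0.5,
                      lowpass_cutoff_hz = NULL,
                      frame_rate_hz = NULL,
                      x_eval_rel = 0.5,
                      frangi_beta = 0.5,
                      frangi_c = NULL) {
  apo_method <- match.arg(apo_method)
  ellipse_mode <- match.arg(ellipse_mode)
  if (is.null(use_apo_filter)) use_apo_filter <- identical(apo_method, "object")

  cfg <- list(
    d_superficial = as.numeric(d_superficial), d_deep = as.numeric(d_deep),
    sigma_fas_px = sigma_fas_px, sigma_apo_px = sigma_apo_px,
    t_fas = t_fas, t_apo = t_apo,
    theta_apo_res_deg = theta_apo_res_deg,
    theta_fas_res_deg = theta_fas_res_deg,
    theta_fas_range_deg = as.numeric(theta_fas_range_deg),
    n_apox = as.integer(n_apox), x_margin_px = x_margin_px,
    l_ratio_max = l_ratio_max,
    o_super = as.integer(o_super), o_deep = as.integer(o_deep),
    beta_range_deg = as.numeric(beta_range_deg),
    gamma_range_deg = as.numeric(gamma_range_deg),
    k_peaks = as.integer(k_peaks),
    apo_method = apo_method, use_apo_filter = isTRUE(use_apo_filter),
    ellipse_mode = ellipse_mode,
    rotation_delta_deg = rotation_delta_deg,
    extrap_warn_fraction = extrap_warn_fraction,
    brightness_threshold_rel = brightness_threshold_rel,
    lowpass_cutoff_hz = lowpass_cutoff_hz,
    frame_rate_hz = frame_rate_hz,
    x_eval_rel = x_eval_rel,
    frangi_beta = frangi_beta, frangi_c = frangi_c)
  class(cfg) <- "pt_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, msg, ...) if (!ok) pt_stop("pt_validation_error", msg, ...)
  ds <- cfg$d_superficial; dd <- cfg$d_deep
  chk(length(ds) == 2 && length(dd) == 2, "depth ranges must be length-2 [lo, hi]")
  chk(0 <= ds[1] && ds[1] < ds[2] && ds[2] <= dd[1] && dd[1] < dd[2] && dd[2] <= 1,
      "depth regions must be ordered and non-overlapping: 0 <= sup_lo < sup_hi <= deep_lo < deep_hi <= 1")
  chk(cfg$sigma_fas_px > 0 && cfg$sigma_apo_px > 0, "vesselness scales must be positive")
  chk(cfg$sigma_fas_px < cfg$sigma_apo_px,
      "sigma_fas_px must be smaller than sigma_apo_px (fascicles are thinner than aponeuroses)")
  chk(cfg$t_fas >= 0 && cfg$t_fas <= 1 && cfg$t_apo >= 0 && cfg$t_apo <= 1,
      "thresholds must lie in [0, 1]")
  tr <- cfg$theta_fas_range_deg
  chk(length(tr) == 2 && tr[1] < tr[2] && tr[1] > 0 && tr[2] < 90,
      "theta_fas_range_deg must be a subset of (0, 90) degrees")
  chk(cfg$theta_apo_res_deg > 0 && cfg$theta_fas_res_deg > 0,
      "Hough angle resolutions must be positive")
  chk(cfg$k_peaks >= 1L, "k_peaks must be >= 1")
  chk(cfg$n_apox >= 2L, "n_apox must be >= 2")
  chk(cfg$x_margin_px >= 0, "x_margin_px must be nonnegative")
  chk(cfg$l_ratio_max > 0 && cfg$l_ratio_max < 1, "l_ratio_max must lie in (0, 1)")
  chk(cfg$o_super >= 1L && cfg$o_deep >= 1L, "polynomial orders must be >= 1")
  chk(abs(cfg$rotation_delta_deg %% 45) > 1e-9,
      "rotation_delta_deg must not be a multiple of 45 degrees")
  chk(cfg$extrap_warn_fraction >= 0, "extrap_warn_fraction must be nonnegative")
  chk(cfg$x_eval_rel >= 0 && cfg$x_eval_rel <= 1, "x_eval_rel must lie in [0, 1]")
  chk(cfg$frangi_beta > 0, "frangi_beta must be positive")
  invisible(cfg)
}

#' @export
print.pt_config <- function(x, ...) {
  cat("<pt_config>\n")
  cat(sprintf("  aponeurosis method : %s (vesselness filter: %s)\n",
              x$apo_method, if (x$use_apo_filter) "on" else "off"))
  cat(sprintf("  depth regions      : superficial [%.2f, %.2f], deep [%.2f, %.2f]\n",
              x$d_superficial[1], x$d_superficial[2], x$d_deep[1], x$d_deep[2]))
  cat(sprintf("  vesselness scales  : sigma_fas %.3g px, sigma_apo %.3g px (t_fas %.2f, t_apo %.2f)\n",
              x$sigma_fas_px, x$sigma_apo_px, x$t_fas, x$t_apo))
  cat(sprintf("  fascicle angles    : [%.1f, %.1f] deg at %.2g deg, %d peaks\n",
              x$theta_fas_range_deg[1], x$theta_fas_range_deg[2],
              x$theta_fas_res_deg, x$k_peaks))
  invisible(x)
}

#' Read / write a configuration file
#'
#' Configurations are stored as flat YAML key-value files mirroring the
#' [pt_config()] argument names; unknown keys are rejected so typos fail loudly.
#'
#' @param path File path.
#' @return `read_config()` returns a `pt_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) pt_stop("pt_io_error", "config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pt_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    pt_stop("pt_validation_error", "unknown config keys: %s",
            paste(unknown, collapse = ", "))
  do.call(pt_config, vals)
}

#' @param cfg A `pt_config` object.
#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pt_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
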