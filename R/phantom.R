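# Ground-truthed synthetic pennate-muscle phantoms: two bright
# quasi-horizontal aponeurosis bands, oblique fascicle stripes terminating
# exactly at the bands' inner edges, multiplicative speckle, and optional
# per-frame brightness drops emulating probe occlusion.
#
# Default band and stripe thicknesses equal the corresponding vesselness
# scales (band = sigma_apo, stripe = sigma_fas): the filter chain's
# smoothing SD is half a structure thickness, i.e. sigma/2, which pins the
# thickness-to-scale pairing at 1:1; the edge-trim compensation of the
# object detection method is consistent only under that pairing.

#' Phantom specification
#'
#' Describes a synthetic pennate-muscle image or sequence with known ground
#' truth. Aponeurosis band centre lines are polynomials in `x` (ascending
#' pixel coefficients, depth vs column); fascicle stripes run at
#' `alpha_true_deg` between the bands' inner edges, so the ground-truth
#' insertion points are well defined. Speckle is multiplicative mean-one
#' log-normal with log-SD `speckle_sigma` (a standard B-mode approximation),
#' seeded and reproducible.
#'
#' @param height_px,width_px Image size in pixels.
#' @param cm_per_px Isotropic calibration.
#' @param S_true,D_true Ascending polynomial coefficients of the superficial
#'   and deep band centre lines (row vs column).
#' @param alpha_true_deg True fascicle angle (degrees, CCW-positive, up =
#'   superficial).
#' @param band_thickness_px,stripe_thickness_px,stripe_spacing_px Band and
#'   stripe geometry; the inner-edge separation must be at least
#'   `4 * stripe_thickness_px` everywhere.
#' @param band_intensity,stripe_intensity,background_intensity Intensities in
#'   `[0, 1]`, ordered `background < stripe <= band`.
#' @param speckle_sigma Log-SD of the multiplicative speckle (`0` disables).
#' @param seed Integer seed; frame `i` uses `seed + i`.
#' @param n_frames Number of frames for sequences.
#' @param alpha_trajectory Optional per-frame true fascicle angles (length
#'   `n_frames`).
#' @param thickness_trajectory Optional per-frame true inner-edge muscle
#'   thickness (cm); requires constant (order-0) `S_true` and `D_true`, whose
#'   deep intercept is adjusted per frame.
#' @param occluded_frames 0-based indices of frames whose brightness is
#'   scaled by `occlusion_factor`.
#' @param occlusion_factor Brightness scale of occluded frames.
#' @param outlier_angle_deg,outlier_offsets_px,outlier_intensity Optional
#'   second stripe population for robustness experiments: stripes at this
#'   angle drawn at the given signed line distances (same parameterisation
#'   as the Hough transform) with the given intensity.
#' @return Object of class `pt_phantom_spec`.
#' @export
phantom_spec <- function(height_px = 320, width_px = 320, cm_per_px = 0.01,
                         S_true = 60, D_true = 240, alpha_true_deg = 25,
                         band_thickness_px = 8,
                         stripe_thickness_px = 2, stripe_spacing_px = 14,
                         band_intensity = 0.9, stripe_intensity = 0.65,
                         background_intensity = 0.08,
                         speckle_sigma = 0, seed = 42L, n_frames = 1L,
                         alpha_trajectory = NULL, thickness_trajectory = NULL,
                         occluded_frames = integer(0), occlusion_factor = 0.3,
                         outlier_angle_deg = NULL, outlier_offsets_px = NULL,
                         outlier_intensity = NULL) {
  spec <- list(height_px = as.integer(height_px), width_px = as.integer(width_px),
               cm_per_px = cm_per_px,
               S_true = as.numeric(S_true), D_true = as.numeric(D_true),
               alpha_true_deg = alpha_true_deg,
               band_thickness_px = band_thickness_px,
               stripe_thickness_px = stripe_thickness_px,
               stripe_spacing_px = stripe_spacing_px,
               band_intensity = band_intensity,
               stripe_intensity = stripe_intensity,
               background_intensity = background_intensity,
               speckle_sigma = speckle_sigma, seed = as.integer(seed),
               n_frames = as.integer(n_frames),
               alpha_trajectory = alpha_trajectory,
               thickness_trajectory = thickness_trajectory,
               occluded_frames = as.integer(occluded_frames),
               occlusion_factor = occlusion_factor,
               outlier_angle_deg = outlier_angle_deg,
               outlier_offsets_px = outlier_offsets_px,
               outlier_intensity = outlier_intensity)
  class(spec) <- "pt_phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  chk <- function(ok, msg, ...) if (!ok) pt_stop("pt_validation_error", msg, ...)
  xs <- seq_len(spec$width_px)
  sep <- inner_deep(spec, xs) - inner_sup(spec, xs)
  chk(all(sep >= 4 * spec$stripe_thickness_px),
      "inner-edge separation must be >= 4 * stripe_thickness_px everywhere")
  chk(spec$background_intensity < spec$stripe_intensity &&
        spec$stripe_intensity <= spec$band_intensity,
      "intensities must be ordered: background < stripe <= band")
  chk(spec$speckle_sigma >= 0, "speckle_sigma must be nonnegative")
  chk(spec$height_px >= 16L && spec$width_px >= 16L, "phantom must be at least 16 x 16")
  if (!is.null(spec$thickness_trajectory))
    chk(length(spec$S_true) == 1L && length(spec$D_true) == 1L,
        "thickness_trajectory requires constant (order-0) S_true and D_true")
  for (tr in c("alpha_trajectory", "thickness_trajectory"))
    if (!is.null(spec[[tr]]))
      chk(length(spec[[tr]]) == spec$n_frames,
          "%s must have length n_frames (%d)", tr, spec$n_frames)
  invisible(spec)
}

inner_sup <- function(spec, x) poly_eval(spec$S_true, x) + spec$band_thickness_px / 2
inner_deep <- function(spec, x) poly_eval(spec$D_true, x) - spec$band_thickness_px / 2

# Evaluate expression with a temporary RNG seed, restoring the global state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Spec effective at a given frame index (trajectories applied).
spec_at_frame <- function(spec, frame_index) {
  i <- frame_index + 1L
  if (!is.null(spec$alpha_trajectory)) spec$alpha_true_deg <- spec$alpha_trajectory[i]
  if (!is.null(spec$thickness_trajectory)) {
    t_px <- spec$thickness_trajectory[i] / spec$cm_per_px
    spec$D_true <- spec$S_true[1] + spec$band_thickness_px + t_px
  }
  spec
}

#' Render one phantom frame with ground truth
#'
#' Draws the two aponeurosis bands centred on `S_true` / `D_true`, the
#' oblique fascicle stripes strictly between the bands' inner edges, applies
#' seeded multiplicative speckle and the occlusion brightness scale if the
#' frame is occluded, clips to `[0, 1]`, and returns the frame together with
#' the ground-truth geometry (alpha; beta from the right-border derivative of
#' the superficial line; inner-edge thickness and fascicle length at the
#' mid-image evaluation abscissa, via the same trigonometric definitions the
#' pipeline estimates).
#'
#' @param spec A [phantom_spec()].
#' @param frame_index 0-based frame index (selects trajectory values, the
#'   speckle stream and occlusion).
#' @return List with elements `frame` (a [pt_frame()]) and `truth` (list:
#'   `alpha_deg`, `beta_deg`, `phi_deg`, `thickness_cm`,
#'   `fascicle_length_cm`, `x_eval_px`, `occluded`).
#' @export
render_phantom <- function(spec, frame_index = 0L) {
  stopifnot(inherits(spec, "pt_phantom_spec"))
  spec <- spec_at_frame(validate_phantom_spec(spec), frame_index)
  h <- spec$height_px; w <- spec$width_px
  xg <- rep(seq_len(w), each = h)
  yg <- rep(seq_len(h), times = w)

  img <- rep(spec$background_intensity, h * w)
  Sx <- poly_eval(spec$S_true, xg)
  Dx <- poly_eval(spec$D_true, xg)
  bt2 <- spec$band_thickness_px / 2
  in_band <- abs(yg - Sx) <= bt2 | abs(yg - Dx) <= bt2
  between <- yg > Sx + bt2 & yg < Dx - bt2

  a <- deg2rad(spec$alpha_true_deg)
  cc <- xg * sin(a) + yg * cos(a)
  sp <- spec$stripe_spacing_px
  dist <- abs((cc + sp / 2) %% sp - sp / 2)
  in_stripe <- between & dist <= spec$stripe_thickness_px / 2
  img[in_stripe] <- spec$stripe_intensity
  if (!is.null(spec$outlier_angle_deg)) {
    a2 <- deg2rad(spec$outlier_angle_deg)
    c2 <- xg * sin(a2) + yg * cos(a2)
    hit <- rep(FALSE, length(c2))
    for (off in spec$outlier_offsets_px)
      hit <- hit | abs(c2 - off) <= spec$stripe_thickness_px / 2
    inten <- if (is.null(spec$outlier_intensity)) spec$stripe_intensity else spec$outlier_intensity
    img[between & hit] <- inten
  }
  img[in_band] <- spec$band_intensity

  if (spec$speckle_sigma > 0) {
    s <- spec$speckle_sigma
    mult <- with_seed(spec$seed + frame_index,
                      exp(stats::rnorm(h * w, mean = -s^2 / 2, sd = s)))
    img <- img * mult
  }
  occluded <- frame_index %in% spec$occluded_frames
  if (occluded) img <- img * spec$occlusion_factor
  img <- pmin(pmax(img, 0), 1)

  frame <- pt_frame(matrix(img, h, w), spec$cm_per_px, frame_index = frame_index,
                    timestamp_s = NA_real_)
  list(frame = frame, truth = phantom_truth(spec, occluded))
}

phantom_truth <- function(spec, occluded = FALSE) {
  w <- spec$width_px
  beta <- rad2deg(atan(-poly_eval(poly_deriv(spec$S_true), w)))
  x_eval <- 0.5 * w
  t_px <- inner_deep(spec, x_eval) - inner_sup(spec, x_eval)
  thick <- t_px * cos(deg2rad(beta)) * spec$cm_per_px
  phi <- spec$alpha_true_deg - beta
  list(alpha_deg = spec$alpha_true_deg, beta_deg = beta, phi_deg = phi,
       thickness_cm = thick,
       fascicle_length_cm = thick / sin(deg2rad(phi)),
       x_eval_px = x_eval, occluded = occluded)
}

#' Render a phantom sequence
#'
#' Renders `n_frames` frames with the per-frame true fascicle angle and
#' thickness taken from the trajectories (constant when absent); frame `i`
#' gets timestamp `i / frame_rate_hz` when a rate is given.
#'
#' @param spec A [phantom_spec()].
#' @param frame_rate_hz Optional frame rate for timestamps.
#' @return List of `list(frame, truth)` pairs of length `n_frames`.
#' @export
render_sequence <- function(spec, frame_rate_hz = NULL) {
  stopifnot(inherits(spec, "pt_phantom_spec"))
  validate_phantom_spec(spec)
  lapply(seq_len(spec$n_frames) - 1L, function(i) {
    out <- render_phantom(spec, frame_index = i)
    if (!is.null(frame_rate_hz)) out$frame$timestamp_s <- i / frame_rate_hz
    out
  })
}

#' Configuration matched to a phantom
#'
#' Derives depth regions hugging the phantom's aponeurosis bands — from
#' 12 px outside each band's outer edge to `sigma_apo_px / 4` px beyond its
#' inner edge (the overshoot the object method's outward shift compensates)
#' — emulating the once-per-dataset region selection an operator performs on
#' real images. All remaining arguments are forwarded to [pt_config()].
#'
#' @param spec A [phantom_spec()].
#' @param ... Overrides forwarded to [pt_config()].
#' @return A [pt_config()].
#' @export
phantom_config <- function(spec, ...) {
  h <- spec$height_px
  xs <- seq_len(spec$width_px)
  args <- list(...)
  pad_in <- (if (!is.null(args$sigma_apo_px)) args$sigma_apo_px else 8) / 4
  bt2 <- spec$band_thickness_px / 2
  sup_top <- max(1, floor(min(poly_eval(spec$S_true, xs)) - bt2 - 12))
  sup_bot <- min(h, ceiling(max(inner_sup(spec, xs)) + pad_in))
  deep_top <- max(1, floor(min(inner_deep(spec, xs)) - pad_in))
  deep_bot <- min(h, ceiling(max(poly_eval(spec$D_true, xs)) + bt2 + 12))
  defaults <- list(d_superficial = c((sup_top - 1) / h, sup_bot / h),
                   d_deep = c((deep_top - 1) / h, deep_bot / h))
  do.call(pt_config, utils::modifyList(defaults, args))
}
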