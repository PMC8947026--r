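# Per-sequence post-processing: brightness diagnostics, occlusion
# time-interpolation, zero-phase low-pass filtering, and the RMSD/MAD
# agreement metrics.

#' Image brightness
#'
#' Arithmetic mean of all pixel values (0-1); a per-frame occlusion
#' diagnostic.
#'
#' @param frame A [pt_frame()].
#' @return Scalar in `[0, 1]`.
#' @export
brightness <- function(frame) {
  stopifnot(inherits(frame, "pt_frame"))
  mean(frame$pixels)
}

# The feature series is the per-frame result table (one row per frame, see
# pt_analyze) with columns frame_index, time_s, alpha_deg, beta_deg,
# phi_deg, thickness_cm, fascicle_length_cm, extrapolated_fraction,
# brightness, interpolated_flag, method, status.

series_times <- function(df) {
  t <- df$time_s
  if (all(is.finite(t)) && !is.unsorted(t, strictly = TRUE)) return(t)
  as.numeric(df$frame_index)
}

#' Time-interpolate occluded frames
#'
#' Frames whose brightness falls below `threshold_rel` times the
#' time-average brightness of the sequence (default 50%) are treated as
#' occluded: their detected features alpha, beta and thickness are replaced
#' by linear interpolation in time between the nearest valid neighbours
#' (nearest-valid extension at the boundaries), the derived pennation angle
#' and fascicle length are recomputed, and `interpolated_flag` is set.
#' Frames with failed detection (`NA` features) are filled the same way.
#' The operation is idempotent.
#'
#' @param series Feature data frame as produced by [pt_analyze()].
#' @param threshold_rel Occlusion threshold relative to the time-mean
#'   brightness (default 0.5).
#' @return The series with occluded rows interpolated.
#' @export
interpolate_occluded <- function(series, threshold_rel = 0.5) {
  df <- as.data.frame(series)
  thr <- threshold_rel * mean(df$brightness)
  occl <- df$brightness < thr | is.na(df$alpha_deg)
  valid <- !occl
  if (sum(valid) < 2L)
    pt_stop("pt_validation_error",
            "time-interpolation needs at least 2 valid frames (%d available)", sum(valid))
  if (!any(occl)) return(df)
  t <- series_times(df)
  for (col in c("alpha_deg", "beta_deg", "thickness_cm")) {
    df[[col]][occl] <- approx(t[valid], df[[col]][valid], xout = t[occl],
                              method = "linear", rule = 2)$y
  }
  df$phi_deg[occl] <- df$alpha_deg[occl] - df$beta_deg[occl]
  df$fascicle_length_cm[occl] <-
    df$thickness_cm[occl] / sin(deg2rad(df$phi_deg[occl]))
  df$interpolated_flag[occl] <- TRUE
  df$status[occl] <- "interpolated"
  df
}

#' Zero-phase low-pass filtering of feature time series
#'
#' Applies a second-order Butterworth low-pass forward and backward
#' (zero phase, DC gain 1) to the independent detected features alpha, beta
#' and thickness, then recomputes the derived pennation angle and fascicle
#' length so the trigonometric identities continue to hold row-wise. Each
#' series is filtered about its mean, so constant series pass through
#' unchanged. Series length and timestamps are preserved.
#'
#' @param series Feature data frame as produced by [pt_analyze()]; must
#'   contain no missing features (interpolate first).
#' @param cutoff_hz Cut-off frequency (Hz), strictly below the Nyquist
#'   frequency `frame_rate_hz / 2`.
#' @param frame_rate_hz Acquisition rate (Hz).
#' @return The filtered series.
#' @export
lowpass_features <- function(series, cutoff_hz, frame_rate_hz) {
  df <- as.data.frame(series)
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= frame_rate_hz / 2)
    pt_stop("pt_validation_error",
            "cutoff (%.3g Hz) must lie in (0, Nyquist = %.3g Hz)", cutoff_hz, frame_rate_hz / 2)
  if (anyNA(df$alpha_deg))
    pt_stop("pt_validation_error", "series contains missing features; interpolate first")
  bf <- signal::butter(2, cutoff_hz / (frame_rate_hz / 2), type = "low")
  for (col in c("alpha_deg", "beta_deg", "thickness_cm")) {
    x <- df[[col]]
    mu <- mean(x)
    df[[col]] <- signal::filtfilt(bf, x - mu) + mu
  }
  df$phi_deg <- df$alpha_deg - df$beta_deg
  df$fascicle_length_cm <- df$thickness_cm / sin(deg2rad(df$phi_deg))
  df
}

#' Root-mean-square and mean-absolute difference
#'
#' Agreement metrics between two equally long series:
#' `rmsd = sqrt(mean((a - b)^2))` and `mad_diff = mean(|a - b|)`.
#' (`mad_diff` rather than `mad` to avoid masking [stats::mad()].)
#'
#' @param a,b Numeric vectors of equal length `>= 1`.
#' @return Scalar.
#' @export
rmsd <- function(a, b) {
  check_pair(a, b)
  sqrt(mean((a - b)^2))
}

#' @rdname rmsd
#' @export
mad_diff <- function(a, b) {
  check_pair(a, b)
  mean(abs(a - b))
}

check_pair <- function(a, b) {
  if (!length(a) || length(a) != length(b))
    pt_stop("pt_validation_error", "series must have equal length >= 1 (%d vs %d)",
            length(a), length(b))
  invisible(TRUE)
}
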