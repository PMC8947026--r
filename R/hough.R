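# Straight-line Hough transform and its rotation de-biasing.
#
# Lines are parameterised by their visual angle theta (counter-clockwise
# positive w.r.t. horizontal, up = superficial) and signed distance
# rho = x * sin(theta) + y * cos(theta), with x = column and y = row
# (1-based, origin at the image top-left, y increasing downward). This is the
# normal parameterisation rho = x cos(theta') + y sin(theta') with
# theta' = 90 - theta; using the visual angle directly keeps accumulator
# columns aligned with the fascicle/aponeurosis angle conventions.

#' Hough transform for straight lines
#'
#' Each true pixel votes once per angle sample into the 1-pixel-wide bin of
#' `rho = x * sin(theta) + y * cos(theta)` (see package conventions: `theta`
#' is the line's counter-clockwise angle from horizontal). An all-false image
#' yields a valid all-zero accumulator.
#'
#' @param binary Logical (or 0/1 numeric) matrix.
#' @param theta_deg Vector of angle samples in degrees.
#' @return Object of class `pt_hough`: list with `counts` (rho x theta
#'   matrix of vote counts), `theta_deg`, `rho_px` (signed distances at 1-px
#'   resolution) and `dim_px`.
#' @export
hough_lines <- function(binary, theta_deg) {
  if (!is.matrix(binary)) pt_stop("pt_validation_error", "binary must be a matrix")
  if (!length(theta_deg)) pt_stop("pt_validation_error", "theta_deg must be nonempty")
  h <- nrow(binary); w <- ncol(binary)
  idx <- which(binary != 0)
  y <- ((idx - 1L) %% h) + 1L
  x <- ((idx - 1L) %/% h) + 1L
  dmax <- ceiling(sqrt(h^2 + w^2))
  rho_px <- seq.int(-dmax, dmax)
  counts <- matrix(0L, length(rho_px), length(theta_deg))
  th <- deg2rad(theta_deg)
  for (j in seq_along(th)) {
    rho <- x * sin(th[j]) + y * cos(th[j])
    counts[, j] <- tabulate(as.integer(round(rho)) + dmax + 1L, nbins = length(rho_px))
  }
  structure(list(counts = counts, theta_deg = as.numeric(theta_deg),
                 rho_px = rho_px, dim_px = c(h, w)),
            class = "pt_hough")
}

# theta sample axis covering [lo, hi] at the given resolution.
theta_axis <- function(range_deg, res_deg) {
  n <- floor((range_deg[2] - range_deg[1]) / res_deg + 1e-9)
  range_deg[1] + res_deg * 0:n
}

# Bilinear image rotation by delta degrees (visual CCW: structures' visual
# angles increase by delta) about the image centre, onto an enlarged canvas
# with constant zero padding.
rotate_bilinear <- function(img, delta_deg) {
  h <- nrow(img); w <- ncol(img)
  d <- deg2rad(delta_deg); cd <- cos(d); sd <- sin(d)
  w2 <- ceiling(abs(w * cd) + abs(h * sd))
  h2 <- ceiling(abs(h * cd) + abs(w * sd))
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  cx2 <- (w2 + 1) / 2; cy2 <- (h2 + 1) / 2
  xp <- rep(seq_len(w2), each = h2) - cx2
  yp <- rep(seq_len(h2), times = w2) - cy2
  # forward map rotates visual angle by +delta: R = [[cd, sd], [-sd, cd]]
  xs <- cd * xp - sd * yp + cx
  ys <- sd * xp + cd * yp + cy
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  val <- function(yy, xx) {
    ok <- xx >= 1 & xx <= w & yy >= 1 & yy <= h
    v <- numeric(length(xx))
    v[ok] <- img[cbind(yy[ok], xx[ok])]
    v
  }
  v <- (1 - fx) * (1 - fy) * val(y0, x0) + fx * (1 - fy) * val(y0, x0 + 1L) +
       (1 - fx) * fy * val(y0 + 1L, x0) + fx * fy * val(y0 + 1L, x0 + 1L)
  matrix(v, h2, w2)
}

#' De-bias a Hough accumulator at axis-aligned and diagonal angles
#'
#' Square pixels make exactly horizontal, vertical and diagonal lines collect
#' disproportionately many votes. For the angle samples in
#' `{0, +45, -45, 90}` that occur on the accumulator's theta axis, the counts
#' are replaced by those of the same physical lines measured on a copy of the
#' image rotated by `delta_deg` about its centre (bilinear interpolation onto
#' an enlarged zero-padded canvas, re-binarised at 0.5): the rotated line
#' appears at angle `theta + delta_deg`, away from the biased angles, and its
#' distance is remapped exactly through the rotation about the centre with
#' nearest-bin assignment. All other accumulator columns are untouched.
#'
#' @param acc A `pt_hough` accumulator.
#' @param binary The binary image `acc` was computed from.
#' @param delta_deg Rotation angle in degrees; must not be a multiple of 45.
#' @return A `pt_hough` accumulator with the biased columns replaced.
#' @export
debias_accumulator <- function(acc, binary, delta_deg) {
  stopifnot(inherits(acc, "pt_hough"))
  if (abs(delta_deg %% 45) < 1e-9)
    pt_stop("pt_validation_error", "delta_deg must not be a multiple of 45 degrees")
  bias <- c(0, 45, -45, 90)
  cols <- which(acc$theta_deg %in% bias)
  if (!length(cols)) return(acc)

  rot <- rotate_bilinear(binary * 1, delta_deg) >= 0.5
  racc <- hough_lines(rot, acc$theta_deg[cols] + delta_deg)

  h <- nrow(binary); w <- ncol(binary)
  h2 <- nrow(rot); w2 <- ncol(rot)
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  cx2 <- (w2 + 1) / 2; cy2 <- (h2 + 1) / 2
  dmax2 <- (length(racc$rho_px) - 1L) / 2L
  for (k in seq_along(cols)) {
    th <- deg2rad(acc$theta_deg[cols[k]])
    th2 <- deg2rad(acc$theta_deg[cols[k]] + delta_deg)
    # rho' = rho - centre . n(theta) + centre' . n(theta + delta)
    shift <- -(cx * sin(th) + cy * cos(th)) + (cx2 * sin(th2) + cy2 * cos(th2))
    bin2 <- as.integer(round(acc$rho_px + shift)) + dmax2 + 1L
    newcol <- integer(length(acc$rho_px))
    ok <- bin2 >= 1L & bin2 <= length(racc$rho_px)
    newcol[ok] <- racc$counts[bin2[ok], k]
    acc$counts[, cols[k]] <- newcol
  }
  acc
}

# Arg-max of an accumulator with deterministic tie-breaking:
# smaller |theta| first, then smaller |rho|.
hough_argmax <- function(acc) {
  mx <- max(acc$counts)
  if (mx <= 0) return(NULL)
  hits <- which(acc$counts == mx, arr.ind = TRUE)
  th <- acc$theta_deg[hits[, 2]]
  rh <- acc$rho_px[hits[, 1]]
  k <- order(abs(th), abs(rh))[1]
  list(theta_deg = th[k], rho_px = rh[k], count = mx)
}

# The k highest local maxima of an accumulator, found by iteratively taking
# the global maximum and suppressing its 3 x 3 cell neighbourhood
# (deterministic ties: first index, i.e. smaller rho then smaller theta).
hough_peaks <- function(acc, k) {
  cc <- acc$counts
  nr <- nrow(cc); nt <- ncol(cc)
  out <- vector("list", k)
  n <- 0L
  while (n < k) {
    m <- which.max(cc)
    if (length(m) == 0L || cc[m] <= 0) break
    i <- ((m - 1L) %% nr) + 1L
    j <- ((m - 1L) %/% nr) + 1L
    n <- n + 1L
    out[[n]] <- list(theta_deg = acc$theta_deg[j], rho_px = acc$rho_px[i],
                     value = cc[m])
    cc[max(1L, i - 1L):min(nr, i + 1L), max(1L, j - 1L):min(nt, j + 1L)] <- -Inf
  }
  out[seq_len(n)]
}
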