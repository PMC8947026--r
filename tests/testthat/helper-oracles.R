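# Independent oracles and fixture builders shared across the suite.

# Brute-force per-pixel Hough voting oracle (same line parameterisation,
# independent accumulation path).
oracle_hough <- function(binary, theta_deg) {
  h <- nrow(binary); w <- ncol(binary)
  dmax <- ceiling(sqrt(h^2 + w^2))
  counts <- matrix(0L, 2L * dmax + 1L, length(theta_deg))
  th <- theta_deg * pi / 180
  for (x in seq_len(w)) for (y in seq_len(h)) if (binary[y, x]) {
    bins <- as.integer(round(x * sin(th) + y * cos(th))) + dmax + 1L
    for (j in seq_along(bins)) counts[bins[j], j] <- counts[bins[j], j] + 1L
  }
  counts
}

# Finite-difference Frangi oracle: replicate-pad, smooth with a dnorm kernel
# by direct 1-D convolution, Hessian by central differences, eigenvalues via
# base eigen(), same vesselness formula. Independent of the package's
# Gaussian-derivative convolution route.
oracle_frangi <- function(img, sigma, beta = 0.5, c = 2) {
  r <- max(2L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma); k <- k / sum(k)
  h <- nrow(img); w <- ncol(img)
  pad <- function(m, n) m[pmin(pmax(seq_len(nrow(m) + 2 * n) - n, 1), nrow(m)),
                          pmin(pmax(seq_len(ncol(m) + 2 * n) - n, 1), ncol(m))]
  p <- pad(img, r + 1L)
  conv1 <- function(m, along_rows) {
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) {
      sh <- i - r - 1L
      if (along_rows) {
        rows <- pmin(pmax(seq_len(nrow(m)) + sh, 1), nrow(m))
        out <- out + k[i] * m[rows, ]
      } else {
        cols <- pmin(pmax(seq_len(ncol(m)) + sh, 1), ncol(m))
        out <- out + k[i] * m[, cols]
      }
    }
    out
  }
  sm <- conv1(conv1(p, TRUE), FALSE)
  core <- function(m, dr, dc) m[(r + 2 + dr):(r + 1 + h + dr), (r + 2 + dc):(r + 1 + w + dc)]
  f0 <- core(sm, 0, 0)
  dyy <- sigma^2 * (core(sm, 1, 0) - 2 * f0 + core(sm, -1, 0))
  dxx <- sigma^2 * (core(sm, 0, 1) - 2 * f0 + core(sm, 0, -1))
  dxy <- sigma^2 * (core(sm, 1, 1) - core(sm, 1, -1) -
                      core(sm, -1, 1) + core(sm, -1, -1)) / 4
  v <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ev <- eigen(matrix(c(dxx[i, j], dxy[i, j], dxy[i, j], dyy[i, j]), 2),
                symmetric = TRUE, only.values = TRUE)$values
    l <- ev[order(abs(ev))]
    if (l[2] < 0) {
      S2 <- sum(l^2)
      v[i, j] <- exp(-(l[1] / l[2])^2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * c^2)))
    }
  }
  if (max(v) > 0) v <- v / max(v)
  v
}

# Principal orientation of a labelled component via second moments of pixel
# coordinates (degrees, CCW-positive with up = shallower rows).
comp_orientation <- function(lab, id) {
  idx <- which(lab == id)
  y <- ((idx - 1) %% nrow(lab)) + 1
  x <- ((idx - 1) %/% nrow(lab)) + 1
  cv <- stats::cov(cbind(x, -y))
  e <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  a <- atan2(e[2], e[1]) * 180 / pi
  ((a %% 180) + 180) %% 180
}

# Horner evaluation of ascending polynomial coefficients (test-local copy).
poly_eval_test <- function(coef, x) {
  y <- 0
  for (k in rev(seq_along(coef))) y <- y * x + coef[k]
  y
}

# Hand-built aponeurosis fit (ascending coefficients, y(x) in pixels).
make_fit <- function(coeffs, which = "superficial", slope_bound = 1) {
  structure(list(coeffs = coeffs, order = length(coeffs) - 1L,
                 slope_bound = slope_bound, which = which,
                 xs_px = numeric(0), source_method = "manual"),
            class = "pt_apo_fit")
}

# Straight-band phantom with a prescribed inner-edge thickness in cm
# (cm_per_px = 0.01, superficial band centred at row 45).
recovery_spec <- function(alpha, T_cm, seed = 1L, speckle = 0, width = 320L, ...) {
  S0 <- 45; bt <- 8
  D0 <- S0 + bt + T_cm / 0.01
  phantom_spec(height_px = as.integer(ceiling(D0 + bt / 2 + 20)),
               width_px = width, S_true = S0, D_true = D0,
               band_thickness_px = bt, alpha_true_deg = alpha,
               speckle_sigma = speckle, seed = seed, ...)
}

# Small default phantom for fast pipeline tests.
small_spec <- function(...) {
  phantom_spec(height_px = 220L, width_px = 256L, S_true = 40, D_true = 180, ...)
}

# Feature series table as produced by pt_analyze, built directly.
make_series <- function(t, alpha, beta, thick, bright) {
  phi <- alpha - beta
  data.frame(frame_index = seq_along(t) - 1L, alpha_deg = alpha,
             beta_deg = beta, phi_deg = phi, thickness_cm = thick,
             fascicle_length_cm = thick / sin(phi * pi / 180),
             extrapolated_fraction = 0, brightness = bright,
             interpolated_flag = FALSE, method = "hough",
             time_s = t, status = "ok")
}
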