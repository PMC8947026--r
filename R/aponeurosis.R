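# Aponeurosis detection: locate the inner edges of the superficial and deep
# aponeuroses by either a straight-line Hough search or connected-object
# analysis, then fit slope-constrained polynomial lines S(x), D(x).

# Polynomial helpers (ascending coefficients: c0 + c1 x + c2 x^2 + ...).
poly_eval <- function(coef, x) {
  y <- rep(coef[length(coef)], length(x))
  for (k in rev(seq_len(length(coef) - 1L))) y <- y * x + coef[k]
  y
}
poly_deriv <- function(coef) {
  if (length(coef) <= 1L) return(0)
  coef[-1] * seq_len(length(coef) - 1L)
}
# Expand p(t) = sum c_k (x - m)^k into ascending coefficients in x.
poly_uncenter <- function(coef, m) {
  out <- numeric(length(coef))
  basis <- 1 # coefficients of (x - m)^k, built iteratively
  for (k in seq_along(coef)) {
    out[seq_along(basis)] <- out[seq_along(basis)] + coef[k] * basis
    basis <- c(0, basis) - m * c(basis, 0)
  }
  out
}

# Equidistant sampling abscissae inside [x_margin, width - x_margin].
apo_abscissae <- function(width_px, cfg) {
  if (2 * cfg$x_margin_px >= width_px)
    pt_stop("pt_validation_error", "2 * x_margin_px must be smaller than the image width")
  seq(max(cfg$x_margin_px, 1), width_px - cfg$x_margin_px, length.out = cfg$n_apox)
}

apo_points <- function(which, xs, ys, method) {
  structure(list(which = which, xs_px = xs, ys_px = ys, source_method = method),
            class = "pt_apo_points")
}

apo_region <- function(cfg, which) {
  if (identical(which, "superficial")) cfg$d_superficial else cfg$d_deep
}
apo_angle_range <- function(cfg, which) {
  if (identical(which, "superficial")) cfg$beta_range_deg else cfg$gamma_range_deg
}

#' Detect an aponeurosis inner edge with the Hough transform
#'
#' The default detection method: within the aponeurosis' depth region the
#' dominant straight line is found as the de-biased Hough accumulator
#' arg-max (angle range from the eligible aponeurosis angles, resolution
#' `theta_apo_res_deg`; ties broken toward smaller `|theta|`, then smaller
#' `|rho|`). The line is evaluated at `n_apox` equidistant abscissae; at each
#' abscissa landing on a true pixel the edge is traced vertically toward the
#' fascicles (downward for the superficial aponeurosis, upward for the deep
#' one) and the last true pixel before a false one is reported as the inner
#' edge. Abscissae landing on false pixels are reported missing (`NA`).
#'
#' @param binary Logical matrix (thresholded aponeurosis image).
#' @param frame The source [pt_frame()].
#' @param cfg A [pt_config()].
#' @param which `"superficial"` or `"deep"`.
#' @return A `pt_apo_points` object: sampled abscissae `xs_px`, inner-edge
#'   depths `ys_px` (may contain `NA`), `which`, `source_method`.
#' @export
detect_apo_hough <- function(binary, frame, cfg, which = c("superficial", "deep")) {
  which <- match.arg(which)
  h <- nrow(binary); w <- ncol(binary)
  rr <- region_rows(h, apo_region(cfg, which))
  if (!length(rr)) pt_stop("pt_detection_error", "empty %s depth region", which)
  work <- matrix(FALSE, h, w)
  work[rr, ] <- binary[rr, ]

  thetas <- theta_axis(apo_angle_range(cfg, which), cfg$theta_apo_res_deg)
  acc <- hough_lines(work, thetas)
  acc <- debias_accumulator(acc, work, cfg$rotation_delta_deg)
  best <- hough_argmax(acc)
  if (is.null(best))
    pt_stop("pt_detection_error", "no aponeurosis line found in %s depth region (empty accumulator)", which)

  th <- deg2rad(best$theta_deg)
  xs <- apo_abscissae(w, cfg)
  dirn <- if (which == "superficial") 1L else -1L # toward the fascicles
  ys <- rep(NA_real_, length(xs))
  for (i in seq_along(xs)) {
    xc <- as.integer(round(xs[i]))
    yl <- as.integer(round((best$rho_px - xc * sin(th)) / cos(th)))
    if (yl < 1L || yl > h || !work[yl, xc]) next
    y <- yl
    while (y + dirn >= 1L && y + dirn <= h && work[y + dirn, xc]) y <- y + dirn
    ys[i] <- y
  }
  apo_points(which, xs, ys, "hough")
}

#' Detect an aponeurosis inner edge by connected-object analysis
#'
#' The alternative method for curved or blob-like aponeuroses (to be used
#' with the aponeurosis vesselness filter). Among the 8-connected objects in
#' the depth region the two longest (by major-axis length) are compared: if
#' the length ratio second/longest is below `l_ratio_max` the longest wins,
#' otherwise the object with the higher mean grayscale intensity under its
#' mask wins (a single object is selected unconditionally). The winner's
#' per-column inner edge (deepest true pixel per column for the superficial
#' aponeurosis, shallowest for the deep one) is shifted outward — away from
#' the fascicles — by `sigma_apo_px / 4` rows to undo the dilation added by
#' the Gaussian smoothing of the filter chain, then sampled at the `n_apox`
#' abscissae; columns not covered by the object are missing.
#'
#' @inheritParams detect_apo_hough
#' @return A `pt_apo_points` object.
#' @export
detect_apo_object <- function(binary, frame, cfg, which = c("superficial", "deep")) {
  which <- match.arg(which)
  h <- nrow(binary); w <- ncol(binary)
  rr <- region_rows(h, apo_region(cfg, which))
  if (!length(rr)) pt_stop("pt_detection_error", "empty %s depth region", which)
  work <- matrix(FALSE, h, w)
  work[rr, ] <- binary[rr, ]
  if (!any(work))
    pt_stop("pt_detection_error", "no objects in %s depth region", which)

  lab <- label_components(work)
  feats <- object_features(lab, frame$pixels)
  ord <- order(-feats$major_axis_length_px)
  winner <- feats$label[ord[1]]
  if (nrow(feats) >= 2L) {
    ratio <- feats$major_axis_length_px[ord[2]] / feats$major_axis_length_px[ord[1]]
    if (ratio >= cfg$l_ratio_max) {
      cand <- feats$label[ord[1:2]]
      winner <- cand[which.max(feats$mean_masked_intensity[match(cand, feats$label)])]
    }
  }

  idx <- which(lab == winner)
  yy <- ((idx - 1L) %% h) + 1L
  xx <- ((idx - 1L) %/% h) + 1L
  edge_fun <- if (which == "superficial") max else min
  edges <- vapply(split(yy, xx), edge_fun, numeric(1))
  cols <- as.integer(names(edges))
  shift <- cfg$sigma_apo_px / 4
  edges <- if (which == "superficial") edges - shift else edges + shift
  edges <- pmin(pmax(edges, min(rr)), max(rr)) # stay inside the depth region

  xs <- apo_abscissae(w, cfg)
  ys <- edges[match(as.integer(round(xs)), cols)]
  apo_points(which, xs, unname(ys), "object")
}

#' Fit an aponeurosis line with slope constraints
#'
#' Least-squares polynomial fit `y = p(x)` of the given order through the
#' non-missing inner-edge points, subject to `|p'(x_i)| <= tan(max |angle|)`
#' at every sampled abscissa, where the angle range is the eligible
#' aponeurosis angle range. The quadratic program is solved exactly with a
#' primal active-set method (the unconstrained optimum is returned when
#' feasible).
#'
#' @param points A `pt_apo_points` object.
#' @param order Polynomial order (`>= 1`).
#' @param angle_range_deg Eligible angle range `c(lo, hi)` in degrees; the
#'   slope bound is `tan(max(abs(angle_range)))`.
#' @return Object of class `pt_apo_fit`: ascending polynomial coefficients
#'   `coeffs` (pixel coordinates, `y(x)`), `order`, `slope_bound`, `which`,
#'   `xs_px` (the fit's sampling abscissae) and `source_method`.
#' @export
fit_aponeurosis <- function(points, order, angle_range_deg) {
  stopifnot(inherits(points, "pt_apo_points"))
  keep <- !is.na(points$ys_px)
  x <- points$xs_px[keep]; y <- points$ys_px[keep]
  if (length(x) < order + 1L)
    pt_stop("pt_fit_error", "%s aponeurosis: %d points available but order-%d fit needs at least %d",
            points$which, length(x), order, order + 1L)
  s <- max(abs(tan(deg2rad(angle_range_deg))))
  if (s <= 0) pt_stop("pt_fit_error", "infeasible slope constraint (bound %.3g)", s)

  m <- mean(x)
  t <- x - m
  X <- outer(t, 0:order, `^`)
  H <- 2 * crossprod(X)
  f <- -2 * crossprod(X, y)
  # derivative rows at each abscissa: dp(t_i) = sum_{k>=1} k c_k t_i^(k-1)
  tc <- points$xs_px - m
  R <- cbind(0, outer(tc, seq_len(order) - 1L, `^`) *
                  rep(seq_len(order), each = length(tc)))
  A <- rbind(R, -R)
  b <- rep(s, nrow(A))
  key <- apply(signif(cbind(A, b), 10), 1, paste, collapse = ",")
  dup <- duplicated(key)
  z <- solve_qp_activeset(H, drop(f), A[!dup, , drop = FALSE], b[!dup])
  structure(list(coeffs = poly_uncenter(z, m), order = as.integer(order),
                 slope_bound = s, which = points$which,
                 xs_px = points$xs_px, source_method = points$source_method),
            class = "pt_apo_fit")
}

#' @export
print.pt_apo_fit <- function(x, ...) {
  cat(sprintf("<pt_apo_fit> %s, order %d (%s method), coeffs: %s\n",
              x$which, x$order, x$source_method,
              paste(signif(x$coeffs, 6), collapse = ", ")))
  invisible(x)
}

#' @export
coef.pt_apo_fit <- function(object, ...) object$coeffs

#' @export
predict.pt_apo_fit <- function(object, x, ...) poly_eval(object$coeffs, x)

# Primal active-set solver for min 0.5 z'Hz + f'z subject to A z <= b, with
# H positive definite and b > 0 (z = 0 feasible). Exact KKT solves; suitable
# for the tiny systems arising from low-order polynomial fits.
solve_qp_activeset <- function(H, f, A, b, tol = 1e-9, maxit = 500L) {
  n <- length(f)
  z <- drop(solve(H, -f))
  if (!nrow(A) || all(A %*% z <= b + tol)) return(z)
  z <- numeric(n)
  W <- integer(0)
  for (it in seq_len(maxit)) {
    if (length(W)) {
      Aw <- A[W, , drop = FALSE]
      K <- rbind(cbind(H, t(Aw)),
                 cbind(Aw, matrix(0, length(W), length(W))))
      sol <- tryCatch(solve(K, c(-f, b[W])),
                      error = function(e) qr.solve(K, c(-f, b[W])))
      zeq <- sol[1:n]; lam <- sol[-(1:n)]
    } else {
      zeq <- drop(solve(H, -f)); lam <- numeric(0)
    }
    p <- zeq - z
    if (max(abs(p)) < tol) {
      if (!length(W) || all(lam >= -tol)) return(z)
      W <- W[-which.min(lam)]
    } else {
      inact <- setdiff(seq_len(nrow(A)), W)
      Ap <- drop(A[inact, , drop = FALSE] %*% p)
      cand <- which(Ap > tol)
      alpha <- 1; blk <- NA_integer_
      if (length(cand)) {
        resid <- b[inact][cand] - drop(A[inact, , drop = FALSE] %*% z)[cand]
        steps <- resid / Ap[cand]
        jm <- which.min(steps)
        if (steps[jm] < 1) { alpha <- max(0, steps[jm]); blk <- inact[cand[jm]] }
      }
      z <- z + alpha * p
      if (!is.na(blk)) W <- c(W, blk)
    }
  }
  pt_stop("pt_fit_error", "constrained fit did not converge")
}
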