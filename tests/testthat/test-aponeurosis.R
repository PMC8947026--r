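band_setup <- function(sup_rows = 21:25, deep_rows = 81:85, h = 100, w = 60,
                       drop_col = NULL) {
  b <- matrix(FALSE, h, w)
  b[sup_rows, ] <- TRUE
  b[deep_rows, ] <- TRUE
  if (!is.null(drop_col)) b[, drop_col] <- FALSE
  fr <- pt_frame(b * 0.9 + 0.05, 0.01)
  cfg <- pt_config(d_superficial = c(0, 0.4), d_deep = c(0.6, 1),
                   x_margin_px = 2, n_apox = 10)
  list(b = b, fr = fr, cfg = cfg)
}

test_that("hough detection traces to the inner edge of each band", {
  s <- band_setup()
  pS <- detect_apo_hough(s$b, s$fr, s$cfg, "superficial")
  expect_equal(pS$ys_px, rep(25, 10))       # deepest row of the superficial band
  expect_equal(diff(pS$xs_px), rep(diff(pS$xs_px)[1], 9), tolerance = 1e-9)
  pD <- detect_apo_hough(s$b, s$fr, s$cfg, "deep")
  expect_equal(pD$ys_px, rep(81, 10))       # shallowest row of the deep band
})

test_that("abscissae on false columns are reported missing", {
  xs <- pennatrack:::apo_abscissae(60, band_setup()$cfg)
  dead <- round(xs[4])
  s <- band_setup(drop_col = dead)
  pS <- detect_apo_hough(s$b, s$fr, s$cfg, "superficial")
  expect_true(is.na(pS$ys_px[4]))
  expect_equal(pS$ys_px[-4], rep(25, 9))
})

test_that("hough detection fails loudly on empty regions", {
  s <- band_setup()
  blank <- matrix(FALSE, 100, 60)
  expect_error(detect_apo_hough(blank, s$fr, s$cfg, "superficial"),
               class = "pt_detection_error")
})

test_that("object selection follows the length-ratio and intensity rules", {
  h <- 100; w <- 120
  cfg <- pt_config(d_superficial = c(0, 0.5), d_deep = c(0.6, 1),
                   x_margin_px = 2, n_apox = 12, l_ratio_max = 0.5)
  # lengths 100 vs 30: ratio 0.3 < 0.5 -> longest wins regardless of intensity
  b <- matrix(FALSE, h, w); b[20:24, 1:100] <- TRUE; b[35:39, 1:30] <- TRUE
  gray <- matrix(0.05, h, w); gray[20:24, 1:100] <- 0.3; gray[35:39, 1:30] <- 0.95
  pS <- detect_apo_object(b, pt_frame(gray, 0.01), cfg, "superficial")
  expect_true(all(stats::na.omit(pS$ys_px) == 24 - cfg$sigma_apo_px / 4))

  # lengths 100 vs 90: ratio 0.9 > 0.5 -> brighter object wins
  b2 <- matrix(FALSE, h, w); b2[20:24, 1:100] <- TRUE; b2[35:39, 1:90] <- TRUE
  g2 <- matrix(0.05, h, w); g2[20:24, 1:100] <- 0.4; g2[35:39, 1:90] <- 0.8
  p2 <- detect_apo_object(b2, pt_frame(g2, 0.01), cfg, "superficial")
  expect_true(all(stats::na.omit(p2$ys_px) == 39 - cfg$sigma_apo_px / 4))
})

test_that("object inner edges are shifted sigma_apo/4 away from the fascicles", {
  h <- 100; w <- 80
  cfg <- pt_config(d_superficial = c(0, 0.5), d_deep = c(0.6, 1),
                   x_margin_px = 2, n_apox = 8, sigma_apo_px = 8)
  b <- matrix(FALSE, h, w); b[20:26, ] <- TRUE; b[70:76, ] <- TRUE
  fr <- pt_frame(b * 0.9, 0.01)
  pS <- detect_apo_object(b, fr, cfg, "superficial")
  pD <- detect_apo_object(b, fr, cfg, "deep")
  expect_equal(unique(pS$ys_px), 26 - 2)  # raw edge 26, shifted 2 rows up
  expect_equal(unique(pD$ys_px), 70 + 2)  # raw edge 70, shifted 2 rows down
  expect_error(detect_apo_object(matrix(FALSE, h, w), fr, cfg, "deep"),
               class = "pt_detection_error")
})

test_that("both detectors agree on a noise-free straight band", {
  # bands only: stripe intensity below the aponeurosis threshold, so the
  # comparison probes pure band detection (hough on the thresholded raw
  # image, object on the filtered chain)
  sp <- small_spec(alpha_true_deg = 25, stripe_intensity = 0.09)
  r <- render_phantom(sp)
  cfg_h <- phantom_config(sp, apo_method = "hough")
  cfg_o <- phantom_config(sp, apo_method = "object")
  bh <- pennatrack:::aponeurosis_binary(r$frame, cfg_h)
  bo <- pennatrack:::aponeurosis_binary(r$frame, cfg_o)
  for (which in c("superficial", "deep")) {
    ph <- detect_apo_hough(bh, r$frame, cfg_h, which)
    po <- detect_apo_object(bo, r$frame, cfg_o, which)
    keep <- !is.na(ph$ys_px) & !is.na(po$ys_px)
    expect_gt(sum(keep), 10)
    expect_lte(max(abs(ph$ys_px[keep] - po$ys_px[keep])), 1)
  }
})

test_that("polynomial fits recover exact data and respect slope bounds", {
  xs <- seq(5, 95, length.out = 12)
  pts <- pennatrack:::apo_points("superficial", xs, 5 + 0.1 * xs, "manual")
  fit <- fit_aponeurosis(pts, 1, c(-atan(0.5) * 180 / pi, atan(0.5) * 180 / pi))
  expect_equal(fit$coeffs, c(5, 0.1), tolerance = 1e-6)

  # steep data: constraint activates at the bound tan(30 deg)
  pts2 <- pennatrack:::apo_points("superficial", xs, 5 + 2 * xs, "manual")
  fit2 <- fit_aponeurosis(pts2, 1, c(-30, 30))
  expect_equal(fit2$coeffs[2], tan(30 * pi / 180), tolerance = 1e-4)
  # oracle: grid search over bounded slopes with optimal intercept
  slopes <- seq(-tan(pi / 6), tan(pi / 6), length.out = 20001)
  sse <- vapply(slopes, function(b) {
    a <- mean(5 + 2 * xs - b * xs); sum((5 + 2 * xs - a - b * xs)^2)
  }, 1)
  expect_equal(fit2$coeffs[2], slopes[which.min(sse)], tolerance = 1e-4)

  # quadratic recovery within bounds
  y3 <- 40 + 0.05 * xs - 4e-4 * xs^2
  pts3 <- pennatrack:::apo_points("deep", xs, y3, "manual")
  fit3 <- fit_aponeurosis(pts3, 2, c(-20, 20))
  expect_equal(fit3$coeffs, c(40, 0.05, -4e-4), tolerance = 1e-6)

  expect_error(fit_aponeurosis(
    pennatrack:::apo_points("deep", xs[1:2], c(1, NA), "manual"), 2, c(-20, 20)),
    class = "pt_fit_error")
})

test_that("constrained fits are KKT-consistent optima", {
  set.seed(8)
  xs <- seq(10, 90, length.out = 15)
  for (i in 1:10) {
    slope <- runif(1, -1.5, 1.5)
    y <- runif(1, 0, 50) + slope * xs + rnorm(15, sd = 0.5)
    pts <- pennatrack:::apo_points("superficial", xs, y, "manual")
    bound_deg <- 25
    fit <- fit_aponeurosis(pts, 1, c(-bound_deg, bound_deg))
    s <- tan(bound_deg * pi / 180)
    expect_lte(abs(fit$coeffs[2]), s + 1e-9)
    # residual never beats the unconstrained LS fit; equal iff inactive
    ls <- stats::lm.fit(cbind(1, xs), y)$coefficients
    r_con <- sum((y - poly_eval_test(fit$coeffs, xs))^2)
    r_un <- sum((y - ls[1] - ls[2] * xs)^2)
    expect_gte(r_con, r_un - 1e-8)
    if (abs(ls[2]) <= s) {
      expect_equal(r_con, r_un, tolerance = 1e-8)
    } else {
      expect_equal(abs(fit$coeffs[2]), s, tolerance = 1e-8) # constraint active
    }
  }
})
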