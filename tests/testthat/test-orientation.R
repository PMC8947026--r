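flat_roi <- function(s_row, d_row, h, w, margin = 0) {
  fr <- pt_frame(matrix(0.5, h, w), 0.01)
  build_ellipse(make_fit(s_row), make_fit(d_row, "deep"), fr,
                pt_config(x_margin_px = margin))
}

test_that("elliptic ROI geometry follows the fitted lines", {
  roi <- flat_roi(20, 120, 150, 200)
  expect_equal(unname(roi$center["x"]), 100.5)
  expect_equal(unname(roi$center["y"]), 70)
  expect_equal(roi$semi_axis_x, 100)
  expect_equal(roi$semi_axis_y, 50)
  # pixelated area matches the analytic ellipse area
  expect_lt(abs(sum(roi$mask) / (pi * 100 * 50) - 1), 0.02)
  expect_error(flat_roi(80, 80, 150, 200), class = "pt_geometry_error")
})

test_that("ROI mask stays strictly between the aponeurosis lines", {
  fr <- pt_frame(matrix(0.5, 160, 120), 0.01)
  fit_S <- make_fit(c(25, 0.08))            # sloped superficial line
  fit_D <- make_fit(c(120, -0.05), "deep")
  roi <- build_ellipse(fit_S, fit_D, fr, pt_config(x_margin_px = 5))
  idx <- which(roi$mask)
  y <- ((idx - 1) %% 160) + 1
  x <- ((idx - 1) %/% 160) + 1
  expect_true(all(y > poly_eval_test(fit_S$coeffs, x) - 1))
  expect_true(all(y < poly_eval_test(fit_D$coeffs, x) + 1))
})

test_that("chord correction rescales columns by the relative chord length", {
  mk_acc <- function(v) structure(
    list(counts = matrix(v, 3, 3), theta_deg = c(0, 45, 90),
         rho_px = -1:1, dim_px = c(10, 10)), class = "pt_hough")
  circ <- flat_roi(20, 100, 140, 110, margin = 15)   # a = b = 40
  expect_equal(circ$semi_axis_x, circ$semi_axis_y)
  acc <- mk_acc(6)
  expect_equal(chord_correction(acc, circ)$counts, matrix(6, 3, 3))

  ell <- flat_roi(30, 110, 160, 170, margin = 5)     # a = 80, b = 40
  cc <- chord_correction(acc, ell)$counts
  expect_equal(cc[1, 1], 6)                          # theta = 0: longest chord
  expect_equal(cc[1, 3], 12)                         # theta = 90: chord halves
  expect_equal(chord_correction(mk_acc(0), ell)$counts, matrix(0, 3, 3))
})

test_that("weighted median follows the cumulative-weight rule", {
  expect_equal(weighted_median(c(10, 20, 30), c(1, 5, 1)), 20)
  expect_equal(weighted_median(42, 7), 42)
  expect_equal(weighted_median(c(10, 20), c(1, 1)), 10)
  expect_equal(weighted_median(c(30, 10, 20), c(1, 1, 5)), 20) # order-invariant
  expect_error(weighted_median(numeric(0), numeric(0)), class = "pt_validation_error")
  expect_error(weighted_median(c(1, 2), c(1, -1)), class = "pt_validation_error")
})

stripe_binary <- function(h, w, angle_deg, offsets, half = 1) {
  x <- rep(seq_len(w), each = h); y <- rep(seq_len(h), times = w)
  a <- angle_deg * pi / 180
  cc <- x * sin(a) + y * cos(a)
  hit <- rep(FALSE, h * w)
  for (off in offsets) hit <- hit | abs(cc - off) <= half
  matrix(hit, h, w)
}

test_that("fascicle angle lands on the stripe orientation", {
  h <- 140; w <- 200
  roi <- flat_roi(10, 130, h, w, margin = 5)
  cfg <- pt_config()
  ctr <- 100.5 * sin(pi / 6) + 70 * cos(pi / 6)
  bin <- stripe_binary(h, w, 30, ctr + c(-30, -15, 0, 15, 30))
  est <- estimate_fascicle_angle(bin, roi, cfg)
  expect_lte(abs(est$alpha_deg - 30), cfg$theta_fas_res_deg)
  expect_lte(nrow(est$peaks), cfg$k_peaks)
  expect_error(estimate_fascicle_angle(matrix(FALSE, h, w), roi, cfg),
               class = "pt_detection_error")
})

test_that("the weighted median resists a short outlier population", {
  h <- 140; w <- 200
  roi <- flat_roi(10, 130, h, w, margin = 5)
  cfg <- pt_config()
  c25 <- 100.5 * sin(25 * pi / 180) + 70 * cos(25 * pi / 180)
  bin <- stripe_binary(h, w, 25, c25 + seq(-40, 40, by = 20))
  # short, isolated steep stripe: a single strong peak at 70 degrees
  out <- stripe_binary(h, w, 70, 100.5 * sin(70 * pi / 180) + 70 * cos(70 * pi / 180))
  out[, c(1:60, 141:200)] <- FALSE
  est <- estimate_fascicle_angle(bin | out, roi, cfg)
  expect_lte(abs(est$alpha_deg - 25), cfg$theta_fas_res_deg)
})

test_that("heavier angle populations win the weighted median", {
  h <- 140; w <- 200
  roi <- flat_roi(10, 130, h, w, margin = 5)
  cfg <- pt_config()
  mk <- function(ang, offs) {
    ctr <- 100.5 * sin(ang * pi / 180) + 70 * cos(ang * pi / 180)
    stripe_binary(h, w, ang, ctr + offs)
  }
  bin <- mk(25, c(-20, 20)) | mk(35, seq(-45, 45, by = 15))
  est <- estimate_fascicle_angle(bin, roi, cfg)
  expect_lte(abs(est$alpha_deg - 35), cfg$theta_fas_res_deg)
})

test_that("angle estimate is contrast-invariant on a noise-free phantom", {
  sp <- small_spec(alpha_true_deg = 28)
  cfg <- phantom_config(sp)
  fr1 <- render_phantom(sp)$frame
  fr2 <- fr1; fr2$pixels <- pmin(fr1$pixels * 2, 1)
  a1 <- process_frame(fr1, cfg)$alpha_deg
  a2 <- process_frame(fr2, cfg)$alpha_deg
  expect_lte(abs(a1 - a2), cfg$theta_fas_res_deg)
})

test_that("argmax and weighted-median estimators disagree on two populations", {
  sp <- small_spec(alpha_true_deg = 25,
                   outlier_angle_deg = 55,
                   outlier_offsets_px = 128.5 * sin(55 * pi / 180) + 110 * cos(55 * pi / 180),
                   outlier_intensity = 0.85)
  r <- render_phantom(sp)
  cfg <- phantom_config(sp)
  fas <- fascicle_filter(r$frame, cfg)
  row <- process_frame(r$frame, cfg, keep_fits = TRUE)
  roi <- attr(row, "roi")
  wm <- estimate_fascicle_angle(fas, roi, cfg, estimator = "weighted_median")
  am <- estimate_fascicle_angle(fas, roi, cfg, estimator = "argmax")
  expect_false(isTRUE(all.equal(wm$alpha_deg, am$alpha_deg)))
  expect_lt(abs(wm$alpha_deg - 25), abs(am$alpha_deg - 25))
})
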