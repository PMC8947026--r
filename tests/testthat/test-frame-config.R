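test_that("image loading rescales 8- and 16-bit data to [0, 1]", {
  d <- withr::local_tempdir()
  p1 <- file.path(d, "white.png")
  png::writePNG(matrix(1, 20, 20), p1)
  expect_equal(load_frame(p1, 0.01)$pixels, matrix(1, 20, 20))

  p0 <- file.path(d, "black.png")
  png::writePNG(matrix(0, 20, 20), p0)
  expect_equal(load_frame(p0, 0.01)$pixels, matrix(0, 20, 20))

  m <- matrix(0.25, 20, 20); m[3, 7] <- 1
  p16 <- file.path(d, "peak.tif")
  tiff::writeTIFF(m, p16, bits.per.sample = 16L)
  fr <- load_frame(p16, 0.02)
  expect_equal(fr$pixels[3, 7], 1)
  expect_equal(fr$cm_per_px, 0.02)
})

test_that("frame validation rejects bad inputs", {
  expect_error(pt_frame(matrix(0.5, 8, 8), 0.01), class = "pt_validation_error")
  expect_error(pt_frame(matrix(0.5, 20, 20), -1), class = "pt_validation_error")
  expect_error(pt_frame(matrix(2, 20, 20), 0.01), class = "pt_validation_error")
  expect_error(load_frame("/nonexistent/file.png", 0.01), class = "pt_io_error")
})

test_that("sequences load in natural filename order with timestamps", {
  d <- withr::local_tempdir()
  # encode the intended position in the pixel value
  for (nm in c("f2.png", "f10.png", "f1.png"))
    png::writePNG(matrix(as.numeric(sub("\\D*(\\d+).*", "\\1", nm)) * 10 / 255, 16, 16),
                  file.path(d, nm))
  frames <- load_sequence(d, 0.01, frame_rate_hz = 10)
  expect_equal(vapply(frames, function(f) round(f$pixels[1, 1] * 255 / 10), 1),
               c(1, 2, 10))
  expect_equal(vapply(frames, `[[`, 1, "timestamp_s"), c(0, 0.1, 0.2))
  expect_equal(vapply(frames, `[[`, 1L, "frame_index"), 0:2)

  # single frame gets timestamp 0
  one <- load_sequence(file.path(d, "f1.png"), 0.01)
  expect_length(one, 1L)
  expect_equal(one[[1]]$timestamp_s, 0)

  empty <- withr::local_tempdir()
  expect_error(load_sequence(empty, 0.01), class = "pt_io_error")

  png::writePNG(matrix(0.5, 18, 16), file.path(d, "f3.png"))
  expect_error(load_sequence(d, 0.01), "f3", class = "pt_validation_error")
})

test_that("depth-region masks select exactly the requested row band", {
  fr <- pt_frame(matrix(0.5, 100, 30), 0.01)
  m <- depth_region_mask(fr, c(0, 0.3))
  expect_equal(which(m[, 1]), 1:30)
  m2 <- depth_region_mask(fr, c(0.7, 1))
  expect_equal(which(m2[, 1]), 71:100)
  expect_true(all(m2[, 1] == m2[, 30]))
  expect_error(depth_region_mask(fr, c(0.5, 0.5)), class = "pt_validation_error")
})

test_that("superficial and deep masks are disjoint under config ordering", {
  fr <- pt_frame(matrix(0.5, 97, 16), 0.01)
  set.seed(5)
  for (i in 1:20) {
    br <- sort(runif(4))
    cfg <- pt_config(d_superficial = br[1:2], d_deep = br[3:4])
    expect_false(any(depth_region_mask(fr, cfg$d_superficial) &
                       depth_region_mask(fr, cfg$d_deep)))
  }
})

test_that("config invariants are enforced", {
  expect_error(pt_config(d_superficial = c(0.4, 0.7), d_deep = c(0.6, 1)),
               class = "pt_validation_error")
  expect_error(pt_config(sigma_fas_px = 8, sigma_apo_px = 2),
               class = "pt_validation_error")
  expect_error(pt_config(theta_fas_range_deg = c(-5, 80)),
               class = "pt_validation_error")
  expect_error(pt_config(rotation_delta_deg = 45), class = "pt_validation_error")
  expect_error(pt_config(k_peaks = 0), class = "pt_validation_error")
  expect_error(pt_config(n_apox = 1), class = "pt_validation_error")
})

test_that("config and result tables round-trip through files", {
  d <- withr::local_tempdir()
  cfg <- pt_config(sigma_fas_px = 3, t_fas = 0.15, apo_method = "object")
  cp <- file.path(d, "cfg.yaml")
  write_config(cfg, cp)
  cfg2 <- read_config(cp)
  expect_equal(unclass(cfg2), unclass(cfg))
  writeLines("not_a_real_key: 3", cp)
  expect_error(read_config(cp), "unknown config keys", class = "pt_validation_error")

  df <- make_series(t = c(0, 0.1), alpha = c(25.12345, 26.2),
                    beta = c(-1.5, 0.2), thick = c(1.23456, 1.3),
                    bright = c(0.25, 0.26))
  rp <- file.path(d, "res.csv")
  write_results(df, rp)
  back <- read_results(rp)
  expect_equal(back$alpha_deg, round(df$alpha_deg, 4))
  expect_equal(back$thickness_cm, round(df$thickness_cm, 4))
  expect_equal(names(back)[1:10],
               c("frame_index", "alpha_deg", "beta_deg", "phi_deg",
                 "thickness_cm", "fascicle_length_cm", "extrapolated_fraction",
                 "brightness", "interpolated_flag", "method"))
  # writing what was read back reproduces the file (lossless at 4 decimals)
  rp2 <- file.path(d, "res2.csv")
  write_results(back, rp2)
  expect_identical(readLines(rp), readLines(rp2))
})
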