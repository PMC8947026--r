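# Vesselness filtering: highlight thin (fascicle) and thick (aponeurosis)
# line-like structures prior to line / object detection.

# Gaussian and Gaussian-derivative kernels, truncated at 4 standard
# deviations. Convolution uses edge replication to avoid the strong border
# response a zero-padded Hessian would create.
gauss_kernel_1d <- function(sigma, order = 0) {
  r <- max(1L, ceiling(4 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
         "0" = g,
         "1" = -x / sigma^2 * g, # odd: zero-sum by symmetry
         "2" = {
           k <- (x^2 - sigma^2) / sigma^4 * g
           k - mean(k) # exact zero response to constants despite truncation
         })
}

conv_sep <- function(img, ky, kx) {
  k2 <- outer(ky, kx)
  as.matrix(EBImage::filter2(img, k2, boundary = "replicate"))
}

#' Single-scale Frangi vesselness filter
#'
#' Enhances bright ridges (line-like structures on a darker background) at a
#' single scale `sigma_px`, the Hessian formulation originally devised for
#' blood-vessel enhancement. The image is convolved with scale-normalised
#' (`sigma^2`) Gaussian second-derivative kernels (replicate borders), the
#' Hessian eigenvalues `|lambda1| <= |lambda2|` are computed per pixel, and
#' the response is
#' `exp(-Rb^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))` with
#' `Rb = lambda1/lambda2` and `S = sqrt(lambda1^2 + lambda2^2)`, set to zero
#' wherever `lambda2 >= 0` (bright-ridge polarity). The output is
#' max-normalised to `[0, 1]` unless identically zero.
#'
#' @param frame A [pt_frame()] or a numeric intensity matrix.
#' @param sigma_px Positive scale in pixels; structures of full thickness
#'   about `2 * sigma_px` respond maximally.
#' @param beta Blob-suppression constant (default 0.5).
#' @param c Structure-sensitivity constant; `NULL` (default) uses half the
#'   maximum Hessian norm of the image.
#' @return List of class `pt_vesselness` with `values` (matrix in `[0, 1]`)
#'   and `scale_px`.
#' @export
frangi_filter <- function(frame, sigma_px, beta = 0.5, c = NULL) {
  img <- if (inherits(frame, "pt_frame")) frame$pixels else frame
  if (!is.numeric(sigma_px) || length(sigma_px) != 1L || sigma_px <= 0)
    pt_stop("pt_validation_error", "sigma_px must be a positive scalar")
  g0 <- gauss_kernel_1d(sigma_px, 0)
  g1 <- gauss_kernel_1d(sigma_px, 1)
  g2 <- gauss_kernel_1d(sigma_px, 2)
  s2 <- sigma_px^2
  # rows = y (depth), cols = x
  dxx <- s2 * conv_sep(img, g0, g2)
  dyy <- s2 * conv_sep(img, g2, g0)
  dxy <- s2 * conv_sep(img, g1, g1)

  tmp <- sqrt((dxx - dyy)^2 + 4 * dxy^2)
  mu1 <- (dxx + dyy + tmp) / 2
  mu2 <- (dxx + dyy - tmp) / 2
  # order by magnitude: |l1| <= |l2|
  swap <- abs(mu1) > abs(mu2)
  l1 <- ifelse(swap, mu2, mu1)
  l2 <- ifelse(swap, mu1, mu2)

  S2 <- l1^2 + l2^2
  if (is.null(c)) c <- sqrt(max(S2)) / 2
  v <- matrix(0, nrow(img), ncol(img))
  ok <- l2 < 0
  if (any(ok) && c > 0) {
    rb2 <- (l1[ok] / l2[ok])^2
    v[ok] <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-S2[ok] / (2 * c^2)))
  }
  mx <- max(v)
  if (mx > 0) v <- v / mx
  structure(list(values = v, scale_px = sigma_px), class = "pt_vesselness")
}

#' Fascicle filtering
#'
#' Vesselness at the fascicle scale `sigma_fas_px` followed by thresholding at
#' `t_fas`, yielding the binary fascicle image used for orientation
#' estimation.
#'
#' @param frame A [pt_frame()].
#' @param cfg A [pt_config()].
#' @return Logical matrix (`provenance` attribute `"fascicle"`).
#' @export
fascicle_filter <- function(frame, cfg) {
  v <- frangi_filter(frame, cfg$sigma_fas_px, beta = cfg$frangi_beta, c = cfg$frangi_c)
  structure(v$values >= cfg$t_fas & v$values > 0, provenance = "fascicle")
}

#' Aponeurosis filtering
#'
#' The thick-line branch: vesselness at `sigma_apo_px`, masking by the
#' thresholded original image (`>= t_apo`, reducing vesselness boundary
#' effects), restriction to the two user-defined depth regions, per-region
#' 2-D Gaussian smoothing with standard deviation `sigma_apo_px / 2`
#' (replicate borders, kernel truncated at 4 SD), and final thresholding at
#' `t_apo`.
#'
#' @inheritParams fascicle_filter
#' @return Logical matrix (`provenance` attribute `"aponeurosis"`).
#' @export
aponeurosis_filter <- function(frame, cfg) {
  v <- frangi_filter(frame, cfg$sigma_apo_px, beta = cfg$frangi_beta, c = cfg$frangi_c)$values
  masked <- v * (frame$pixels >= cfg$t_apo)
  h <- frame$height_px
  g <- gauss_kernel_1d(cfg$sigma_apo_px / 2, 0)
  out <- matrix(FALSE, h, frame$width_px)
  for (region in list(cfg$d_superficial, cfg$d_deep)) {
    rr <- region_rows(h, region)
    reg <- matrix(0, h, frame$width_px)
    reg[rr, ] <- masked[rr, ]
    sm <- conv_sep(reg, g, g)
    out <- out | (sm >= cfg$t_apo)
  }
  structure(out, provenance = "aponeurosis")
}

# Binary image handed to aponeurosis detection: the filtered chain when
# use_apo_filter is on, otherwise simply the thresholded original image
# (the vesselness filter may be omitted with the Hough method).
aponeurosis_binary <- function(frame, cfg) {
  if (cfg$use_apo_filter) aponeurosis_filter(frame, cfg)
  else structure(frame$pixels >= cfg$t_apo, provenance = "aponeurosis")
}
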