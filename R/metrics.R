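#' Full-reference error metrics
#'
#' Pixelwise fidelity measures between a clean reference and a test image on
#' the 0--255 scale: mean squared error, its square root, mean absolute
#' error, and peak signal-to-noise ratio
#' `PSNR = 10 * log10(max_value^2 / MSE)` in decibels (with `Inf` when
#' MSE = 0).
#'
#' @param reference,test numeric matrices of equal shape.
#' @param max_value peak signal value (255 for 8-bit images).
#' @return a single number.
#' @examples
#' a <- matrix(c(0, 10, 20, 30), 2)
#' b <- matrix(c(1, 12, 23, 26), 2)
#' iq_mse(a, b)   # 7.5
#' iq_psnr(a, a)  # Inf
#' @name error_metrics
NULL

#' @rdname error_metrics
#' @export
iq_mse <- function(reference, test) {
  reference <- as_plane(reference, "reference")
  test <- as_plane(test, "test")
  check_same_shape(reference, test)
  mean((reference - test)^2)
}

#' @rdname error_metrics
#' @export
iq_rmse <- function(reference, test) sqrt(iq_mse(reference, test))

#' @rdname error_metrics
#' @export
iq_mae <- function(reference, test) {
  reference <- as_plane(reference, "reference")
  test <- as_plane(test, "test")
  check_same_shape(reference, test)
  mean(abs(reference - test))
}

#' @rdname error_metrics
#' @export
iq_psnr <- function(reference, test, max_value = 255) {
  m <- iq_mse(reference, test)
  if (m == 0) return(Inf)
  10 * log10(max_value^2 / m)
}

#' Structural similarity index (SSIM)
#'
#' Windowed luminance/contrast/structure similarity
#' \deqn{SSIM = \frac{(2\mu_x\mu_y + c_1)(2\sigma_{xy} + c_2)}
#'   {(\mu_x^2 + \mu_y^2 + c_1)(\sigma_x^2 + \sigma_y^2 + c_2)}}
#' with \eqn{c_1 = (k_1 L)^2}, \eqn{c_2 = (k_2 L)^2}, averaged over all fully
#' interior windows. The default window is an 8x8 uniform sliding window; an
#' 11x11 Gaussian window (sigma 1.5) is available.
#'
#' @param reference,test numeric matrices of equal shape, at least as large
#'   as the window.
#' @param k1,k2 stabilising constants (0.01 and 0.03).
#' @param dynamic_range pixel dynamic range L (255 for 8-bit).
#' @param window `"uniform8"` or `"gaussian11"`.
#' @return mean SSIM over windows; 1 for identical images.
#' @export
iq_ssim <- function(reference, test, k1 = 0.01, k2 = 0.03,
                    dynamic_range = 255,
                    window = c("uniform8", "gaussian11")) {
  reference <- as_plane(reference, "reference")
  test <- as_plane(test, "test")
  check_same_shape(reference, test)
  window <- match.arg(window)
  w <- if (window == "uniform8") {
    rep(1 / 8, 8)
  } else {
    g <- dnorm(seq(-5, 5), sd = 1.5)
    g / sum(g)
  }
  if (min(dim(reference)) < length(w)) {
    stop(sprintf("image smaller than the %d-pixel SSIM window", length(w)),
         call. = FALSE)
  }
  c1 <- (k1 * dynamic_range)^2
  c2 <- (k2 * dynamic_range)^2
  mu_x <- sep_valid_filter(reference, w)
  mu_y <- sep_valid_filter(test, w)
  xx <- sep_valid_filter(reference * reference, w) - mu_x^2
  yy <- sep_valid_filter(test * test, w) - mu_y^2
  xy <- sep_valid_filter(reference * test, w) - mu_x * mu_y
  s <- ((2 * mu_x * mu_y + c1) * (2 * xy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (xx + yy + c2))
  mean(s)
}

#' Visual information fidelity (VIF), pixel domain
#'
#' Multi-scale pixel-domain VIF under the Gaussian scalar channel model: at
#' each of four scales, local means/variances/covariances over a Gaussian
#' window give per-window channel gains `g` and distortion variances; the
#' metric is the ratio of the information the distorted image retains about
#' the reference to the reference's own information content
#' (`sigma_nsq` is the channel noise variance). Ranges from ~0 (no shared
#' information) to 1 (perfect fidelity).
#'
#' @param reference,test numeric matrices of equal shape, minimum dimension
#'   >= 32.
#' @param sigma_nsq visual-channel noise variance (default 2).
#' @return VIF value, clipped below at 0.
#' @export
iq_vif <- function(reference, test, sigma_nsq = 2) {
  reference <- as_plane(reference, "reference")
  test <- as_plane(test, "test")
  check_same_shape(reference, test)
  if (min(dim(reference)) < 32L) {
    stop("VIF needs a minimum image dimension of 32", call. = FALSE)
  }
  eps <- 1e-10
  num <- 0
  den <- 0
  ref <- reference
  dst <- test
  for (scale in 1:4) {
    n <- 2^(4 - scale + 1) + 1
    g1 <- dnorm(seq(-(n - 1) / 2, (n - 1) / 2), sd = n / 5)
    g1 <- g1 / sum(g1)
    if (scale > 1) {
      ref <- sep_valid_filter(ref, g1)
      dst <- sep_valid_filter(dst, g1)
      ref <- ref[seq(1, nrow(ref), 2), seq(1, ncol(ref), 2), drop = FALSE]
      dst <- dst[seq(1, nrow(dst), 2), seq(1, ncol(dst), 2), drop = FALSE]
    }
    mu1 <- sep_valid_filter(ref, g1)
    mu2 <- sep_valid_filter(dst, g1)
    s1 <- pmax(sep_valid_filter(ref * ref, g1) - mu1^2, 0)
    s2 <- pmax(sep_valid_filter(dst * dst, g1) - mu2^2, 0)
    s12 <- sep_valid_filter(ref * dst, g1) - mu1 * mu2
    g <- s12 / (s1 + eps)
    sv <- s2 - g * s12
    g[s1 < eps] <- 0
    sv[s1 < eps] <- s2[s1 < eps]
    s1[s1 < eps] <- 0
    g[s2 < eps] <- 0
    sv[s2 < eps] <- 0
    sv[g < 0] <- s2[g < 0]
    g[g < 0] <- 0
    sv[sv < eps] <- eps
    num <- num + sum(log10(1 + g^2 * s1 / (sv + sigma_nsq)))
    den <- den + sum(log10(1 + s1 / sigma_nsq))
  }
  if (den == 0) return(1)
  max(num / den, 0)
}

# Sobel gradient-magnitude edge map; edges = top (1 - quantile) fraction of
# gradient magnitudes
sobel_edges <- function(x, edge_quantile = 0.9) {
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3)
  mag <- sqrt(.conv2_reflect(x, sx)^2 + .conv2_reflect(x, t(sx))^2)
  mag > quantile(mag, edge_quantile)
}

#' Pratt's figure of merit (FOM)
#'
#' Edge-preservation score: both images are reduced to binary edge maps
#' (Sobel gradient magnitude, thresholded at the top 10% by default), and
#' \deqn{FOM = \frac{1}{\max(N_{ref}, N_{test})}
#'   \sum_{test\ edges} \frac{1}{1 + \alpha d^2}}
#' where `d` is each detected edge pixel's Euclidean distance to the nearest
#' reference edge pixel. 1 means perfect edge correspondence; 0 means no
#' detected edges or none near reference edges.
#'
#' @param reference,test numeric matrices of equal shape.
#' @param alpha scaling constant of the distance penalty (default 1/9).
#' @param edge_quantile gradient-magnitude quantile above which a pixel
#'   counts as an edge (default 0.9, i.e. the top 10%).
#' @return FOM in \[0, 1\]; errors if the reference has no edge pixels.
#' @export
iq_fom <- function(reference, test, alpha = 1 / 9, edge_quantile = 0.9) {
  reference <- as_plane(reference, "reference")
  test <- as_plane(test, "test")
  check_same_shape(reference, test)
  e_ref <- sobel_edges(reference, edge_quantile)
  e_test <- sobel_edges(test, edge_quantile)
  n_ref <- sum(e_ref)
  n_test <- sum(e_test)
  if (n_ref == 0L) {
    stop("FOM undefined: reference image has no detected edge pixels",
         call. = FALSE)
  }
  if (n_test == 0L) return(0)
  d <- .edt_cpp(e_ref)
  sum(1 / (1 + alpha * d[e_test]^2)) / max(n_ref, n_test)
}

#' Population standard deviation
#'
#' Dispersion of a metric vector about its mean with divisor `N`
#' (population form), as used when reporting per-dataset metric spread.
#'
#' @param values numeric vector, length >= 1.
#' @return population standard deviation.
#' @examples
#' dispersion_sd(c(1, 2, 3, 4))  # sqrt(1.25)
#' @export
dispersion_sd <- function(values) {
  if (length(values) < 1L) stop("`values` must be non-empty", call. = FALSE)
  values <- as.numeric(values)
  sqrt(mean((values - mean(values))^2))
}

#' Evaluate one (reference, denoised) pair
#'
#' Computes the full metric battery for one image pair and returns it as a
#' one-row data frame in the report schema.
#'
#' @param reference,test numeric matrices of equal shape.
#' @param image_id label for the image.
#' @param method label for the denoiser that produced `test`.
#' @param elapsed_seconds measured wall time of the denoise call (pass 0 when
#'   not timed).
#' @return one-row `data.frame` with columns `image_id`, `method`, `psnr_db`,
#'   `ssim`, `mse`, `rmse`, `vif`, `fom`, `mae`, `time_s`.
#' @export
evaluate_pair <- function(reference, test, image_id = "image",
                          method = "method", elapsed_seconds = 0) {
  data.frame(
    image_id = as.character(image_id),
    method = as.character(method),
    psnr_db = iq_psnr(reference, test),
    ssim = iq_ssim(reference, test),
    mse = iq_mse(reference, test),
    rmse = iq_rmse(reference, test),
    vif = iq_vif(reference, test),
    fom = iq_fom(reference, test),
    mae = iq_mae(reference, test),
    time_s = as.numeric(elapsed_seconds),
    stringsAsFactors = FALSE)
}

#' Write a metric report CSV
#'
#' One row per (image, method) pair; infinite PSNR is written as the literal
#' `"inf"`.
#'
#' @param reports data frame of rows from [evaluate_pair()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_csv <- function(reports, path) {
  out <- reports
  out$psnr_db <- ifelse(is.infinite(out$psnr_db), "inf",
                        as.character(out$psnr_db))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
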