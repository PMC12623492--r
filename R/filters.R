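#' Bilateral filter
#'
#' Edge-preserving smoother: each pixel is replaced by an average of its
#' `diameter` x `diameter` neighbourhood, weighted by both spatial distance
#' (Gaussian with `sigma_spatial`) and intensity difference (Gaussian with
#' `sigma_intensity` on the 0--255 scale). Large intensity differences
#' suppress averaging across edges. Borders are reflected; constant images
#' are preserved exactly.
#'
#' @param image numeric matrix on the 0--255 scale.
#' @param diameter odd window side length (the neighbourhood parameter).
#' @param sigma_intensity range-kernel standard deviation, intensity units.
#' @param sigma_spatial spatial-kernel standard deviation in pixels; defaults
#'   to `diameter / 2`, coupling the falloff to the window.
#' @return filtered matrix, same shape.
#' @export
filter_bilateral <- function(image, diameter = 5L, sigma_intensity = 7,
                             sigma_spatial = diameter / 2) {
  image <- as_plane(image)
  diameter <- check_odd_size(diameter, "diameter")
  sigma_intensity <- check_positive(sigma_intensity, "sigma_intensity")
  sigma_spatial <- check_positive(sigma_spatial, "sigma_spatial")
  .bilateral_cpp(image, diameter, sigma_intensity, sigma_spatial)
}

#' Median filter
#'
#' Per-pixel window median with reflective borders; removes impulsive
#' (salt-and-pepper) noise without blurring step edges.
#'
#' @param image numeric matrix.
#' @param kernel_size odd window side length.
#' @return filtered matrix, same shape.
#' @export
filter_median <- function(image, kernel_size = 3L) {
  image <- as_plane(image)
  kernel_size <- check_odd_size(kernel_size, "kernel_size")
  .median_cpp(image, kernel_size)
}

#' Gaussian filter
#'
#' Convolution with [gauss_kernel()] and reflective borders.
#'
#' @param image numeric matrix.
#' @param sigma kernel standard deviation in pixels.
#' @param kernel_size odd kernel side length.
#' @return filtered matrix, same shape.
#' @export
filter_gaussian <- function(image, sigma = 0.7, kernel_size = 5L) {
  image <- as_plane(image)
  .conv2_reflect(image, unclass(gauss_kernel(sigma, kernel_size)))
}
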