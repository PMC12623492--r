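#' Gaussian smoothing kernel
#'
#' Samples the isotropic Gaussian \eqn{G_\sigma(x, y) \propto
#' \exp(-(x^2 + y^2) / (2\sigma^2))} on an odd `size` x `size` grid centred at
#' the origin and renormalises the taps to sum to one. This kernel drives both
#' pyramid construction ([pyr_reduce()]) and plain Gaussian filtering
#' ([filter_gaussian()]).
#'
#' @param sigma positive standard deviation, in pixels; controls blurring.
#' @param size odd integer side length, between 3 and 31.
#' @return a `size` x `size` numeric matrix of class `"gauss_kernel"` whose
#'   entries sum to 1, with `sigma` and `size` attached as attributes.
#' @examples
#' k <- gauss_kernel(0.7, 5)
#' sum(k)          # 1
#' which.max(k)    # centre tap
#' @export
gauss_kernel <- function(sigma, size) {
  sigma <- check_positive(sigma, "sigma")
  size <- check_odd_size(size, "size")
  if (size > 31L) stop("`size` must be <= 31", call. = FALSE)
  h <- (size - 1L) / 2L
  g <- seq.int(-h, h)
  w <- exp(-g^2 / (2 * sigma^2))
  k <- outer(w, w)
  k <- k / sum(k)
  structure(k, sigma = sigma, size = size, class = c("gauss_kernel", "matrix"))
}

#' Reduce: blur and 2x-decimate one pyramid level
#'
#' Computes \eqn{I_{l+1}(x, y) = \sum_i \sum_j G(i, j)\, I_l(2x + i, 2y + j)}
#' with reflective (mirror-without-repeat) border handling. Output dimensions
#' are `ceiling(dim(image) / 2)`, so odd sizes are handled losslessly by the
#' shape bookkeeping in [build_pyramid()].
#'
#' @param image numeric matrix on the 0--255 scale, minimum dimension >= 2.
#' @param kernel a [gauss_kernel()]; defaults to `gauss_kernel(1, 5)`.
#' @return numeric matrix of size `ceiling(dim(image) / 2)`.
#' @export
pyr_reduce <- function(image, kernel = gauss_kernel(1, 5)) {
  image <- as_plane(image)
  if (min(dim(image)) < 2L) {
    stop("image too small to reduce: minimum dimension must be >= 2",
         call. = FALSE)
  }
  .reduce_cpp(image, unclass(kernel))
}

#' Expand: upsample one pyramid level to a recorded target shape
#'
#' Zero-stuffs the level onto the target grid (known samples at even
#' coordinates) and interpolates the missing pixels by normalised convolution:
#' the stuffed plane and its sampling mask are both convolved with the kernel
#' and divided elementwise. This estimates every missing pixel as a
#' kernel-weighted average of the known neighbours, preserves constants
#' exactly for any normalised kernel, and keeps mean brightness unchanged.
#'
#' @param image numeric matrix (a coarse pyramid level).
#' @param target_shape integer vector `c(height, width)`; each axis must be
#'   `2 * dim` or `2 * dim - 1` of the input (the shape recorded at reduce
#'   time).
#' @param kernel a [gauss_kernel()]; defaults to `gauss_kernel(1, 5)`.
#' @return numeric matrix of dimension `target_shape`.
#' @export
pyr_expand <- function(image, target_shape, kernel = gauss_kernel(1, 5)) {
  image <- as_plane(image)
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 2L || any(!is.finite(target_shape))) {
    stop("`target_shape` must be c(height, width)", call. = FALSE)
  }
  ok <- target_shape == 2L * dim(image) | target_shape == 2L * dim(image) - 1L
  if (!all(ok)) {
    stop(sprintf(
      "target shape %dx%d is incompatible with input %dx%d (must be 2n or 2n-1)",
      target_shape[1], target_shape[2], nrow(image), ncol(image)),
      call. = FALSE)
  }
  stuffed <- matrix(0, target_shape[1], target_shape[2])
  mask <- stuffed
  rows <- seq.int(1L, target_shape[1], by = 2L)
  cols <- seq.int(1L, target_shape[2], by = 2L)
  stuffed[rows, cols] <- image
  mask[rows, cols] <- 1
  k <- unclass(kernel)
  .conv2_reflect(stuffed, k) / .conv2_reflect(mask, k)
}

#' Maximum feasible Gaussian-pyramid depth for an image size
#'
#' Depth is limited by requiring the coarsest level to keep a minimum
#' dimension of at least 2 pixels under repeated ceiling-halving.
#'
#' @param dims integer vector `c(height, width)`.
#' @return the largest usable `n_levels`.
#' @export
max_pyramid_depth <- function(dims) {
  d <- as.integer(dims)
  depth <- 1L
  while (all(ceiling(d / 2L) >= 2L)) {
    d <- ceiling(d / 2L)
    depth <- depth + 1L
  }
  depth
}

#' Build a Gaussian pyramid
#'
#' Level 0 is the input; each subsequent level is [pyr_reduce()] of the one
#' before. The per-level shapes are recorded so [pyr_expand()] can return to
#' the exact original dimensions for odd sizes.
#'
#' @param image numeric matrix on the 0--255 scale.
#' @param n_levels number of levels (>= 1); the coarsest level must keep a
#'   minimum dimension >= 2.
#' @param kernel smoothing kernel used for every reduce step.
#' @return an object of class `"gauss_pyramid"`: a list with `levels` (list of
#'   matrices, finest first), `kernel`, and `shapes` (per-level dim).
#' @examples
#' p <- build_pyramid(matrix(runif(64 * 64, 0, 255), 64), n_levels = 4)
#' sapply(p$levels, dim)
#' @export
build_pyramid <- function(image, n_levels = 5L, kernel = gauss_kernel(1, 5)) {
  image <- as_plane(image)
  if (length(n_levels) != 1L || !is.finite(n_levels) || n_levels < 1L) {
    stop("`n_levels` must be an integer >= 1", call. = FALSE)
  }
  n_levels <- as.integer(n_levels)
  feasible <- max_pyramid_depth(dim(image))
  if (n_levels > feasible) {
    stop(sprintf(
      "n_levels = %d too deep for a %dx%d image; maximum feasible depth is %d",
      n_levels, nrow(image), ncol(image), feasible), call. = FALSE)
  }
  levels <- vector("list", n_levels)
  levels[[1L]] <- image
  if (n_levels > 1L) {
    for (l in 2:n_levels) levels[[l]] <- pyr_reduce(levels[[l - 1L]], kernel)
  }
  structure(
    list(levels = levels, kernel = kernel, shapes = lapply(levels, dim)),
    class = "gauss_pyramid")
}

#' @export
print.gauss_pyramid <- function(x, ...) {
  cat(sprintf("Gaussian pyramid: %d level(s)\n", length(x$levels)))
  for (l in seq_along(x$levels)) {
    cat(sprintf("  level %d: %d x %d\n", l - 1L,
                nrow(x$levels[[l]]), ncol(x$levels[[l]])))
  }
  cat(sprintf("  kernel: size %d, sigma %.3g\n",
              attr(x$kernel, "size"), attr(x$kernel, "sigma")))
  invisible(x)
}

#' Coarse-to-fine reconstruction from per-level planes
#'
#' Recombines (possibly filtered) pyramid levels by Laplacian-style
#' telescoping: starting from the coarsest plane, each step expands the
#' running estimate to the next finer shape and adds that level's detail band
#' `denoised_l - expand(pyramid_l+1)` (the filtered level minus the expansion
#' of the unfiltered next-coarser level). Equivalently, the output is the
#' finest filtered plane plus the expand-chain of every coarser level's
#' filtering correction, so coarse-level filtering acts on the low
#' frequencies of the result. When `denoised_levels` are the pyramid's own
#' levels every correction vanishes and the original image is recovered
#' exactly (telescoping identity).
#'
#' @param denoised_levels list of matrices, one per pyramid level (finest
#'   first), with the same shapes as `pyramid$levels`.
#' @param pyramid a `"gauss_pyramid"` (supplies shapes and the kernel).
#' @return numeric matrix with the finest level's shape.
#' @export
pyr_reconstruct <- function(denoised_levels, pyramid) {
  if (!inherits(pyramid, "gauss_pyramid")) {
    stop("`pyramid` must be a gauss_pyramid", call. = FALSE)
  }
  n <- length(pyramid$levels)
  if (length(denoised_levels) != n) {
    stop(sprintf("expected %d level planes, got %d", n,
                 length(denoised_levels)), call. = FALSE)
  }
  denoised_levels <- lapply(denoised_levels, as_plane)
  for (l in seq_len(n)) {
    if (!identical(dim(denoised_levels[[l]]), pyramid$shapes[[l]])) {
      stop(sprintf("level %d shape mismatch: expected %dx%d, got %dx%d",
                   l - 1L, pyramid$shapes[[l]][1], pyramid$shapes[[l]][2],
                   nrow(denoised_levels[[l]]), ncol(denoised_levels[[l]])),
           call. = FALSE)
    }
  }
  out <- denoised_levels[[n]]
  if (n > 1L) {
    for (l in seq.int(n - 1L, 1L)) {
      up <- pyr_expand(out, pyramid$shapes[[l]], pyramid$kernel)
      detail <- denoised_levels[[l]] -
        pyr_expand(pyramid$levels[[l + 1L]], pyramid$shapes[[l]],
                   pyramid$kernel)
      out <- up + detail
    }
  }
  out
}
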