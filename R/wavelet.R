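# Orthogonal wavelet filter banks. Taps are the standard published
# coefficients for each family (decomposition low-pass; the high-pass is the
# quadrature mirror, and the synthesis operator is the adjoint of analysis).
.wavelet_dec_lo <- list(
  haar = c(0.70710678118654757, 0.70710678118654757),
  db4 = c(-0.010597401785069032, 0.032883011666885197, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.63088076792985892,
          0.71484657055291567, 0.23037781330889651),
  coif4 = c(-1.7849909144933469e-06, -3.259647940030751e-06,
            3.1229861599195265e-05, 6.2338854312787192e-05,
            -0.00025997433712225682, -0.00058902022463321654,
            0.0012665610789256603, 0.0037514346971460866,
            -0.0056582838001308835, -0.015211728187697211,
            0.025082253337949612, 0.039334422605589149,
            -0.096220424535952642, -0.066627472366817167,
            0.43438603311435653, 0.78223893442428261, 0.41530842700068227,
            -0.056077319603569258, -0.081266710249193727,
            0.02668230466960483, 0.016068947131575029,
            -0.0073461679362680507, -0.001629492425226786,
            0.00089231390253700297),
  sym4 = c(-0.075765714789273325, -0.02963552764599851, 0.49761866763201545,
           0.80373875180591614, 0.29785779560527736, -0.099219543576847216,
           -0.012603967262037833, 0.032223100604042702))

#' Orthogonal wavelet family
#'
#' Returns the analysis filter bank for one of the supported orthogonal
#' families. The high-pass filter is the quadrature mirror of the low-pass:
#' `g[m] = (-1)^m * h[L - 1 - m]`.
#'
#' @param name one of `"haar"`, `"db4"`, `"coif4"`, `"sym4"`.
#' @return a `"wavelet_family"` list with `name`, `dec_lo`, `dec_hi`, and the
#'   filter `length`.
#' @examples
#' sum(wavelet_family("db4")$dec_lo^2)   # orthonormal: 1
#' @export
wavelet_family <- function(name = c("haar", "db4", "coif4", "sym4")) {
  name <- match.arg(name)
  h <- .wavelet_dec_lo[[name]]
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1L)
  structure(list(name = name, dec_lo = h, dec_hi = g, length = L),
            class = "wavelet_family")
}

#' @export
print.wavelet_family <- function(x, ...) {
  cat(sprintf("orthogonal wavelet family '%s' (%d taps)\n", x$name, x$length))
  invisible(x)
}

# pad a plane to even dimensions by edge replication; records nothing --
# callers keep the original dims
pad_even <- function(x) {
  if (nrow(x) %% 2L == 1L) x <- rbind(x, x[nrow(x), , drop = FALSE])
  if (ncol(x) %% 2L == 1L) x <- cbind(x, x[, ncol(x), drop = FALSE])
  x
}

#' Multi-level 2-D wavelet decomposition
#'
#' Separable periodized analysis: at each level the current approximation is
#' split into the four subbands LL (approximation), LH, HL, HH (detail
#' orientations), and the transform recurses on LL. Odd-sized planes are
#' padded to even length by edge replication before each split; the original
#' shape at every level is recorded so [wt_reconstruct()] crops back exactly.
#' For orthogonal banks the round trip is exact to machine precision at any
#' size and depth.
#'
#' @param image numeric matrix.
#' @param family family name or a [wavelet_family()] object.
#' @param n_levels decomposition depth (>= 1); every level must keep a
#'   minimum dimension >= 2 after padding.
#' @return a `"subband_tree"`: list with `approx` (final LL), `details`
#'   (list per level of LH/HL/HH matrices, finest level first), `family`,
#'   `n_levels`, and `shapes` (per-level pre-split dims).
#' @export
wt_decompose <- function(image, family = "db4", n_levels = 2L) {
  image <- as_plane(image)
  if (is.character(family)) family <- wavelet_family(family)
  if (length(n_levels) != 1L || !is.finite(n_levels) || n_levels < 1L) {
    stop("`n_levels` must be an integer >= 1", call. = FALSE)
  }
  n_levels <- as.integer(n_levels)
  cur <- image
  details <- vector("list", n_levels)
  shapes <- vector("list", n_levels)
  for (l in seq_len(n_levels)) {
    if (min(dim(cur)) < 2L) {
      stop(sprintf(
        "decomposition depth %d infeasible: level %d plane is %dx%d",
        n_levels, l - 1L, nrow(cur), ncol(cur)), call. = FALSE)
    }
    shapes[[l]] <- dim(cur)
    sb <- .dwt2_per_cpp(pad_even(cur), family$dec_lo, family$dec_hi)
    details[[l]] <- list(LH = sb$LH, HL = sb$HL, HH = sb$HH)
    cur <- sb$LL
  }
  structure(list(approx = cur, details = details, family = family,
                 n_levels = n_levels, shapes = shapes),
            class = "subband_tree")
}

#' @export
print.subband_tree <- function(x, ...) {
  cat(sprintf("wavelet subband tree: '%s', %d level(s), image %d x %d\n",
              x$family$name, x$n_levels, x$shapes[[1]][1], x$shapes[[1]][2]))
  for (l in seq_len(x$n_levels)) {
    cat(sprintf("  level %d details: %d x %d\n", l,
                nrow(x$details[[l]]$HH), ncol(x$details[[l]]$HH)))
  }
  cat(sprintf("  approximation: %d x %d\n", nrow(x$approx), ncol(x$approx)))
  invisible(x)
}

#' Robust noise estimate from the finest diagonal subband
#'
#' `sigma_hat = median(|HH1|) / 0.6745`, the conventional estimator of the
#' additive-noise standard deviation from wavelet coefficients.
#'
#' @param tree a `"subband_tree"`.
#' @return estimated noise standard deviation.
#' @export
estimate_noise_sigma <- function(tree) {
  stopifnot(inherits(tree, "subband_tree"))
  median(abs(tree$details[[1L]]$HH)) / 0.6745
}

#' Threshold the detail coefficients of a subband tree
#'
#' Hard thresholding keeps a coefficient unchanged when `|w| >= T` and zeroes
#' it otherwise; soft thresholding shrinks every coefficient towards zero:
#' `sign(w) * max(|w| - T, 0)`. The approximation plane is never thresholded.
#'
#' With `threshold = "universal"` the VisuShrink rule is used:
#' `T = sigma_hat * sqrt(2 * log(N))` with `sigma_hat` from
#' [estimate_noise_sigma()]. Under `scope = "global"` (default) `N` is the
#' image pixel count and one `T` applies to all levels; under
#' `scope = "per-level"` `N` is the detail-coefficient count of each level
#' and `T` is recomputed per level.
#'
#' @param tree a `"subband_tree"`.
#' @param mode `"soft"` or `"hard"`.
#' @param threshold `"universal"` or a fixed non-negative number.
#' @param scope `"global"` or `"per-level"` (universal selector only).
#' @return a thresholded `"subband_tree"`; the applied threshold(s) are
#'   attached as attribute `"threshold"`.
#' @export
wt_threshold <- function(tree, mode = c("soft", "hard"),
                         threshold = "universal",
                         scope = c("global", "per-level")) {
  stopifnot(inherits(tree, "subband_tree"))
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  n_lev <- tree$n_levels
  if (is.character(threshold)) {
    if (!identical(threshold, "universal")) {
      stop("`threshold` must be \"universal\" or a fixed number",
           call. = FALSE)
    }
    sigma_hat <- estimate_noise_sigma(tree)
    if (scope == "global") {
      n_pix <- prod(tree$shapes[[1L]])
      tvals <- rep(sigma_hat * sqrt(2 * log(n_pix)), n_lev)
    } else {
      tvals <- vapply(tree$details, function(d) {
        sigma_hat * sqrt(2 * log(3 * length(d$HH)))
      }, numeric(1))
    }
  } else {
    if (!is.numeric(threshold) || length(threshold) != 1L ||
        !is.finite(threshold) || threshold < 0) {
      stop("fixed `threshold` must be a single number >= 0", call. = FALSE)
    }
    tvals <- rep(as.numeric(threshold), n_lev)
  }
  shrink <- function(w, tval) {
    if (mode == "hard") w * (abs(w) >= tval)
    else sign(w) * pmax(abs(w) - tval, 0)
  }
  for (l in seq_len(n_lev)) {
    tree$details[[l]] <- lapply(tree$details[[l]], shrink, tval = tvals[l])
  }
  attr(tree, "threshold") <- tvals
  tree
}

#' Inverse 2-D wavelet transform
#'
#' Applies the adjoint periodized synthesis level by level, cropping each
#' reconstruction to the shape recorded at decomposition time.
#'
#' @param tree a `"subband_tree"`.
#' @return numeric matrix with the original image shape.
#' @export
wt_reconstruct <- function(tree) {
  stopifnot(inherits(tree, "subband_tree"))
  cur <- tree$approx
  for (l in seq.int(tree$n_levels, 1L)) {
    d <- tree$details[[l]]
    if (!identical(dim(d$LH), dim(cur)) || !identical(dim(d$HL), dim(cur)) ||
        !identical(dim(d$HH), dim(cur))) {
      stop(sprintf("corrupted subband shapes at level %d", l), call. = FALSE)
    }
    cur <- .idwt2_per_cpp(cur, d$LH, d$HL, d$HH,
                          tree$family$dec_lo, tree$family$dec_hi)
    sh <- tree$shapes[[l]]
    cur <- cur[seq_len(sh[1]), seq_len(sh[2]), drop = FALSE]
  }
  cur
}

#' Wavelet-shrinkage denoising
#'
#' Decompose, threshold the detail coefficients, reconstruct.
#'
#' @inheritParams wt_decompose
#' @inheritParams wt_threshold
#' @return denoised numeric matrix (0--255 scale, not clipped).
#' @examples
#' x <- make_phantom("geometric_shapes", c(64, 64), seed = 1)
#' y <- add_noise(x, "gaussian", list(sigma = 15), seed = 1)
#' d <- denoise_wavelet(y, "db4", n_levels = 2, mode = "soft")
#' @export
denoise_wavelet <- function(image, family = "db4", n_levels = 2L,
                            mode = c("soft", "hard"),
                            threshold = "universal",
                            scope = c("global", "per-level")) {
  tree <- wt_decompose(image, family, n_levels)
  tree <- wt_threshold(tree, mode = mode, threshold = threshold,
                       scope = scope)
  wt_reconstruct(tree)
}
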