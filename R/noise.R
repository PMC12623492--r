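#' Deterministic clean test phantoms
#'
#' Generates seeded synthetic reference images on the 0--255 scale containing
#' both smooth regions and sharp edges, so PSNR, SSIM, and FOM all exercise
#' non-trivially. Kinds:
#' \describe{
#'   \item{`shepp_like`}{concentric ellipses of distinct intensity plateaus
#'     on a dark background, in the spirit of CT head phantoms.}
#'   \item{`geometric_shapes`}{rectangles and discs of several intensities on
#'     a smooth gradient background.}
#'   \item{`gradient_texture`}{smooth two-dimensional ramp plus a sinusoidal
#'     texture.}
#'   \item{`edge_grid`}{checker-like block grid: many straight edges.}
#' }
#'
#' @param kind phantom kind (see above).
#' @param size integer `c(height, width)`, each >= 32.
#' @param seed integer seed; the same spec always yields the same image.
#' @return numeric matrix in \[0, 255\].
#' @examples
#' p <- make_phantom("shepp_like", c(128, 128), seed = 7)
#' range(p)
#' @export
make_phantom <- function(kind = c("shepp_like", "geometric_shapes",
                                  "gradient_texture", "edge_grid"),
                         size = c(256L, 256L), seed = 1L) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 32L)) {
    stop("`size` must be c(height, width) with both >= 32", call. = FALSE)
  }
  nr <- size[1]; nc <- size[2]
  yy <- matrix(seq_len(nr), nr, nc)                 # row coordinate
  xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)   # column coordinate
  u <- (xx - (nc + 1) / 2) / (nc / 2)               # in [-1, 1]
  v <- (yy - (nr + 1) / 2) / (nr / 2)
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  img <- switch(kind,
    shepp_like = {
      z <- matrix(20, nr, nc)
      z[(u / 0.92)^2 + (v / 0.95)^2 <= 1] <- 60
      z[(u / 0.82)^2 + (v / 0.85)^2 <= 1] <- 110
      z[((u + 0.25) / 0.30)^2 + ((v - 0.05) / 0.45)^2 <= 1] <- 160
      z[((u - 0.25) / 0.28)^2 + ((v - 0.05) / 0.42)^2 <= 1] <- 190
      z[(u / 0.12)^2 + ((v + 0.45) / 0.15)^2 <= 1] <- 235
      z
    },
    geometric_shapes = {
      z <- 40 + 60 * (xx - 1) / (nc - 1) + 30 * (yy - 1) / (nr - 1)
      for (i in 1:4) {
        r0 <- sample.int(nr - nr %/% 4, 1)
        c0 <- sample.int(nc - nc %/% 4, 1)
        z[r0:(r0 + nr %/% 5), c0:(c0 + nc %/% 5)] <- sample(
          c(15, 90, 170, 240), 1)
      }
      for (i in 1:3) {
        cy <- runif(1, -0.6, 0.6); cx <- runif(1, -0.6, 0.6)
        rad <- runif(1, 0.1, 0.25)
        z[(u - cx)^2 + (v - cy)^2 <= rad^2] <- sample(c(30, 130, 220), 1)
      }
      z
    },
    gradient_texture = {
      base <- 60 + 120 * (xx - 1) / (nc - 1)
      tex <- 25 * sin(2 * pi * xx / 16) * cos(2 * pi * yy / 24)
      base + tex + 20 * (yy - 1) / (nr - 1)
    },
    edge_grid = {
      block <- max(8L, min(nr, nc) %/% 16L)
      lev <- c(30, 90, 150, 210)
      idx <- ((yy - 1L) %/% block + (xx - 1L) %/% block) %% 4L + 1L
      matrix(lev[idx], nr, nc)
    })
  pmin(pmax(img, 0), 255)
}

# save/restore the global RNG state so seeded generators do not disturb the
# caller's random stream
save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# default severity parameters per noise family, calibrated once so that
# noisy-input PSNR on the phantoms falls in roughly the 18-28 dB band
.noise_defaults <- list(
  gaussian = list(sigma = 15),
  lognormal = list(sdlog = 0.5, sd = 15),
  uniform = list(half_width = 26),
  exponential = list(sd = 15),
  poisson = list(gain = 0.5),
  salt_pepper = list(density = 0.05),
  rayleigh = list(sd = 15),
  speckle = list(sigma_u = 0.12),
  erlang = list(shape = 2, sd = 15))

#' Names of the supported noise families
#' @return character vector of the nine family names.
#' @export
noise_families <- function() names(.noise_defaults)

#' Add synthetic noise of a named family
#'
#' Implements the additive observation model `I_n = I + N` for the nine
#' supported families. Additive non-Gaussian families (lognormal, uniform,
#' exponential, Rayleigh, Erlang) are location-shifted so the added noise has
#' mean zero (set `center = FALSE` for the raw, positively biased draws).
#' `poisson` converts intensities to photon counts with `gain` counts per
#' intensity unit, draws Poisson counts, and rescales, so the noise variance
#' equals `I / gain` (signal-dependent). `speckle` is multiplicative:
#' `I * (1 + u)`, `u ~ N(0, sigma_u^2)`. `salt_pepper` sets a `density`
#' fraction of pixels to 0 or 255 equiprobably. The result is not clipped;
#' clip at export with [clip_to_uint8()].
#'
#' @param image numeric matrix on the 0--255 scale.
#' @param family one of [noise_families()].
#' @param params named list of family parameters; unspecified entries take
#'   the calibrated defaults.
#' @param seed integer seed: identical (image, family, params, seed) always
#'   yields an identical noisy image.
#' @param center logical; location-shift additive non-Gaussian families to
#'   mean zero (default `TRUE`).
#' @return noisy numeric matrix, same shape.
#' @examples
#' x <- make_phantom("edge_grid", c(64, 64))
#' y <- add_noise(x, "gaussian", list(sigma = 10), seed = 3)
#' sd(y - x)  # ~10
#' @export
add_noise <- function(image, family, params = list(), seed = 1L,
                      center = TRUE) {
  image <- as_plane(image)
  if (!family %in% names(.noise_defaults)) {
    stop(sprintf("unknown noise family '%s'", family), call. = FALSE)
  }
  p <- utils::modifyList(.noise_defaults[[family]], params)
  n <- length(image)
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  out <- switch(family,
    gaussian = image + rnorm(n, 0, p$sigma),
    lognormal = {
      # lognormal(0, sdlog) rescaled to standard deviation `sd`
      raw <- rlnorm(n, 0, p$sdlog)
      raw <- raw * p$sd / sqrt((exp(p$sdlog^2) - 1) * exp(p$sdlog^2))
      image + raw - if (center) mean_lognormal_scaled(p) else 0
    },
    uniform = {
      raw <- runif(n, 0, 2 * p$half_width)
      image + raw - if (center) p$half_width else 0
    },
    exponential = {
      raw <- rexp(n, rate = 1 / p$sd)   # sd = mean = 1/rate
      image + raw - if (center) p$sd else 0
    },
    poisson = {
      lam <- pmax(image, 0) * p$gain
      noisy <- rpois(n, lam) / p$gain
      matrix(noisy, nrow(image)) + pmin(image, 0)   # keep any negatives
    },
    salt_pepper = {
      z <- image
      hit <- which(runif(n) < p$density)
      z[hit] <- 255 * rbinom(length(hit), 1, 0.5)
      z
    },
    rayleigh = {
      # Rayleigh(scale) has sd = scale * sqrt(2 - pi/2)
      scale <- p$sd / sqrt(2 - pi / 2)
      raw <- scale * sqrt(-2 * log(runif(n)))
      image + raw - if (center) scale * sqrt(pi / 2) else 0
    },
    speckle = image * (1 + rnorm(n, 0, p$sigma_u)),
    erlang = {
      # Erlang(shape k, scale) has sd = scale * sqrt(k)
      scale <- p$sd / sqrt(p$shape)
      raw <- rgamma(n, shape = p$shape, scale = scale)
      image + raw - if (center) p$shape * scale else 0
    })
  matrix(out, nrow(image), ncol(image))
}

mean_lognormal_scaled <- function(p) {
  s <- p$sd / sqrt((exp(p$sdlog^2) - 1) * exp(p$sdlog^2))
  s * exp(p$sdlog^2 / 2)
}

#' Signal-dependent camera noise composition
#'
#' Emulates a sensor pipeline: a static per-pixel multiplicative gain field
#' (fixed-pattern noise, drawn once per seed), then Poisson shot noise
#' (signal-dependent), then additive Gaussian read noise
#' (signal-independent), then impulsive defects. With every parameter at 0
#' the image passes through unchanged.
#'
#' @param image numeric matrix on the 0--255 scale.
#' @param shot_gain photon counts per intensity unit (0 disables shot
#'   noise; larger gain = less shot noise).
#' @param read_sigma read-noise standard deviation (0 disables).
#' @param fpn_sigma relative standard deviation of the fixed-pattern gain
#'   field (0 disables).
#' @param impulse_density fraction of pixels replaced by 0/255 impulses.
#' @param seed integer seed.
#' @return noisy numeric matrix, same shape.
#' @export
camera_mix <- function(image, shot_gain = 2, read_sigma = 5,
                       fpn_sigma = 0.02, impulse_density = 0.002,
                       seed = 1L) {
  image <- as_plane(image)
  stopifnot(shot_gain >= 0, read_sigma >= 0, fpn_sigma >= 0,
            impulse_density >= 0, impulse_density <= 1)
  n <- length(image)
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  out <- image
  if (fpn_sigma > 0) {
    gain_field <- matrix(rnorm(n, 1, fpn_sigma), nrow(image))
    out <- out * gain_field
  }
  if (shot_gain > 0) {
    out <- matrix(rpois(n, pmax(out, 0) * shot_gain) / shot_gain,
                  nrow(image)) + pmin(out, 0)
  }
  if (read_sigma > 0) out <- out + rnorm(n, 0, read_sigma)
  if (impulse_density > 0) {
    hit <- which(runif(n) < impulse_density)
    out[hit] <- 255 * rbinom(length(hit), 1, 0.5)
  }
  out
}

#' Generate a seeded synthetic benchmark set on disk
#'
#' Writes paired clean/noisy PNGs plus a CSV manifest, standing in for an
#' external evaluation dataset. Fully reproducible: the same arguments always
#' produce identical files.
#'
#' @param out_dir output directory (created if missing).
#' @param n_images number of images (>= 1).
#' @param phantom_kinds phantom kinds to cycle through.
#' @param families noise families to cycle through.
#' @param params named list: per-family parameter overrides.
#' @param size image size `c(height, width)`.
#' @param seed master seed; per-image seeds are derived from it.
#' @return data frame manifest with columns `image_id`, `path_clean`,
#'   `path_noisy`, `family`, `params`, `seed`; also written to
#'   `manifest.csv` in `out_dir`.
#' @export
make_benchmark_set <- function(out_dir, n_images = 10L,
                               phantom_kinds = c("shepp_like",
                                                 "geometric_shapes",
                                                 "gradient_texture",
                                                 "edge_grid"),
                               families = "gaussian", params = list(),
                               size = c(128L, 128L), seed = 1L) {
  if (n_images < 1L) stop("`n_images` must be >= 1", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    kind <- phantom_kinds[[(i - 1L) %% length(phantom_kinds) + 1L]]
    family <- families[[(i - 1L) %% length(families) + 1L]]
    img_seed <- seed * 1000L + i
    clean <- make_phantom(kind, size, seed = img_seed)
    fam_params <- if (!is.null(params[[family]])) params[[family]] else list()
    noisy <- add_noise(clean, family, fam_params, seed = img_seed)
    id <- sprintf("img%03d_%s_%s", i, kind, family)
    path_clean <- file.path(out_dir, paste0(id, "_clean.png"))
    path_noisy <- file.path(out_dir, paste0(id, "_noisy.png"))
    write_image(clean, path_clean)
    write_image(noisy, path_noisy)
    all_params <- utils::modifyList(.noise_defaults[[family]], fam_params)
    rows[[i]] <- data.frame(
      image_id = id, path_clean = path_clean, path_noisy = path_noisy,
      family = family,
      params = as.character(jsonlite::toJSON(all_params, auto_unbox = TRUE)),
      seed = img_seed, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}
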