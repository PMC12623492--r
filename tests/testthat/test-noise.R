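test_that("phantoms are deterministic and structurally non-trivial", {
  for (kind in c("shepp_like", "geometric_shapes", "gradient_texture",
                 "edge_grid")) {
    a <- make_phantom(kind, c(64, 64), seed = 3)
    b <- make_phantom(kind, c(64, 64), seed = 3)
    expect_identical(a, b)
    expect_true(all(a >= 0 & a <= 255))
  }
  expect_error(make_phantom("shepp_like", c(16, 64)), ">= 32")

  # edge_grid must give FOM a well-defined reference
  eg <- make_phantom("edge_grid", c(64, 64))
  expect_gt(sum(pyrwave:::sobel_edges(eg)), 0)

  # shepp-like phantom has at least 4 distinct intensity plateaus
  sh <- make_phantom("shepp_like", c(256, 256))
  counts <- table(round(sh))
  expect_gte(sum(counts > 500), 4)
})

test_that("noise is seed-deterministic and seed-sensitive", {
  x <- make_phantom("gradient_texture", c(64, 64))
  for (fam in noise_families()) {
    a <- add_noise(x, fam, seed = 9)
    b <- add_noise(x, fam, seed = 9)
    cc <- add_noise(x, fam, seed = 10)
    expect_identical(a, b, label = fam)
    expect_gt(mean(abs(a - cc)), 0)
  }
  expect_error(add_noise(x, "perlin"), "unknown noise family")
})

test_that("additive families are mean-zero with the requested spread", {
  x <- matrix(128, 128, 128)
  for (fam in c("gaussian", "lognormal", "uniform", "exponential",
                "rayleigh", "erlang")) {
    devs <- vapply(1:10, function(s) {
      d <- add_noise(x, fam, seed = s) - x
      c(mean(d), sd(d))
    }, numeric(2))
    expect_lt(abs(mean(devs[1, ])), 0.5)   # centred
    target <- if (fam == "uniform") 26 / sqrt(3) else 15
    expect_lt(abs(mean(devs[2, ]) - target) / target, 0.02, label = fam)
  }
  # uncentred draws keep the family's positive bias
  d_raw <- add_noise(x, "exponential", seed = 1, center = FALSE) - x
  expect_gt(mean(d_raw), 10)
})

test_that("gaussian sigma moment check across seeds", {
  x <- matrix(128, 256, 256)
  sds <- vapply(1:10, function(s) {
    sd(add_noise(x, "gaussian", list(sigma = 15), seed = s) - x)
  }, 1)
  expect_true(all(abs(sds - 15) / 15 < 0.02))
})

test_that("salt-and-pepper corrupts the requested pixel fraction", {
  x <- matrix(128, 128, 128)
  fr <- vapply(1:10, function(s) {
    mean(add_noise(x, "salt_pepper", list(density = 0.05), seed = s) != 128)
  }, 1)
  expect_true(all(abs(fr - 0.05) < 0.01))
  y <- add_noise(x, "salt_pepper", seed = 1)
  expect_true(all(y[y != 128] %in% c(0, 255)))
})

test_that("poisson noise obeys the mean/gain variance law", {
  for (gain in c(0.25, 0.5, 1)) {
    x <- matrix(100, 256, 256)
    v <- vapply(1:10, function(s) {
      var(as.vector(add_noise(x, "poisson", list(gain = gain), seed = s) - x))
    }, 1)
    expect_lt(abs(mean(v) - 100 / gain) / (100 / gain), 0.05)
  }
})

test_that("speckle noise variance scales with intensity squared", {
  x <- cbind(matrix(50, 64, 32), matrix(200, 64, 32))
  ratio <- vapply(1:10, function(s) {
    d <- add_noise(x, "speckle", seed = s) - x
    var(as.vector(d[, 33:64])) / var(as.vector(d[, 1:32]))
  }, 1)
  expect_lt(abs(mean(ratio) - 16) / 16, 0.15)   # (200/50)^2 = 16
})

test_that("camera_mix composes sensor noise stages", {
  x <- make_phantom("shepp_like", c(64, 64))
  expect_identical(camera_mix(x, 0, 0, 0, 0, seed = 1), x)

  # read noise alone reduces to the gaussian family for the same seed
  a <- camera_mix(x, 0, 5, 0, 0, seed = 4)
  b <- add_noise(x, "gaussian", list(sigma = 5), seed = 4)
  expect_equal(a, b)

  # shot noise is signal-dependent: brighter plateau, larger variance
  two <- cbind(matrix(40, 64, 32), matrix(220, 64, 32))
  vr <- vapply(1:10, function(s) {
    d <- camera_mix(two, shot_gain = 2, read_sigma = 0, fpn_sigma = 0,
                    impulse_density = 0, seed = s) - two
    var(as.vector(d[, 33:64])) / var(as.vector(d[, 1:32]))
  }, 1)
  expect_true(all(vr > 2))
})

test_that("benchmark sets are written completely and reproducibly", {
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  m1 <- make_benchmark_set(dir_a, n_images = 6, families = "gaussian",
                           size = c(64, 64), seed = 2)
  expect_equal(nrow(m1), 6L)
  expect_true(all(file.exists(m1$path_clean)))
  expect_true(all(file.exists(m1$path_noisy)))
  expect_true(file.exists(file.path(dir_a, "manifest.csv")))

  m2 <- make_benchmark_set(dir_b, n_images = 6, families = "gaussian",
                           size = c(64, 64), seed = 2)
  expect_identical(m1$image_id, m2$image_id)
  for (i in seq_len(6)) {
    expect_identical(read_image(m1$path_noisy[i]),
                     read_image(m2$path_noisy[i]))
  }

  # a grid over all nine families labels each family
  m9 <- make_benchmark_set(withr::local_tempdir(), n_images = 9,
                           families = noise_families(), size = c(64, 64))
  expect_setequal(m9$family, noise_families())
})
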