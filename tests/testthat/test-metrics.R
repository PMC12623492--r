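test_that("mse/rmse/mae match hand-computed sums", {
  a <- matrix(c(0, 20, 10, 30), 2)   # [[0,10],[20,30]] row-wise
  b <- matrix(c(1, 23, 12, 26), 2)
  expect_equal(iq_mse(a, b), 7.5)
  expect_equal(iq_rmse(a, b), sqrt(7.5))
  expect_equal(iq_mae(a, b), 2.5)
  expect_equal(iq_mse(a, a), 0)
  expect_equal(iq_mae(a, a), 0)
  expect_equal(iq_mse(matrix(0, 3, 3), matrix(255, 3, 3)), 65025)
  off <- a + 5
  expect_equal(iq_mae(a, off), 5)
  expect_equal(iq_rmse(a, off), 5)
  expect_error(iq_mse(a, matrix(0, 3, 3)), "shapes differ")
})

test_that("psnr follows 10*log10(max^2/mse) with an infinity sentinel", {
  a <- matrix(runif(64, 0, 255), 8)
  expect_identical(iq_psnr(a, a), Inf)
  expect_equal(iq_psnr(matrix(0, 2, 2), matrix(255, 2, 2)), 0)
  b <- a + 10   # mse = 100
  expect_equal(iq_psnr(a, b), 10 * log10(65025 / 100), tolerance = 1e-12)
  expect_equal(iq_psnr(a, b), 28.13080, tolerance = 1e-5)
})

test_that("metric identities hold on random pairs", {
  set.seed(51)
  for (i in 1:100) {
    a <- rand_img(8)
    b <- rand_img(8)
    m <- iq_mse(a, b)
    expect_equal(iq_rmse(a, b)^2, m, tolerance = 1e-9)
    expect_equal(iq_psnr(a, b), 10 * log10(255^2 / m), tolerance = 1e-9)
  }
})

test_that("ssim is 1 at identity, symmetric, and matches the constant-image
           closed form", {
  x <- make_phantom("gradient_texture", c(64, 64))
  y <- add_noise(x, "gaussian", list(sigma = 20), seed = 1)
  expect_equal(iq_ssim(x, x), 1)
  expect_equal(iq_ssim(x, y), iq_ssim(y, x), tolerance = 1e-12)
  expect_lt(iq_ssim(x, y), 1)

  # zero-variance windows: only the luminance term survives
  c1 <- (0.01 * 255)^2
  lum <- (2 * 100 * 110 + c1) / (100^2 + 110^2 + c1)
  got <- iq_ssim(matrix(100, 16, 16), matrix(110, 16, 16))
  expect_equal(got, lum, tolerance = 1e-12)
  expect_equal(got, 0.99548, tolerance = 1e-4)

  expect_error(iq_ssim(matrix(1, 4, 4), matrix(1, 4, 4)), "window")
})

test_that("vif is 1 at identity, low for pure noise, monotone in severity", {
  x <- make_phantom("shepp_like", c(128, 128))
  expect_equal(iq_vif(x, x), 1, tolerance = 1e-6)

  set.seed(52)
  noise_only <- vapply(1:10, function(s) {
    set.seed(s)
    iq_vif(x, matrix(runif(128^2, 0, 255), 128))
  }, 1)
  expect_true(all(noise_only < 0.05))

  v <- vapply(c(5, 15, 30), function(sg) {
    iq_vif(x, add_noise(x, "gaussian", list(sigma = sg), seed = 3))
  }, 1)
  expect_true(all(diff(v) < 0))
  expect_true(all(v >= 0 & v <= 1 + 1e-6))
  expect_error(iq_vif(matrix(1, 16, 16), matrix(1, 16, 16)), "32")
})

test_that("fom is 1 for identical edge maps and 0 for edgeless tests", {
  x <- make_phantom("edge_grid", c(64, 64))
  expect_equal(iq_fom(x, x), 1)
  # constant test image: no gradient anywhere -> no detected edges
  expect_equal(iq_fom(x, matrix(100, 64, 64)), 0)
  # constant reference has no edges: FOM undefined
  expect_error(iq_fom(matrix(100, 64, 64), x), "no detected edge")
})

test_that("fom penalises displaced edges smoothly", {
  x <- make_phantom("edge_grid", c(64, 64))
  shifted <- x[, c(3:64, 63, 62)]   # shift edges 2 px horizontally
  f <- iq_fom(x, shifted)
  expect_lt(f, 1)
  expect_gt(f, 0.2)
  y <- add_noise(x, "gaussian", list(sigma = 10), seed = 2)
  expect_true(iq_fom(x, y) >= 0 && iq_fom(x, y) <= 1 + 1e-6)
})

test_that("dispersion_sd is the population standard deviation", {
  expect_equal(dispersion_sd(c(5, 5, 5, 5)), 0)
  expect_equal(dispersion_sd(c(1, 2, 3, 4)), sqrt(1.25))
  expect_equal(dispersion_sd(1:4 + 100), dispersion_sd(1:4))
  expect_error(dispersion_sd(numeric(0)), "non-empty")
})

test_that("evaluate_pair aggregates every metric with the report schema", {
  x <- make_phantom("shepp_like", c(64, 64))
  r <- evaluate_pair(x, x, image_id = "p1", method = "none",
                     elapsed_seconds = 0.5)
  expect_identical(names(r), c("image_id", "method", "psnr_db", "ssim",
                               "mse", "rmse", "vif", "fom", "mae", "time_s"))
  expect_identical(r$psnr_db, Inf)
  expect_equal(r$ssim, 1)
  expect_equal(r$mse, 0)
  expect_equal(r$vif, 1, tolerance = 1e-6)
  expect_equal(r$fom, 1)
  expect_equal(r$time_s, 0.5)

  y <- add_noise(x, "gaussian", seed = 1)
  r2 <- evaluate_pair(x, y)
  expect_equal(r2$rmse^2, r2$mse, tolerance = 1e-9)
})

test_that("metric CSV writes an inf literal for infinite PSNR", {
  x <- make_phantom("shepp_like", c(64, 64))
  rows <- rbind(evaluate_pair(x, x, "a"), evaluate_pair(x, x + 3, "b"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_metric_csv(rows, path)
  txt <- readLines(path)
  expect_match(txt[1], "^image_id,method,psnr_db,ssim,mse,rmse,vif,fom,mae,time_s$")
  expect_match(txt[2], ",inf,", fixed = TRUE)
})
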