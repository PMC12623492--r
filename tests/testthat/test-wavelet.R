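families <- c("haar", "db4", "coif4", "sym4")

test_that("filter banks are orthonormal quadrature-mirror pairs", {
  for (fam in families) {
    w <- wavelet_family(fam)
    expect_equal(sum(w$dec_lo^2), 1, tolerance = 1e-12)
    expect_equal(sum(w$dec_hi^2), 1, tolerance = 1e-12)
    expect_equal(sum(w$dec_lo * w$dec_hi), 0, tolerance = 1e-12)
    expect_equal(sum(w$dec_lo), sqrt(2), tolerance = 1e-10)
  }
})

test_that("constant 2x2 haar block puts all energy in the approximation", {
  tr <- wt_decompose(matrix(1, 2, 2), "haar", 1)
  expect_equal(as.vector(tr$approx), 2, tolerance = 1e-12)
  expect_equal(unname(unlist(tr$details)), rep(0, 3), tolerance = 1e-12)
})

test_that("4x4 haar level-1 subbands equal the hand butterfly", {
  x <- matrix(c(1, 2, 3, 4,
                5, 6, 7, 8,
                9, 10, 11, 12,
                13, 14, 15, 16), 4, byrow = TRUE)
  tr <- wt_decompose(x, "haar", 1)
  # orthonormal haar on a 2x2 cell [a b; c d]:
  #   LL = (a+b+c+d)/2, row-detail, column-detail, diagonal via +/- sums
  cells <- list(x[1:2, 1:2], x[1:2, 3:4], x[3:4, 1:2], x[3:4, 3:4])
  ll <- vapply(cells, function(m) sum(m) / 2, 1)
  expect_equal(as.vector(t(tr$approx)), ll, tolerance = 1e-12)
  hh <- vapply(cells, function(m) (m[1, 1] - m[1, 2] - m[2, 1] + m[2, 2]) / 2, 1)
  expect_equal(as.vector(t(tr$details[[1]]$HH)), hh, tolerance = 1e-12)
})

test_that("decompose/reconstruct round trip is exact for all families", {
  set.seed(41)
  for (fam in families) {
    for (depth in 1:3) {
      x <- rand_img(32)
      expect_lt(max(abs(wt_reconstruct(wt_decompose(x, fam, depth)) - x)),
                1e-8, label = paste(fam, depth))
    }
    # odd, non-square sizes through the edge-padding path
    x <- rand_img(45, 37)
    expect_lt(max(abs(wt_reconstruct(wt_decompose(x, fam, 2)) - x)), 1e-8)
  }
})

test_that("subband shapes follow ceiling halving and depth is validated", {
  tr <- wt_decompose(rand_img(45, 37), "haar", 2)
  expect_equal(dim(tr$details[[1]]$HH), c(23L, 19L))
  expect_equal(dim(tr$details[[2]]$HH), c(12L, 10L))
  expect_error(wt_decompose(rand_img(8), "haar", 5), "infeasible")
})

test_that("a single HH coefficient reconstructs the 2-D wavelet atom", {
  for (fam in c("haar", "db4")) {
    w <- wavelet_family(fam)
    tr <- wt_decompose(matrix(0, 16, 16), fam, 1)
    tr$details[[1]]$HH[3, 4] <- 1
    got <- wt_reconstruct(tr)
    # separable oracle: adjoint upsample-convolve of the unit coefficient
    rows <- naive_idwt1(numeric(8), replace(numeric(8), 3, 1),
                        w$dec_lo, w$dec_hi, 16)
    cols <- naive_idwt1(numeric(8), replace(numeric(8), 4, 1),
                        w$dec_lo, w$dec_hi, 16)
    expect_lt(max(abs(got - outer(rows, cols))), 1e-10)
  }
})

test_that("soft and hard thresholding follow their defining formulas", {
  w <- c(3, -1, 0.5)
  soft <- sign(w) * pmax(abs(w) - 1, 0)
  expect_equal(soft, c(2, 0, 0))
  tr <- wt_decompose(rand_img(16), "haar", 1)
  tr$details[[1]]$HH[1, 1:3] <- w

  ts <- wt_threshold(tr, "soft", threshold = 1)
  expect_equal(ts$details[[1]]$HH[1, 1:3], c(2, 0, 0))
  th <- wt_threshold(tr, "hard", threshold = 1)
  expect_equal(th$details[[1]]$HH[1, 1:3], c(3, -1, 0))
  # approximation plane is never touched
  expect_equal(ts$approx, tr$approx)
  expect_error(wt_threshold(tr, "soft", threshold = -2), ">= 0")
})

test_that("threshold zero is an exact identity in both modes", {
  set.seed(42)
  x <- rand_img(32)
  for (mode in c("soft", "hard")) {
    expect_lt(max(abs(denoise_wavelet(x, "sym4", 2, mode, threshold = 0) - x)),
              1e-8)
  }
})

test_that("soft shrinkage is non-expansive; hard is a masked copy", {
  set.seed(43)
  w <- rnorm(1e5, 0, 20)
  tval <- 15
  soft <- sign(w) * pmax(abs(w) - tval, 0)
  hard <- w * (abs(w) >= tval)
  expect_true(all(abs(soft) <= abs(w)))
  expect_true(all(hard == w | hard == 0))

  tr <- wt_decompose(rand_img(64), "db4", 2)
  ts <- wt_threshold(tr, "soft", threshold = 10)
  th <- wt_threshold(tr, "hard", threshold = 10)
  for (l in 1:2) for (b in c("LH", "HL", "HH")) {
    expect_true(all(abs(ts$details[[l]][[b]]) <= abs(tr$details[[l]][[b]])))
    hb <- th$details[[l]][[b]]
    expect_true(all(hb == tr$details[[l]][[b]] | hb == 0))
  }
})

test_that("raising T never increases the nonzero-coefficient count", {
  set.seed(44)
  tr <- wt_decompose(rand_img(32), "haar", 2)
  nnz <- vapply(c(0, 5, 10, 20, 40), function(tval) {
    tt <- wt_threshold(tr, "hard", threshold = tval)
    sum(vapply(tt$details, function(d) sum(d$LH != 0) + sum(d$HL != 0) +
                 sum(d$HH != 0), 1))
  }, 1)
  expect_true(all(diff(nnz) <= 0))
})

test_that("universal threshold tracks sigma * sqrt(2 log N)", {
  ratios <- vapply(1:20, function(s) {
    set.seed(s)
    img <- matrix(rnorm(4096, 0, 10), 64)
    tr <- wt_decompose(img, "db4", 1)
    attr(wt_threshold(tr, "soft", "universal"), "threshold")[1] /
      (10 * sqrt(2 * log(4096)))
  }, 1)
  expect_lt(abs(mean(ratios) - 1), 0.05)
  expect_true(all(abs(ratios - 1) < 0.12))
})

test_that("thresholding cannot increase image energy (orthogonal bank)", {
  set.seed(45)
  x <- rand_img(64)
  y <- denoise_wavelet(x, "db4", 2, "soft", threshold = 12)
  expect_lte(sum(y^2), sum(x^2) * (1 + 1e-6))
  z <- wt_reconstruct(local({
    tr <- wt_decompose(x, "haar", 2)
    for (l in 1:2) tr$details[[l]] <- lapply(tr$details[[l]], function(m) m * 0)
    tr
  }))
  expect_lte(sum(z^2), sum(x^2) * (1 + 1e-6))
})

test_that("soft shrinkage denoises and differs from hard at equal T", {
  x <- make_phantom("shepp_like", c(64, 64))
  gains <- vapply(1:10, function(s) {
    y <- add_noise(x, "gaussian", list(sigma = 15), seed = s)
    iq_psnr(x, denoise_wavelet(y, "db4", 2, "soft")) - iq_psnr(x, y)
  }, 1)
  expect_true(all(gains > 0))

  y <- add_noise(x, "gaussian", list(sigma = 15), seed = 1)
  s <- denoise_wavelet(y, "db4", 2, "soft", threshold = 30)
  h <- denoise_wavelet(y, "db4", 2, "hard", threshold = 30)
  expect_gt(max(abs(s - h)), 1)
})
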