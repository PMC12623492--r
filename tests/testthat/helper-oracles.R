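# Independent brute-force oracles, written directly from the defining
# formulas. Deliberately slow and loop-based; only ever run on tiny inputs.

refl_idx <- function(i, n) {
  # mirror-without-repeat, 1-based
  i <- i - 1L
  if (n == 1L) return(1L)
  while (i < 0L || i >= n) {
    if (i < 0L) i <- -i
    if (i >= n) i <- 2L * n - 2L - i
  }
  i + 1L
}

naive_conv <- function(x, k) {
  nr <- nrow(x); nc <- ncol(x)
  hr <- (nrow(k) - 1L) / 2L; hc <- (ncol(k) - 1L) / 2L
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    acc <- 0
    for (i in seq_len(nrow(k))) for (j in seq_len(ncol(k))) {
      acc <- acc + k[i, j] *
        x[refl_idx(r + i - 1L - hr, nr), refl_idx(c + j - 1L - hc, nc)]
    }
    out[r, c] <- acc
  }
  out
}

naive_reduce <- function(x, k) {
  onr <- ceiling(nrow(x) / 2); onc <- ceiling(ncol(x) / 2)
  hr <- (nrow(k) - 1L) / 2L; hc <- (ncol(k) - 1L) / 2L
  out <- matrix(0, onr, onc)
  for (r in seq_len(onr)) for (c in seq_len(onc)) {
    acc <- 0
    for (i in seq_len(nrow(k))) for (j in seq_len(ncol(k))) {
      acc <- acc + k[i, j] *
        x[refl_idx(2L * (r - 1L) + i - hr, nrow(x)),
          refl_idx(2L * (c - 1L) + j - hc, ncol(x))]
    }
    out[r, c] <- acc
  }
  out
}

naive_expand <- function(x, target, k) {
  stuffed <- matrix(0, target[1], target[2])
  mask <- stuffed
  stuffed[seq(1, target[1], 2), seq(1, target[2], 2)] <- x
  mask[seq(1, target[1], 2), seq(1, target[2], 2)] <- 1
  naive_conv(stuffed, k) / naive_conv(mask, k)
}

naive_bilateral <- function(x, d, si, ss) {
  h <- (d - 1L) / 2L
  out <- x
  for (r in seq_len(nrow(x))) for (c in seq_len(ncol(x))) {
    num <- 0; den <- 0
    for (i in -h:h) for (j in -h:h) {
      v <- x[refl_idx(r + i, nrow(x)), refl_idx(c + j, ncol(x))]
      w <- exp(-(i^2 + j^2) / (2 * ss^2)) *
        exp(-(v - x[r, c])^2 / (2 * si^2))
      num <- num + w * v
      den <- den + w
    }
    out[r, c] <- num / den
  }
  out
}

naive_median <- function(x, ksize) {
  h <- (ksize - 1L) / 2L
  out <- x
  for (r in seq_len(nrow(x))) for (c in seq_len(ncol(x))) {
    win <- numeric(0)
    for (i in -h:h) for (j in -h:h) {
      win <- c(win, x[refl_idx(r + i, nrow(x)), refl_idx(c + j, ncol(x))])
    }
    out[r, c] <- sort(win)[(ksize * ksize + 1L) / 2L]
  }
  out
}

# adjoint periodized 1-D synthesis, straight from the index formula
naive_idwt1 <- function(a, d, h, g, n) {
  y <- numeric(n)
  for (k in seq_along(a)) for (m in seq_along(h)) {
    i <- (2L * (k - 1L) + (m - 1L)) %% n + 1L
    y[i] <- y[i] + a[k] * h[m] + d[k] * g[m]
  }
  y
}

# literal 2^n enumeration of the Wilcoxon signed-rank null
brute_wilcoxon_p <- function(values_a, values_b) {
  d <- values_a - values_b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  s_pos <- as.vector(signs %*% r)
  min(1, 2 * mean(s_pos <= w_obs))
}

rand_img <- function(nr, nc = nr, lo = 0, hi = 255) {
  matrix(runif(nr * nc, lo, hi), nr, nc)
}
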