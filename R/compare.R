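#' Paired t-test on per-image metric vectors
#'
#' Standard paired t statistic on the differences `d = a - b`:
#' `t = mean(d) / (sd(d) / sqrt(n))` with the sample standard deviation
#' (divisor n - 1) and a two-sided p-value from the t distribution with
#' n - 1 degrees of freedom.
#'
#' @param values_a,values_b equal-length numeric vectors (paired by image).
#' @return list with `t`, `p`, `df`.
#' @examples
#' paired_t(c(2, 4, 6), c(1, 2, 3))  # t = 3.4641, df = 2
#' @export
paired_t <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  n <- length(values_a)
  if (n < 2L) stop("paired t needs at least 2 pairs", call. = FALSE)
  d <- as.numeric(values_a) - as.numeric(values_b)
  s <- sd(d)
  if (s == 0) {
    stop("degenerate variance: all paired differences are identical",
         call. = FALSE)
  }
  tval <- mean(d) / (s / sqrt(n))
  list(t = tval, p = 2 * pt(-abs(tval), df = n - 1L), df = n - 1L)
}

# exact null distribution of the positive-rank sum: counts over all 2^n sign
# assignments, tabulated by generating-function convolution over doubled
# midranks (identical to full enumeration, O(n * max sum))
signed_rank_counts <- function(ranks2) {
  counts <- c(1, numeric(sum(ranks2)))  # counts[s + 1] = #assignments, sum s
  top <- 1L                             # valid prefix length
  for (r in ranks2) {
    new_top <- top + r
    counts[seq_len(new_top)] <- counts[seq_len(new_top)] +
      c(numeric(r), counts[seq_len(top)])
    top <- new_top
  }
  counts
}

#' Exact Wilcoxon signed-rank test
#'
#' Nonparametric paired test. Zero differences are dropped; absolute
#' differences are ranked with midranks for ties; the statistic is
#' `W = min(sum of positive ranks, sum of negative ranks)`. The two-sided
#' p-value is exact: the positive-rank sum is enumerated over all `2^n` sign
#' assignments of the ranks, and `p = min(1, 2 * P(S+ <= W))`. Exact
#' enumeration is used up to `n = 25` effective pairs; beyond that a normal
#' approximation with continuity correction is used.
#'
#' @param values_a,values_b equal-length numeric vectors (paired by image).
#' @return list with `w` (the statistic), `p` (two-sided), `n_effective`
#'   (pairs after dropping zero differences), `n_zero`, and `method`
#'   (`"exact"` or `"normal"`).
#' @examples
#' # every pair favouring the same method, n = 10: W = 0, p = 2 / 2^10
#' wilcoxon_signed_rank_exact(11:20, 1:10)$p  # 0.001953125
#' @export
wilcoxon_signed_rank_exact <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  d <- as.numeric(values_a) - as.numeric(values_b)
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n < 1L) {
    stop("no information: all paired differences are zero", call. = FALSE)
  }
  r <- rank(abs(d))          # midranks for ties
  s_pos <- sum(r[d > 0])
  s_neg <- sum(r[d < 0])
  w <- min(s_pos, s_neg)
  if (n <= 25L) {
    ranks2 <- as.integer(round(2 * r))   # doubled midranks are integers
    counts <- signed_rank_counts(ranks2)
    w2 <- 2 * w
    p_le <- sum(counts[seq_len(floor(w2) + 1L)]) / 2^n
    p <- min(1, 2 * p_le)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                  sum(tabulate(match(r, unique(r)))^3 -
                        tabulate(match(r, unique(r)))) / 48)
    z <- (w - mu + 0.5) / sig
    p <- min(1, 2 * pnorm(z))
    method <- "normal"
  }
  list(w = w, p = p, n_effective = n, n_zero = n_zero, method = method)
}

#' Compare two denoising methods on paired metric reports
#'
#' Aligns two metric-report data frames by `image_id`, extracts one metric
#' column, and runs both the paired t-test and the exact Wilcoxon
#' signed-rank test. The significance verdict is taken from the Wilcoxon
#' p-value at `alpha`.
#'
#' @param reports_a,reports_b data frames of [evaluate_pair()] rows for the
#'   two methods, covering the same `image_id`s.
#' @param metric report column to compare (default `"psnr_db"`).
#' @param alpha significance level for the verdict (default 0.05).
#' @return an object of class `"paired_comparison"`.
#' @export
compare_methods <- function(reports_a, reports_b, metric = "psnr_db",
                            alpha = 0.05) {
  if (!metric %in% names(reports_a) || !metric %in% names(reports_b)) {
    stop(sprintf("metric '%s' not present in both reports", metric),
         call. = FALSE)
  }
  ids_a <- as.character(reports_a$image_id)
  ids_b <- as.character(reports_b$image_id)
  if (!setequal(ids_a, ids_b) || anyDuplicated(ids_a) ||
      anyDuplicated(ids_b)) {
    stop("reports must cover the same image_ids exactly once each",
         call. = FALSE)
  }
  ord <- sort(ids_a)
  va <- reports_a[[metric]][match(ord, ids_a)]
  vb <- reports_b[[metric]][match(ord, ids_b)]
  tt <- paired_t(va, vb)
  wx <- wilcoxon_signed_rank_exact(va, vb)
  structure(list(
    method_a = if (!is.null(reports_a$method)) reports_a$method[1] else "A",
    method_b = if (!is.null(reports_b$method)) reports_b$method[1] else "B",
    metric = metric, values_a = va, values_b = vb, n = length(va),
    t_stat = tt$t, p_t = tt$p, w_stat = wx$w, p_w = wx$p,
    verdict = if (wx$p < alpha) "significant" else "not-significant",
    alpha = alpha), class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s on %s (n = %d pairs)\n", x$method_a, x$method_b,
              x$metric, x$n))
  cat(sprintf("  paired t:  t = %.4f, p = %.6g\n", x$t_stat, x$p_t))
  cat(sprintf("  Wilcoxon:  W = %g, p = %.9g\n", x$w_stat, x$p_w))
  cat(sprintf("  %s at alpha = %g\n", x$verdict, x$alpha))
  invisible(x)
}

#' Write a significance table
#'
#' One row per comparison with columns `pair`, `t`, `p_t`, `W`, `p_w`,
#' `significance`.
#'
#' @param comparisons a `"paired_comparison"` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(comparisons, path) {
  if (inherits(comparisons, "paired_comparison")) {
    comparisons <- list(comparisons)
  }
  rows <- do.call(rbind, lapply(comparisons, function(x) {
    data.frame(pair = paste(x$method_a, "vs", x$method_b),
               t = x$t_stat, p_t = x$p_t, W = x$w_stat, p_w = x$p_w,
               significance = x$verdict, stringsAsFactors = FALSE)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
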