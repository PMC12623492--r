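# internal helpers shared across modules

# coerce to a numeric matrix image plane, with validation
as_plane <- function(x, arg = "image") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("image shapes differ: %dx%d vs %dx%d",
                 nrow(a), ncol(a), nrow(b), ncol(b)), call. = FALSE)
  }
  invisible(TRUE)
}

check_odd_size <- function(size, arg) {
  if (length(size) != 1L || !is.finite(size) || size != as.integer(size) ||
      size < 3L || size %% 2L == 0L) {
    stop(sprintf("`%s` must be an odd integer >= 3", arg), call. = FALSE)
  }
  as.integer(size)
}

check_positive <- function(x, arg) {
  if (length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a positive number", arg), call. = FALSE)
  }
  as.numeric(x)
}

#' Clip and round a working plane to 8-bit integer range
#'
#' Processing keeps images in double precision on the 0--255 scale; this is the
#' single lossy step applied at export time.
#'
#' @param x numeric matrix (or 3-slice array) on the 0--255 scale.
#' @return the same structure with values clipped to \[0, 255\] and rounded.
#' @export
clip_to_uint8 <- function(x) {
  x <- pmin(pmax(x, 0), 255)
  round(x)
}

# apply a plane -> plane function to a matrix or to each slice of an
# nr x nc x 3 array (per-channel colour dispatch)
apply_channels <- function(x, fn) {
  if (is.matrix(x)) return(fn(x))
  if (is.array(x) && length(dim(x)) == 3L) {
    out <- x
    for (ch in seq_len(dim(x)[3L])) out[, , ch] <- fn(x[, , ch])
    return(out)
  }
  stop("expected a matrix or an nr x nc x channels array", call. = FALSE)
}

# valid-mode separable correlation with a 2-D kernel built as outer(wr, wc);
# used by SSIM/VIF where only fully-interior windows count
sep_valid_filter <- function(x, wr, wc = wr) {
  nr <- nrow(x); nc <- ncol(x)
  kr <- length(wr); kc <- length(wc)
  if (nr < kr || nc < kc) {
    stop("image smaller than the filter window", call. = FALSE)
  }
  onr <- nr - kr + 1L
  # band matrix multiply along rows, then columns
  y <- matrix(0, onr, nc)
  for (i in seq_len(kr)) y <- y + wr[i] * x[i:(i + onr - 1L), , drop = FALSE]
  onc <- nc - kc + 1L
  z <- matrix(0, onr, onc)
  for (j in seq_len(kc)) z <- z + wc[j] * y[, j:(j + onc - 1L), drop = FALSE]
  z
}
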