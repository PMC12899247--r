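#' Create a feature map
#'
#' Feature maps are rank-4 numeric arrays laid out as (H, W, C, B): spatial
#' rows, spatial columns, channels, batch. All blocks preserve the batch
#' dimension.
#'
#' @param data numeric array or vector.
#' @param dim integer vector `c(H, W, C, B)`; taken from `data` if omitted.
#' @return a rank-4 array.
#' @export
feature_map <- function(data, dim = NULL) {
  if (is.null(dim)) dim <- base::dim(data)
  if (is.null(dim) || length(dim) != 4L)
    stop("feature map requires dim = c(H, W, C, B)")
  if (any(dim < 1L)) stop("all feature-map dimensions must be >= 1")
  array(as.numeric(data), dim = dim)
}

fm_dims <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4L) stop("not a rank-4 feature map")
  list(h = d[1L], w = d[2L], c = d[3L], b = d[4L])
}

fm_check_channels <- function(x, expected, what = "input") {
  d <- fm_dims(x)
  if (d$c != expected)
    stop(sprintf("%s has %d channels, expected %d", what, d$c, expected))
  invisible(x)
}

# spatial output size for a square kernel
conv_out_size <- function(n, k, stride = 1L, pad = 0L, dilation = 1L) {
  (n + 2L * pad - dilation * (k - 1L) - 1L) %/% stride + 1L
}

# shape-preserving padding at stride 1
same_pad <- function(k, dilation = 1L) dilation * (k - 1L) %/% 2L

concat_channels <- function(xs) {
  d0 <- fm_dims(xs[[1L]])
  for (x in xs[-1L]) {
    d <- fm_dims(x)
    if (d$h != d0$h || d$w != d0$w || d$b != d0$b)
      stop("concat: mismatched spatial or batch dimensions")
  }
  ctot <- sum(vapply(xs, function(x) dim(x)[3L], integer(1L)))
  out <- array(0, dim = c(d0$h, d0$w, ctot, d0$b))
  at <- 0L
  for (x in xs) {
    cc <- dim(x)[3L]
    out[, , at + seq_len(cc), ] <- x
    at <- at + cc
  }
  out
}

split_channels <- function(x, sizes) {
  at <- 0L
  lapply(sizes, function(cc) {
    idx <- at + seq_len(cc)
    at <<- at + cc
    x[, , idx, , drop = FALSE]
  })
}

upsample2_nearest <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , ,
    drop = FALSE]
}

downsample2_sum <- function(dy) {
  # adjoint of nearest x2 upsampling
  d <- dim(dy)
  h <- d[1L] %/% 2L; w <- d[2L] %/% 2L
  oh <- seq(1L, d[1L], by = 2L); ow <- seq(1L, d[2L], by = 2L)
  dy[oh, ow, , , drop = FALSE] + dy[oh + 1L, ow, , , drop = FALSE] +
    dy[oh, ow + 1L, , , drop = FALSE] + dy[oh + 1L, ow + 1L, , , drop = FALSE]
}

#' Per-pixel channel pooling
#'
#' Computes the two global per-pixel statistics used by the spatial-attention
#' and fusion gates: the mean and the maximum over channels.
#'
#' @param x feature map (H, W, C, B).
#' @return feature map (H, W, 2, B); channel 1 is the mean, channel 2 the max.
#' @export
channel_pool <- function(x) {
  d <- fm_dims(x)
  chpool_fwd_cpp(x, dim(x))$y
}
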