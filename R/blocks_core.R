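#' Convolution layer specification
#'
#' A declarative record describing one convolution layer together with its
#' normalization, bias and activation placement. The parameter-count oracle
#' [conv_param_count()] and the builder [make_conv_block()] both consume it,
#' which lets tests assert that built blocks match the closed form exactly.
#'
#' @param in_channels,out_channels channel counts.
#' @param kernel odd kernel size.
#' @param stride,groups,dilation convolution hyper-parameters.
#' @param has_bias,has_bn bias / batch-norm flags.
#' @param activation one of "silu", "relu", "sigmoid", "none".
#' @return an object of class `conv_spec`.
#' @export
conv_spec <- function(in_channels, out_channels, kernel = 3L, stride = 1L,
                      groups = 1L, dilation = 1L, has_bias = FALSE,
                      has_bn = TRUE, activation = "silu") {
  if (in_channels %% groups != 0L || out_channels %% groups != 0L)
    stop("in_channels and out_channels must be divisible by groups")
  if (kernel %% 2L != 1L) stop("kernel must be odd")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 groups = as.integer(groups), dilation = as.integer(dilation),
                 has_bias = isTRUE(has_bias), has_bn = isTRUE(has_bn),
                 activation = match.arg(activation,
                                        c("silu", "relu", "sigmoid", "none"))),
            class = "conv_spec")
}

#' Closed-form parameter count of a convolution layer
#'
#' `(in/groups) * out * k^2`, plus `out` if the layer has a bias and `2 * out`
#' if it has affine batch normalization. Pure arithmetic; no layer is built.
#'
#' @param spec a [conv_spec()].
#' @return integer parameter count.
#' @export
conv_param_count <- function(spec) {
  stopifnot(inherits(spec, "conv_spec"))
  n <- (spec$in_channels %/% spec$groups) * spec$out_channels *
    spec$kernel^2
  if (spec$has_bias) n <- n + spec$out_channels
  if (spec$has_bn) n <- n + 2L * spec$out_channels
  as.integer(n)
}

#' Grouping rule for GCBS blocks
#'
#' A GCBS block (group convolution + batch normalization + SiLU) uses
#' `gcd(in, out)` groups, the maximal grouping that divides both channel
#' counts.
#'
#' @param in_channels,out_channels channel counts.
#' @return integer group count.
#' @export
gcbs_groups <- function(in_channels, out_channels) {
  stopifnot(in_channels >= 1L, out_channels >= 1L)
  a <- as.integer(in_channels); b <- as.integer(out_channels)
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

#' Build a convolution block from a spec
#'
#' @param spec a [conv_spec()].
#' @return a layer whose trainable parameter count equals
#'   `conv_param_count(spec)`.
#' @export
make_conv_block <- function(spec) {
  stopifnot(inherits(spec, "conv_spec"))
  conv_layer(spec$in_channels, spec$out_channels, spec$kernel, spec$stride,
             spec$dilation, spec$groups, bias = spec$has_bias,
             bn = spec$has_bn, act = spec$activation)
}

#' GCBS block: grouped convolution + batch norm + SiLU
#'
#' @param cin,cout channel counts; grouping is `gcd(cin, cout)`.
#' @param k kernel size (default 3).
#' @param stride convolution stride.
#' @return a layer object.
#' @export
gcbs_block <- function(cin, cout, k = 3L, stride = 1L) {
  conv_layer(cin, cout, k, stride, groups = gcbs_groups(cin, cout),
             bias = FALSE, bn = TRUE, act = "silu")
}

# standard bottleneck: two 3x3 convs on `h` channels with additive shortcut
bottleneck_layer <- function(h) {
  m <- new_layer("bottleneck")
  m$sub <- list(conv_layer(h, h, 3L), conv_layer(h, h, 3L))
  m$forward <- function(x, training = FALSE) {
    x + m$sub[[2L]]$forward(m$sub[[1L]]$forward(x, training), training)
  }
  m$backward <- function(dy) {
    dy + m$sub[[1L]]$backward(m$sub[[2L]]$backward(dy))
  }
  m$flops <- function(h_, w_) {
    f1 <- m$sub[[1L]]$flops(h_, w_); f2 <- m$sub[[2L]]$flops(f1$h, f1$w)
    list(macs = f1$macs + f2$macs, h = f2$h, w = f2$w)
  }
  m
}

#' C2f block
#'
#' The stock cross-stage block: a 1x1 split convolution to `2 * hidden`
#' channels, `n` bottlenecks (two 3x3 convolutions with additive shortcut)
#' chained on the second half, concatenation of all `2 + n` streams and a
#' 1x1 merge convolution. All convolutions are bias-free with batch norm and
#' SiLU.
#'
#' @param cin,cout channel counts; `cout` must be even (hidden = `cout / 2`).
#' @param n number of bottlenecks.
#' @param make_unit factory `function(hidden)` for the repeated unit;
#'   defaults to the standard bottleneck. Used by the C2f-MSDDSC variant.
#' @return a layer object.
#' @export
c2f_block <- function(cin, cout, n = 1L, make_unit = bottleneck_layer) {
  if (cout %% 2L != 0L) stop("c2f requires even out_channels")
  h <- cout %/% 2L
  m <- new_layer("c2f")
  m$h <- h; m$n <- n
  units <- lapply(seq_len(n), function(i) make_unit(h))
  m$sub <- c(list(conv_layer(cin, 2L * h, 1L),
                  conv_layer((2L + n) * h, cout, 1L)), units)
  m$forward <- function(x, training = FALSE) {
    y <- m$sub[[1L]]$forward(x, training)
    ys <- split_channels(y, c(h, h))
    for (i in seq_len(n))
      ys[[i + 2L]] <- m$sub[[i + 2L]]$forward(ys[[i + 1L]], training)
    m$cache_nstream <- length(ys)
    m$sub[[2L]]$forward(concat_channels(ys), training)
  }
  m$backward <- function(dy) {
    dcat <- m$sub[[2L]]$backward(dy)
    gs <- split_channels(dcat, rep(h, m$cache_nstream))
    for (i in rev(seq_len(n)))
      gs[[i + 1L]] <- gs[[i + 1L]] + m$sub[[i + 2L]]$backward(gs[[i + 2L]])
    m$sub[[1L]]$backward(concat_channels(gs[1:2]))
  }
  m$flops <- function(h_, w_) {
    macs <- m$sub[[1L]]$flops(h_, w_)$macs
    for (i in seq_len(n)) macs <- macs + m$sub[[i + 2L]]$flops(h_, w_)$macs
    macs <- macs + m$sub[[2L]]$flops(h_, w_)$macs
    list(macs = macs, h = h_, w = w_)
  }
  m
}

#' SPPF block: spatial pyramid pooling (fast)
#'
#' A 1x1 reduction to `cin / 2`, three chained stride-1 max pools of kernel
#' `pool_k`, concatenation of the four streams, and a 1x1 expansion.
#'
#' @param cin,cout channel counts.
#' @param pool_k odd pooling kernel (default 5).
#' @return a layer object.
#' @export
sppf_block <- function(cin, cout, pool_k = 5L) {
  if (pool_k %% 2L != 1L) stop("pool kernel must be odd")
  h <- cin %/% 2L
  m <- new_layer("sppf")
  m$sub <- list(conv_layer(cin, h, 1L), conv_layer(4L * h, cout, 1L),
                maxpool_layer(pool_k), maxpool_layer(pool_k),
                maxpool_layer(pool_k))
  m$forward <- function(x, training = FALSE) {
    y0 <- m$sub[[1L]]$forward(x, training)
    y1 <- m$sub[[3L]]$forward(y0, training)
    y2 <- m$sub[[4L]]$forward(y1, training)
    y3 <- m$sub[[5L]]$forward(y2, training)
    m$sub[[2L]]$forward(concat_channels(list(y0, y1, y2, y3)), training)
  }
  m$backward <- function(dy) {
    g <- split_channels(m$sub[[2L]]$backward(dy), rep(h, 4L))
    g3 <- m$sub[[5L]]$backward(g[[4L]])
    g2 <- m$sub[[4L]]$backward(g[[3L]] + g3)
    g1 <- m$sub[[3L]]$backward(g[[2L]] + g2)
    m$sub[[1L]]$backward(g[[1L]] + g1)
  }
  m$flops <- function(h_, w_) {
    list(macs = m$sub[[1L]]$flops(h_, w_)$macs +
           m$sub[[2L]]$flops(h_, w_)$macs, h = h_, w = w_)
  }
  m
}
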