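# Minimal reverse-mode layer system over (H, W, C, B) arrays.
#
# A layer is an environment with closures:
#   $forward(x, training = FALSE)  caches what backward needs when training
#   $backward(dy)                  returns dx, accumulates $grads
#   $pars / $grads                 named lists of numeric arrays
#   $n_params() / $n_trainable()
#   $flops(h, w)                   list(macs =, h =, w =) analytic shape pass
# Composite blocks wire layers together and follow the same protocol.

new_layer <- function(kind) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$pars <- list()
  e$grads <- list()
  e$buffers <- list()
  e$sub <- list()
  class(e) <- c(paste0("ywl_", kind), "ywl_layer")
  e
}

zero_like <- function(p) {
  if (is.null(dim(p))) numeric(length(p)) else array(0, dim = dim(p))
}

zero_grads <- function(m) {
  m$grads <- lapply(m$pars, zero_like)
  for (s in m$sub) zero_grads(s)
  invisible(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

collect_pars <- function(m, prefix = m$kind) {
  out <- list()
  if (length(m$pars))
    out <- stats::setNames(m$pars, paste0(prefix, ".", names(m$pars)))
  for (i in seq_along(m$sub))
    out <- c(out, collect_pars(m$sub[[i]], paste0(prefix, ".", i)))
  out
}

walk_layers <- function(m, fn) {
  fn(m)
  for (s in m$sub) walk_layers(s, fn)
  invisible(NULL)
}

#' Count parameters of a layer or composite block
#'
#' `layer_param_count()` counts every parameter (including frozen ones);
#' `layer_trainable_count()` counts only gradient-carrying parameters.
#'
#' @param m a layer object.
#' @return numeric count.
#' @export
layer_param_count <- function(m) {
  n <- sum(vapply(m$pars, length, numeric(1L)))
  n + sum(vapply(m$sub, layer_param_count, numeric(1L)))
}

#' @rdname layer_param_count
#' @export
layer_trainable_count <- function(m) {
  n <- if (isTRUE(m$frozen)) 0 else sum(vapply(m$pars, length, numeric(1L)))
  n + sum(vapply(m$sub, layer_trainable_count, numeric(1L)))
}

act_fwd <- function(x, act) {
  switch(act,
    silu = { s <- 1 / (1 + exp(-x)); x * s },
    relu = pmax(x, 0),
    sigmoid = 1 / (1 + exp(-x)),
    none = x,
    stop("unknown activation: ", act))
}

act_bwd <- function(dy, x, act) {
  switch(act,
    silu = { s <- 1 / (1 + exp(-x)); dy * (s * (1 + x * (1 - s))) },
    relu = dy * (x > 0),
    sigmoid = { s <- 1 / (1 + exp(-x)); dy * s * (1 - s) },
    none = dy)
}

# per-channel broadcast over (H, W, C, B); relies on recycling across B
bcast_c <- function(v, d) rep(v, each = d[1L] * d[2L])

channel_sum <- function(x) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1L] * d[2L])
  cs <- colSums(m)                      # length C*B
  rowSums(matrix(cs, nrow = d[3L]))
}

#' Convolution + batch norm + activation layer
#'
#' The universal building block: a square-kernel 2-D convolution with
#' optional bias, optional batch normalization (affine, eps 1e-3) and an
#' activation. Padding is shape-preserving at stride 1
#' (`pad = dilation * (k - 1) / 2`).
#'
#' @param cin,cout input/output channels.
#' @param k odd kernel size.
#' @param stride,dilation,groups usual convolution hyper-parameters;
#'   `cin` and `cout` must both be divisible by `groups`.
#' @param bias include an additive bias term.
#' @param bn apply batch normalization after the convolution.
#' @param act one of "silu", "relu", "sigmoid", "none".
#' @return a layer object.
#' @keywords internal
conv_layer <- function(cin, cout, k, stride = 1L, dilation = 1L, groups = 1L,
                       bias = FALSE, bn = TRUE, act = "silu") {
  if (cin %% groups != 0L || cout %% groups != 0L)
    stop("channels not divisible by groups")
  if (k %% 2L != 1L) stop("kernel size must be odd")
  m <- new_layer("conv")
  m$cin <- cin; m$cout <- cout; m$k <- k; m$stride <- stride
  m$dilation <- dilation; m$groups <- groups
  m$has_bias <- bias; m$has_bn <- bn; m$act <- act
  m$pad <- same_pad(k, dilation)
  cing <- cin %/% groups
  fan_in <- cing * k * k
  m$pars$w <- array(rnorm(k * k * cing * cout, sd = sqrt(2 / fan_in)),
                    dim = c(k, k, cing, cout))
  if (bias) m$pars$b <- numeric(cout)
  if (bn) {
    m$pars$gamma <- rep(1, cout)
    m$pars$beta <- numeric(cout)
    m$buffers$running_mean <- numeric(cout)
    m$buffers$running_var <- rep(1, cout)
    m$bn_eps <- 1e-3
    m$bn_momentum <- 0.03
  }

  # three execution paths: "matmul" for 1x1 stride-1 (pure GEMM),
  # "direct" for grouped or very small convolutions (C++ loops),
  # "gemm" (im2col + BLAS) otherwise
  m$path <- if (k == 1L && stride == 1L && groups == 1L) "matmul"
            else if (groups > 1L || cing * cout * k * k <= 512L) "direct"
            else "gemm"

  conv_raw <- function(x, training) {
    d <- dim(x)
    if (m$path == "matmul") {
      xm <- aperm(x, c(1L, 2L, 4L, 3L))
      dim(xm) <- c(d[1L] * d[2L] * d[4L], cin)
      if (training) m$cache_xm <- xm
      ym <- xm %*% matrix(m$pars$w, nrow = cin)
      dim(ym) <- c(d[1L], d[2L], d[4L], cout)
      aperm(ym, c(1L, 2L, 4L, 3L))
    } else if (m$path == "direct") {
      if (training) m$cache_x <- x
      gconv_fwd_cpp(x, d, m$pars$w, cout, m$k, m$stride, m$pad,
                    m$dilation, m$groups)
    } else {
      cols <- im2col_cpp(x, d, m$k, m$stride, m$pad, m$dilation)
      if (training) { m$cache_cols <- cols; m$cache_dim <- d }
      ho <- conv_out_size(d[1L], m$k, m$stride, m$pad, m$dilation)
      wo <- conv_out_size(d[2L], m$k, m$stride, m$pad, m$dilation)
      ym <- crossprod(cols, matrix(m$pars$w, nrow = m$k * m$k * cing))
      dim(ym) <- c(ho, wo, d[4L], cout)
      aperm(ym, c(1L, 2L, 4L, 3L))
    }
  }

  m$forward <- function(x, training = FALSE) {
    fm_check_channels(x, cin)
    z <- conv_raw(x, training)
    if (m$has_bias) z <- z + bcast_c(m$pars$b, dim(z))
    if (m$has_bn) {
      d <- dim(z)
      n <- d[1L] * d[2L] * d[4L]
      if (training) {
        mu <- channel_sum(z) / n
        zc <- z - bcast_c(mu, d)
        var <- channel_sum(zc * zc) / n
        ivar <- 1 / sqrt(var + m$bn_eps)
        xhat <- zc * bcast_c(ivar, d)
        m$buffers$running_mean <- (1 - m$bn_momentum) *
          m$buffers$running_mean + m$bn_momentum * mu
        m$buffers$running_var <- (1 - m$bn_momentum) *
          m$buffers$running_var + m$bn_momentum * var * n / max(1, n - 1)
        m$cache_bn <- list(xhat = xhat, ivar = ivar, n = n)
        z <- xhat * bcast_c(m$pars$gamma, d) + bcast_c(m$pars$beta, d)
      } else {
        ivar <- 1 / sqrt(m$buffers$running_var + m$bn_eps)
        z <- (z - bcast_c(m$buffers$running_mean, dim(z))) *
          bcast_c(m$pars$gamma * ivar, dim(z)) + bcast_c(m$pars$beta, dim(z))
      }
    }
    if (m$act == "silu") {
      s <- 1 / (1 + exp(-z))
      if (training) { m$cache_z <- z; m$cache_s <- s }
      z * s
    } else {
      if (training) m$cache_z <- z
      act_fwd(z, m$act)
    }
  }

  m$backward <- function(dy) {
    dz <- if (m$act == "silu") {
      s <- m$cache_s
      dy * (s * (1 + m$cache_z * (1 - s)))
    } else act_bwd(dy, m$cache_z, m$act)
    if (m$has_bn) {
      cb <- m$cache_bn
      d <- dim(dz)
      dgamma <- channel_sum(dz * cb$xhat)
      dbeta <- channel_sum(dz)
      m$grads$gamma <- m$grads$gamma + dgamma
      m$grads$beta <- m$grads$beta + dbeta
      gi <- m$pars$gamma * cb$ivar / cb$n
      dz <- bcast_c(gi, d) *
        (cb$n * dz - bcast_c(dbeta, d) - cb$xhat * bcast_c(dgamma, d))
      dz <- array(dz, dim = d)
    }
    if (m$has_bias) m$grads$b <- m$grads$b + channel_sum(dz)
    od <- dim(dz)
    if (m$path == "matmul") {
      dym <- aperm(dz, c(1L, 2L, 4L, 3L))
      dim(dym) <- c(od[1L] * od[2L] * od[4L], cout)
      xm <- m$cache_xm
      m$grads$w <- m$grads$w + array(crossprod(xm, dym), dim = dim(m$pars$w))
      dxm <- tcrossprod(dym, matrix(m$pars$w, nrow = cin))
      dim(dxm) <- c(od[1L], od[2L], od[4L], cin)
      dx <- aperm(dxm, c(1L, 2L, 4L, 3L))
    } else if (m$path == "direct") {
      x <- m$cache_x
      m$grads$w <- m$grads$w +
        gconv_bwd_w_cpp(x, dim(x), dz, cout, m$k, m$stride, m$pad,
                        m$dilation, m$groups)
      dx <- gconv_bwd_x_cpp(dz, dim(x), m$pars$w, cout, m$k, m$stride,
                            m$pad, m$dilation, m$groups)
    } else {
      dym <- aperm(dz, c(1L, 2L, 4L, 3L))
      dim(dym) <- c(od[1L] * od[2L] * od[4L], cout)
      cols <- m$cache_cols
      wn <- matrix(m$pars$w, nrow = m$k * m$k * cing)
      m$grads$w <- m$grads$w + array(cols %*% dym, dim = dim(m$pars$w))
      dcols <- tcrossprod(wn, dym)
      dx <- col2im_cpp(dcols, m$cache_dim, m$k, m$stride, m$pad, m$dilation)
    }
    dx
  }

  m$flops <- function(h, w) {
    ho <- conv_out_size(h, m$k, m$stride, m$pad, m$dilation)
    wo <- conv_out_size(w, m$k, m$stride, m$pad, m$dilation)
    list(macs = as.numeric(ho) * wo * cout * cing * k * k, h = ho, w = wo)
  }
  m
}

# stride-1 max pooling, shape-preserving
maxpool_layer <- function(k) {
  m <- new_layer("maxpool")
  m$k <- k
  m$forward <- function(x, training = FALSE) {
    r <- maxpool_fwd_cpp(x, dim(x), m$k)
    if (training) {
      m$cache_idx <- r$idx
      m$cache_dim <- dim(x)
    }
    r$y
  }
  m$backward <- function(dy) maxpool_bwd_cpp(dy, m$cache_idx, m$cache_dim)
  m$flops <- function(h, w) list(macs = 0, h = h, w = w)
  m
}

upsample_layer <- function() {
  m <- new_layer("upsample")
  m$forward <- function(x, training = FALSE) upsample2_nearest(x)
  m$backward <- function(dy) downsample2_sum(dy)
  m$flops <- function(h, w) list(macs = 0, h = 2L * h, w = 2L * w)
  m
}

chpool_layer <- function() {
  m <- new_layer("chpool")
  m$forward <- function(x, training = FALSE) {
    r <- chpool_fwd_cpp(x, dim(x))
    if (training) {
      m$cache_amax <- r$amax
      m$cache_dim <- dim(x)
    }
    r$y
  }
  m$backward <- function(dy) chpool_bwd_cpp(dy, m$cache_amax, m$cache_dim)
  m$flops <- function(h, w) list(macs = 0, h = h, w = w)
  m
}

# y = x * gate where gate is (H, W, 1, B), broadcast over channels
gate_multiply <- function(x, gate) {
  x * gate[, , rep(1L, dim(x)[3L]), , drop = FALSE]
}

# sum over the channel dimension -> (H, W, 1, B)
sum_channels <- function(x) {
  d <- dim(x)
  if (d[3L] == 1L) return(x)
  m <- array(x, dim = c(d[1L] * d[2L], d[3L], d[4L]))
  out <- array(0, dim = c(d[1L], d[2L], 1L, d[4L]))
  for (b in seq_len(d[4L]))
    out[, , 1L, b] <- rowSums(matrix(m[, , b], ncol = d[3L]))
  out
}
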