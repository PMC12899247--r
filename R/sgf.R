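#' Spatial guidance fusion (SGF) configuration
#'
#' SGF junctions spatially re-weight incoming pyramid features before channel
#' concatenation. Each gated input contributes a sigmoid gate computed from
#' its mean/max channel-pooled descriptor by a small convolution. In the
#' 2-input junction (SGF-2) both inputs are gated; in the 3-input junction
#' (SGF-3) the two lateral inputs are gated and the direct path is scaled by
#' a single learnable scalar, which reproduces the published counts
#' (102 and 103) exactly.
#'
#' @param n_inputs 2 or 3.
#' @param gate_kernel odd gate-convolution kernel (default 5).
#' @param gate_bias bias on the gate convolution (default TRUE).
#' @return an object of class `sgf_config`.
#' @export
sgf_config <- function(n_inputs, gate_kernel = 5L, gate_bias = TRUE) {
  if (!n_inputs %in% c(2L, 3L)) stop("SGF supports 2 or 3 inputs")
  structure(list(n_inputs = as.integer(n_inputs),
                 gate_kernel = as.integer(gate_kernel),
                 gate_bias = isTRUE(gate_bias)),
            class = "sgf_config")
}

#' Closed-form SGF parameter count
#'
#' @param cfg an [sgf_config()].
#' @return numeric count: `n_gates * (2k^2 + bias)` plus one scalar for the
#'   ungated direct path when `n_inputs = 3`.
#' @export
sgf_param_count <- function(cfg) {
  per_gate <- 2 * cfg$gate_kernel^2 + as.integer(cfg$gate_bias)
  if (cfg$n_inputs == 2L) 2 * per_gate else 2 * per_gate + 1
}

#' Build an SGF junction
#'
#' @param cfg an [sgf_config()].
#' @return a layer; its forward takes a *list* of feature maps sharing H, W
#'   and B, and returns their gated channel concatenation. Backward returns a
#'   list of input gradients.
#' @export
sgf_block <- function(cfg) {
  m <- new_layer("sgf")
  m$cfg <- cfg
  n <- cfg$n_inputs
  gated <- if (n == 2L) 1:2 else 2:3     # SGF-3: direct path (input 1) ungated
  subs <- list()
  for (i in gated) {
    subs[[paste0("pool", i)]] <- chpool_layer()
    subs[[paste0("gate", i)]] <- conv_layer(2L, 1L, cfg$gate_kernel,
                                            bias = cfg$gate_bias, bn = FALSE,
                                            act = "sigmoid")
  }
  m$sub <- subs
  if (n == 3L) m$pars$alpha <- 1
  m$gated <- gated
  m$forward <- function(xs, training = FALSE) {
    if (length(xs) != n) stop("SGF-", n, " expects ", n, " inputs")
    d0 <- fm_dims(xs[[1L]])
    for (x in xs[-1L]) {
      d <- fm_dims(x)
      if (d$h != d0$h || d$w != d0$w || d$b != d0$b)
        stop("SGF inputs must share spatial and batch dimensions")
    }
    ys <- xs
    as <- vector("list", n)
    for (i in m$gated) {
      a <- m$sub[[paste0("gate", i)]]$forward(
        m$sub[[paste0("pool", i)]]$forward(xs[[i]], training), training)
      as[[i]] <- a
      ys[[i]] <- gate_multiply(xs[[i]], a)
    }
    if (n == 3L) ys[[1L]] <- m$pars$alpha * xs[[1L]]
    if (training) { m$cache_xs <- xs; m$cache_as <- as }
    concat_channels(ys)
  }
  m$backward <- function(dy) {
    xs <- m$cache_xs
    sizes <- vapply(xs, function(x) dim(x)[3L], integer(1L))
    gs <- split_channels(dy, sizes)
    dxs <- vector("list", n)
    for (i in m$gated) {
      da <- sum_channels(gs[[i]] * xs[[i]])
      dxi <- gate_multiply(gs[[i]], m$cache_as[[i]])
      dxs[[i]] <- dxi + m$sub[[paste0("pool", i)]]$backward(
        m$sub[[paste0("gate", i)]]$backward(da))
    }
    if (n == 3L) {
      m$grads$alpha <- m$grads$alpha + sum(gs[[1L]] * xs[[1L]])
      dxs[[1L]] <- m$pars$alpha * gs[[1L]]
    }
    dxs
  }
  m$flops <- function(h, w) {
    macs <- sum(vapply(m$sub, function(s) s$flops(h, w)$macs, numeric(1L)))
    list(macs = macs, h = h, w = w)
  }
  m
}

#' Fuse feature maps through an SGF junction
#'
#' @param inputs list of 2 or 3 feature maps sharing H, W and B.
#' @param cfg an [sgf_config()]; inferred from `length(inputs)` if missing.
#' @param block optional pre-built [sgf_block()].
#' @return fused feature map with `sum(channels)` channels.
#' @export
sgf_fuse <- function(inputs, cfg = sgf_config(length(inputs)), block = NULL) {
  if (is.null(block)) block <- sgf_block(cfg)
  block$forward(inputs)
}
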