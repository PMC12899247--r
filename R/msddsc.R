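#' Multi-scale dilated depthwise separable convolution (MSDDSC)
#'
#' Configuration for the literal MSDDSC block: a 1x1 channel compression to
#' `floor(e * C)` channels, parallel depthwise separable convolutions with
#' distinct dilation rates, channel concatenation, a 1x1 integration
#' convolution and a residual addition with the block input.
#'
#' @param compression_ratio e in (0, 2]; compressed width is `floor(e * C)`.
#' @param dilation_rates distinct dilation rates, all >= 1.
#' @param kernel odd depthwise kernel size (default 3).
#' @param branch_bn batch norm on each branch's pointwise convolution.
#' @param fuse_bias bias on the pointwise/integration convolutions.
#' @param residual_projection add a 1x1 projection back to `C` channels so the
#'   residual addition is defined when `e != 1`.
#' @return an object of class `msddsc_config`.
#' @export
msddsc_config <- function(compression_ratio = 1, dilation_rates = c(1L, 2L, 3L),
                          kernel = 3L, branch_bn = TRUE, fuse_bias = FALSE,
                          residual_projection = FALSE) {
  r <- as.integer(dilation_rates)
  if (any(r < 1L) || anyDuplicated(r)) stop("dilation rates must be distinct and >= 1")
  if (compression_ratio <= 0) stop("compression ratio must be positive")
  structure(list(compression_ratio = compression_ratio,
                 dilation_rates = r, kernel = as.integer(kernel),
                 branch_bn = isTRUE(branch_bn), fuse_bias = isTRUE(fuse_bias),
                 residual_projection = isTRUE(residual_projection)),
            class = "msddsc_config")
}

msddsc_compressed_width <- function(channels, cfg) {
  cp <- floor(cfg$compression_ratio * channels)
  if (cp < 1L) stop("compressed width floor(e*C) must be >= 1")
  as.integer(cp)
}

#' Channel compression step of MSDDSC
#'
#' Applies a 1x1 convolution + batch norm + SiLU reducing `C` channels to
#' `floor(e * C)`. Weights are drawn from the current RNG unless a built
#' `layer` is supplied.
#'
#' @param x feature map (H, W, C, B).
#' @param cfg an [msddsc_config()].
#' @param layer optional pre-built layer (to reuse weights).
#' @return feature map with `floor(e * C)` channels, same H, W, B.
#' @export
compress <- function(x, cfg = msddsc_config(), layer = NULL) {
  d <- fm_dims(x)
  cp <- msddsc_compressed_width(d$c, cfg)
  if (is.null(layer)) layer <- conv_layer(d$c, cp, 1L)
  layer$forward(x)
}

# one MSDDSC branch: dilated depthwise conv then pointwise conv (+BN+SiLU)
dilated_dw_separable_block <- function(cp, rate, cfg = msddsc_config()) {
  m <- new_layer("ddws")
  m$rate <- as.integer(rate)
  m$sub <- list(
    conv_layer(cp, cp, cfg$kernel, dilation = m$rate, groups = cp,
               bias = FALSE, bn = FALSE, act = "none"),
    conv_layer(cp, cp, 1L, bias = cfg$fuse_bias, bn = cfg$branch_bn,
               act = "silu"))
  m$forward <- function(x, training = FALSE)
    m$sub[[2L]]$forward(m$sub[[1L]]$forward(x, training), training)
  m$backward <- function(dy) m$sub[[1L]]$backward(m$sub[[2L]]$backward(dy))
  m$flops <- function(h, w)
    list(macs = m$sub[[1L]]$flops(h, w)$macs + m$sub[[2L]]$flops(h, w)$macs,
         h = h, w = w)
  m
}

#' Dilated depthwise separable convolution
#'
#' One parallel branch of MSDDSC: a depthwise k x k convolution with the
#' given dilation rate (shape-preserving padding `rate * (k - 1) / 2`)
#' followed by a 1x1 pointwise convolution with batch norm and SiLU.
#'
#' @param x feature map whose channel count is the compressed width.
#' @param rate dilation rate (>= 1).
#' @param cfg an [msddsc_config()].
#' @param block optional pre-built branch block.
#' @return feature map of identical shape.
#' @export
dilated_dw_separable <- function(x, rate, cfg = msddsc_config(), block = NULL) {
  d <- fm_dims(x)
  if (is.null(block)) block <- dilated_dw_separable_block(d$c, rate, cfg)
  block$forward(x)
}

#' Build the literal MSDDSC block
#'
#' Compression, parallel dilated depthwise separable branches, concatenation,
#' 1x1 integration and residual addition. When `e != 1` the residual is only
#' defined with `residual_projection = TRUE`.
#'
#' @param channels input channel count C.
#' @param cfg an [msddsc_config()].
#' @return a layer object; forward preserves the input shape.
#' @export
msddsc_block <- function(channels, cfg = msddsc_config()) {
  cp <- msddsc_compressed_width(channels, cfg)
  if (cp != channels && !cfg$residual_projection)
    stop("residual add requires floor(e*C) == C or residual_projection")
  m <- new_layer("msddsc")
  m$cfg <- cfg
  n <- length(cfg$dilation_rates)
  branches <- lapply(cfg$dilation_rates,
                     function(r) dilated_dw_separable_block(cp, r, cfg))
  m$sub <- c(list(conv_layer(channels, cp, 1L)), branches,
             list(conv_layer(n * cp, cp, 1L, bias = cfg$fuse_bias)))
  if (cfg$residual_projection)
    m$sub <- c(m$sub, list(conv_layer(cp, channels, 1L, act = "none")))
  m$forward <- function(x, training = FALSE) {
    fm_check_channels(x, channels)
    xc <- m$sub[[1L]]$forward(x, training)
    zs <- lapply(seq_len(n) + 1L,
                 function(i) m$sub[[i]]$forward(xc, training))
    y <- m$sub[[n + 2L]]$forward(concat_channels(zs), training)
    if (m$cfg$residual_projection) y <- m$sub[[n + 3L]]$forward(y, training)
    y + x
  }
  m$backward <- function(dy) {
    dyh <- dy
    if (m$cfg$residual_projection) dyh <- m$sub[[length(m$sub)]]$backward(dyh)
    g <- split_channels(m$sub[[n + 2L]]$backward(dyh), rep(cp, n))
    dxc <- Reduce(`+`, lapply(seq_len(n),
                              function(i) m$sub[[i + 1L]]$backward(g[[i]])))
    dy + m$sub[[1L]]$backward(dxc)
  }
  m$flops <- function(h, w) {
    macs <- sum(vapply(m$sub, function(s) s$flops(h, w)$macs, numeric(1L)))
    list(macs = macs, h = h, w = w)
  }
  m
}

#' MSDDSC forward pass
#'
#' @param x feature map.
#' @param cfg an [msddsc_config()].
#' @param block optional pre-built [msddsc_block()] (to control weights).
#' @return feature map of identical shape.
#' @export
msddsc_forward <- function(x, cfg = msddsc_config(), block = NULL) {
  if (is.null(block)) block <- msddsc_block(fm_dims(x)$c, cfg)
  block$forward(x)
}

# ---------------------------------------------------------------------------
# C2f-MSDDSC structural configuration: how the MSDDSC idea is wired into the
# repeated C2f unit. The layer table's printed counts (rows 2/4/6/8) do not
# follow from the equations alone, so the wiring is resolved by a bounded
# deterministic count-matching search over this space.

#' C2f-MSDDSC structural configuration
#'
#' Describes the repeated inner unit of a C2f-MSDDSC block operating on the
#' hidden width h: `keep_bottleneck` retained 3x3 conv(s) with shortcut, then
#' an MSDDSC stage — optional 1x1 pre-compression to `floor(e_pre * h)`,
#' parallel depthwise k x k branches at dilation rates `1..n`, a pointwise
#' convolution to `floor(e_pw * width)` per branch, concatenation, an
#' integration convolution back to h, an optional mean/max spatial gate, and
#' a residual addition.
#'
#' Normalization placements are one of `"none"`, `"bias"`, `"bn"`,
#' `"bias+bn"`.
#'
#' @param e_pre pre-compression ratio (1 = no pre-compression layer).
#' @param n_rates number of dilation branches; rates are `1..n_rates`.
#' @param kernel odd depthwise kernel size.
#' @param e_pw pointwise output ratio relative to the branch input width.
#' @param keep_bottleneck 0, 1 or 2 retained stock 3x3 convolutions.
#' @param dw_norm,pw_norm,int_norm bias/batch-norm placement.
#' @param int_kernel integration kernel size (1 or 3).
#' @param gate_kernel spatial-gate kernel (0 = no gate; 5 or 7).
#' @return an object of class `c2f_msddsc_config`.
#' @export
c2f_msddsc_config <- function(e_pre = 1, n_rates = 3L, kernel = 3L,
                              e_pw = 0.5, keep_bottleneck = 2L,
                              dw_norm = "bias", pw_norm = "bias+bn",
                              int_kernel = 3L, int_norm = "bn",
                              gate_kernel = 7L) {
  norms <- c("none", "bias", "bn", "bias+bn")
  structure(list(e_pre = e_pre, n_rates = as.integer(n_rates),
                 kernel = as.integer(kernel), e_pw = e_pw,
                 keep_bottleneck = as.integer(keep_bottleneck),
                 dw_norm = match.arg(dw_norm, norms),
                 pw_norm = match.arg(pw_norm, norms),
                 int_kernel = as.integer(int_kernel),
                 int_norm = match.arg(int_norm, norms),
                 gate_kernel = as.integer(gate_kernel)),
            class = "c2f_msddsc_config")
}

norm_flags <- function(norm) {
  list(bias = norm %in% c("bias", "bias+bn"), bn = norm %in% c("bn", "bias+bn"))
}

# closed-form parameter count of one inner unit at hidden width h
msddsc_unit_param_count <- function(h, scfg) {
  cp <- max(1L, floor(scfg$e_pre * h))
  pwo <- max(1L, floor(scfg$e_pw * cp))
  n <- scfg$n_rates
  dw <- norm_flags(scfg$dw_norm); pw <- norm_flags(scfg$pw_norm)
  it <- norm_flags(scfg$int_norm)
  p <- scfg$keep_bottleneck * (9 * h * h + 2 * h)
  if (scfg$e_pre != 1) p <- p + h * cp + 2 * cp            # pre-compress (BN)
  p <- p + n * (cp * scfg$kernel^2 + dw$bias * cp + dw$bn * 2 * cp)
  p <- p + n * (cp * pwo + pw$bias * pwo + pw$bn * 2 * pwo)
  p <- p + n * pwo * h * scfg$int_kernel^2 + it$bias * h + it$bn * 2 * h
  if (scfg$gate_kernel > 0L) p <- p + 2 * scfg$gate_kernel^2
  p
}

#' Closed-form parameter count of a C2f-MSDDSC block
#'
#' Stock C2f skeleton (1x1 split and merge convolutions) plus `n` inner units
#' counted by the structural configuration.
#'
#' @param cin,cout channel counts (`cout` even).
#' @param n number of inner units.
#' @param scfg a [c2f_msddsc_config()].
#' @return numeric parameter count.
#' @export
c2f_msddsc_param_count <- function(cin, cout, n = 1L,
                                   scfg = c2f_msddsc_config()) {
  h <- cout %/% 2L
  cv1 <- cin * 2 * h + 2 * (2 * h)
  cv2 <- (2 + n) * h * cout + 2 * cout
  cv1 + cv2 + n * msddsc_unit_param_count(h, scfg)
}

# the repeated C2f-MSDDSC inner unit
msddsc_unit <- function(h, scfg = c2f_msddsc_config()) {
  cp <- max(1L, floor(scfg$e_pre * h))
  pwo <- max(1L, floor(scfg$e_pw * cp))
  n <- scfg$n_rates
  dw <- norm_flags(scfg$dw_norm); pw <- norm_flags(scfg$pw_norm)
  it <- norm_flags(scfg$int_norm)
  m <- new_layer("msddsc_unit")
  m$scfg <- scfg
  subs <- list()
  if (scfg$keep_bottleneck == 2L) subs$bot <- bottleneck_layer(h)
  if (scfg$keep_bottleneck == 1L) subs$bot <- conv_layer(h, h, 3L)
  if (scfg$e_pre != 1) subs$pre <- conv_layer(h, cp, 1L)
  for (r in seq_len(n)) {
    subs[[paste0("dw", r)]] <- conv_layer(cp, cp, scfg$kernel, dilation = r,
                                          groups = cp, bias = dw$bias,
                                          bn = dw$bn, act = "none")
    subs[[paste0("pw", r)]] <- conv_layer(cp, pwo, 1L, bias = pw$bias,
                                          bn = pw$bn, act = "silu")
  }
  subs$int <- conv_layer(n * pwo, h, scfg$int_kernel, bias = it$bias,
                         bn = it$bn, act = "silu")
  if (scfg$gate_kernel > 0L) {
    subs$gpool <- chpool_layer()
    subs$gconv <- conv_layer(2L, 1L, scfg$gate_kernel, bias = FALSE,
                             bn = FALSE, act = "sigmoid")
  }
  m$sub <- subs
  m$forward <- function(x, training = FALSE) {
    u <- if (is.null(m$sub$bot)) x else m$sub$bot$forward(x, training)
    if (scfg$keep_bottleneck == 1L) u <- u + x
    xb <- if (is.null(m$sub$pre)) u else m$sub$pre$forward(u, training)
    zs <- lapply(seq_len(n), function(r) {
      d <- m$sub[[paste0("dw", r)]]$forward(xb, training)
      m$sub[[paste0("pw", r)]]$forward(d, training)
    })
    y <- m$sub$int$forward(concat_channels(zs), training)
    if (!is.null(m$sub$gconv)) {
      a <- m$sub$gconv$forward(m$sub$gpool$forward(y, training), training)
      if (training) { m$cache_y <- y; m$cache_a <- a }
      y <- gate_multiply(y, a)
    }
    y + u
  }
  m$backward <- function(dy) {
    du <- dy
    dyy <- dy
    if (!is.null(m$sub$gconv)) {
      da <- sum_channels(dy * m$cache_y)
      dyy <- gate_multiply(dy, m$cache_a)
      dyy <- dyy + m$sub$gpool$backward(m$sub$gconv$backward(da))
    }
    dcat <- m$sub$int$backward(dyy)
    g <- split_channels(dcat, rep(pwo, n))
    dxb <- Reduce(`+`, lapply(seq_len(n), function(r) {
      m$sub[[paste0("dw", r)]]$backward(
        m$sub[[paste0("pw", r)]]$backward(g[[r]]))
    }))
    du2 <- if (is.null(m$sub$pre)) dxb else m$sub$pre$backward(dxb)
    du <- du + du2
    if (is.null(m$sub$bot)) return(du)
    dx <- m$sub$bot$backward(du)
    if (scfg$keep_bottleneck == 1L) dx <- dx + du
    dx
  }
  m$flops <- function(h_, w_) {
    macs <- sum(vapply(m$sub, function(s) s$flops(h_, w_)$macs, numeric(1L)))
    list(macs = macs, h = h_, w = w_)
  }
  m
}

#' Build a C2f-MSDDSC block
#'
#' The stock C2f skeleton whose repeated inner units follow the resolved
#' MSDDSC structural configuration.
#'
#' @param cin,cout channel counts (`cout` even).
#' @param n number of inner units.
#' @param scfg a [c2f_msddsc_config()]; the default is the configuration
#'   resolved by [search_msddsc_config()] against the shipped manifest.
#' @return a layer object.
#' @export
c2f_msddsc_block <- function(cin, cout, n = 1L, scfg = c2f_msddsc_config()) {
  c2f_block(cin, cout, n, make_unit = function(h) msddsc_unit(h, scfg))
}

#' Deterministic count-matching search for the C2f-MSDDSC configuration
#'
#' Exhaustively enumerates a bounded space of structural configurations and
#' returns the one minimizing the total absolute deviation of
#' [c2f_msddsc_param_count()] from the expected counts. Enumeration order is
#' fixed, so repeated runs return the identical configuration; ties keep the
#' earliest.
#'
#' @param targets a data frame (or list of lists) with columns
#'   `cin`, `cout`, `n`, `expected`.
#' @return list with `config` (the winning [c2f_msddsc_config()]),
#'   `deviation` (per-target built - expected), and `total_abs_deviation`.
#' @export
search_msddsc_config <- function(targets) {
  if (is.data.frame(targets)) {
    tg <- targets
  } else {
    if (length(targets) == 0L) stop("empty target list")
    tg <- do.call(rbind, lapply(targets, function(t)
      data.frame(cin = t[[1L]], cout = t[[2L]], n = t[[3L]],
                 expected = t[[4L]])))
  }
  if (nrow(tg) == 0L) stop("empty target list")
  space <- expand.grid(
    gate_kernel = c(0L, 5L, 7L),
    int_norm = c("bn", "bias+bn"),
    int_kernel = c(1L, 3L),
    pw_norm = c("bias+bn", "bn", "bias"),
    dw_norm = c("bias", "bn", "bias+bn", "none"),
    e_pw = c(0.5, 1, 0.25, 2),
    keep_bottleneck = c(2L, 1L, 0L),
    n_rates = 2:6,
    e_pre = c(1, 0.5, 0.25),
    stringsAsFactors = FALSE)
  best <- NULL; best_dev <- Inf; best_i <- NA_integer_
  for (i in seq_len(nrow(space))) {
    s <- space[i, ]
    scfg <- c2f_msddsc_config(e_pre = s$e_pre, n_rates = s$n_rates,
                              e_pw = s$e_pw,
                              keep_bottleneck = s$keep_bottleneck,
                              dw_norm = s$dw_norm, pw_norm = s$pw_norm,
                              int_kernel = s$int_kernel, int_norm = s$int_norm,
                              gate_kernel = s$gate_kernel)
    built <- mapply(c2f_msddsc_param_count, tg$cin, tg$cout, tg$n,
                    MoreArgs = list(scfg = scfg))
    dev <- sum(abs(built - tg$expected))
    if (dev < best_dev) { best_dev <- dev; best <- scfg; best_i <- i }
    if (dev == 0) break
  }
  built <- mapply(c2f_msddsc_param_count, tg$cin, tg$cout, tg$n,
                  MoreArgs = list(scfg = best))
  list(config = best, deviation = built - tg$expected,
       total_abs_deviation = best_dev)
}
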