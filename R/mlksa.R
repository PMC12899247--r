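#' Multi-scale large-kernel spatial attention (MLKSA)
#'
#' Kernel set for MLKSA; sizes must be odd and strictly increasing. The
#' default {5, 7, 9, 11, 13} covers fine detail through broad context.
#'
#' @param kernels integer vector of odd, strictly increasing kernel sizes.
#' @return an object of class `mlksa_kernels`.
#' @export
mlksa_kernels <- function(kernels = c(5L, 7L, 9L, 11L, 13L)) {
  k <- as.integer(kernels)
  if (length(k) == 0L) stop("kernel list must not be empty")
  if (any(k %% 2L == 0L)) stop("kernels must be odd")
  if (any(diff(k) <= 0L)) stop("kernels must be strictly increasing")
  structure(k, class = "mlksa_kernels")
}

#' Closed-form MLKSA parameter count
#'
#' The count is independent of the input channel width: channel pooling
#' collapses the input to 2 channels before any learned weight. Branch
#' convolutions (2 -> 1, k x k) are bias-free with batch norm; the two fusion
#' convolutions (1x1 5 -> 5 and 3x3 5 -> 1) carry bias and batch norm; the
#' final 1x1 gate convolution carries only a bias.
#'
#' @param channels input channel count (unused by the count; kept as part of
#'   the interface to document the invariance).
#' @param kernels an [mlksa_kernels()].
#' @return numeric parameter count (990 for the default kernel set).
#' @export
mlksa_param_count <- function(channels = NULL, kernels = mlksa_kernels()) {
  nb <- length(kernels)
  branches <- sum(2 * unclass(kernels)^2 + 2)
  fuse1 <- nb * nb + nb + 2 * nb        # 1x1 nb->nb, bias + BN
  fuse2 <- nb * 9 + 1 + 2              # 3x3 nb->1, bias + BN
  final <- 2                            # 1x1 1->1, bias only
  branches + fuse1 + fuse2 + final
}

#' Build an MLKSA block
#'
#' Pipeline: per-pixel mean/max channel pooling (B x 2 x H x W), one
#' convolution per kernel size (2 -> 1, batch norm, ReLU), concatenation,
#' a 1x1 fusion convolution (nb -> nb, ReLU), a 3x3 fusion convolution
#' (nb -> 1, ReLU), a final 1x1 convolution and a sigmoid producing the
#' spatial attention map A in \[0, 1\], which gates the input:
#' `Y = X * A`. Output channels equal input channels.
#'
#' @param channels input channel count.
#' @param kernels an [mlksa_kernels()].
#' @return a layer object.
#' @export
mlksa_block <- function(channels, kernels = mlksa_kernels()) {
  nb <- length(kernels)
  m <- new_layer("mlksa")
  m$channels <- channels
  m$kernels <- kernels
  subs <- list(pool = chpool_layer())
  for (i in seq_len(nb))
    subs[[paste0("k", i)]] <- conv_layer(2L, 1L, kernels[i], bias = FALSE,
                                         bn = TRUE, act = "relu")
  subs$fuse1 <- conv_layer(nb, nb, 1L, bias = TRUE, bn = TRUE, act = "relu")
  subs$fuse2 <- conv_layer(nb, 1L, 3L, bias = TRUE, bn = TRUE, act = "relu")
  subs$final <- conv_layer(1L, 1L, 1L, bias = TRUE, bn = FALSE,
                           act = "sigmoid")
  m$sub <- subs
  m$attention <- function(x, training = FALSE) {
    z <- m$sub$pool$forward(x, training)
    fs <- lapply(seq_len(nb),
                 function(i) m$sub[[paste0("k", i)]]$forward(z, training))
    f1 <- m$sub$fuse1$forward(concat_channels(fs), training)
    f2 <- m$sub$fuse2$forward(f1, training)
    m$sub$final$forward(f2, training)
  }
  m$forward <- function(x, training = FALSE) {
    fm_check_channels(x, channels)
    a <- m$attention(x, training)
    if (training) { m$cache_x <- x; m$cache_a <- a }
    gate_multiply(x, a)
  }
  m$backward <- function(dy) {
    da <- sum_channels(dy * m$cache_x)
    df2 <- m$sub$final$backward(da)
    df1 <- m$sub$fuse2$backward(df2)
    dcat <- m$sub$fuse1$backward(df1)
    g <- split_channels(dcat, rep(1L, nb))
    dz <- Reduce(`+`, lapply(seq_len(nb), function(i)
      m$sub[[paste0("k", i)]]$backward(g[[i]])))
    gate_multiply(dy, m$cache_a) + m$sub$pool$backward(dz)
  }
  m$flops <- function(h, w) {
    macs <- sum(vapply(m$sub, function(s) s$flops(h, w)$macs, numeric(1L)))
    list(macs = macs, h = h, w = w)
  }
  m
}

#' MLKSA forward pass
#'
#' @param x feature map.
#' @param kernels an [mlksa_kernels()].
#' @param block optional pre-built [mlksa_block()].
#' @return gated feature map, same shape as `x`.
#' @export
mlksa_forward <- function(x, kernels = mlksa_kernels(), block = NULL) {
  if (is.null(block)) block <- mlksa_block(fm_dims(x)$c, kernels)
  block$forward(x)
}

#' Export an attention map as a grayscale PNG
#'
#' @param a attention map (H, W, 1, 1) with values in \[0, 1\].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_attention_png <- function(a, path) {
  img <- matrix(pmin(pmax(a[, , 1L, 1L], 0), 1), nrow = dim(a)[1L])
  png::writePNG(img, path)
  invisible(path)
}
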