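# Smoke-level training: a simplified anchor-free detection objective
# (center-cell assignment, BCE on class logits, L1 on the softmax-expectation
# box distances) sufficient to verify that the architecture and the synthetic
# scenes are jointly learnable. Not a reimplementation of a full production
# training pipeline.

assign_level <- function(side_px, strides) {
  which.min(abs(log2(pmax(side_px, 1) / (4 * strides))))
}

#' Simplified anchor-free detection loss
#'
#' Each ground truth is assigned to the cell containing its center at the
#' pyramid level whose stride best matches its size. The loss is binary
#' cross-entropy on all class logits plus an L1 penalty between the
#' softmax-expectation box distances and the true distances (in stride
#' units) at positive cells. Returns the loss and analytic gradients with
#' respect to the raw head outputs.
#'
#' @param outputs list of per-level arrays (H, W, 4*reg_max + nc, B).
#' @param labels list (length B) of normalized label data frames.
#' @param image_size input side in pixels.
#' @param strides per-level strides.
#' @param nc number of classes.
#' @param reg_max distribution bins per side.
#' @return list with `loss`, `loss_cls`, `loss_box` and `grads` (same shapes
#'   as `outputs`).
#' @export
detection_loss <- function(outputs, labels, image_size,
                           strides = c(4L, 8L, 16L), nc = 6L, reg_max = 16L) {
  nb <- dim(outputs[[1L]])[4L]
  nlv <- length(outputs)
  grads <- lapply(outputs, function(o) array(0, dim = dim(o)))
  cls_idx <- 4L * reg_max + seq_len(nc)
  n_cls_el <- sum(vapply(outputs, function(o)
    prod(dim(o)[c(1L, 2L, 4L)]) * nc, numeric(1L)))
  loss_cls <- 0
  # background everywhere first
  for (l in seq_len(nlv)) {
    z <- outputs[[l]][, , cls_idx, , drop = FALSE]
    s <- 1 / (1 + exp(-z))
    # -log(1 - sigma(z)) = max(z, 0) + log1p(exp(-|z|)), numerically stable
    loss_cls <- loss_cls + sum(pmax(z, 0) + log1p(exp(-abs(z))))
    grads[[l]][, , cls_idx, ] <- s / n_cls_el
  }
  loss_box <- 0
  npos <- 0
  bins01 <- 0:(reg_max - 1L)
  for (b in seq_len(nb)) {
    lab <- labels[[b]]
    if (is.null(lab) || nrow(lab) == 0L) next
    for (t in seq_len(nrow(lab))) {
      side_px <- max(lab$w[t], lab$h[t]) * image_size
      l <- assign_level(side_px, strides)
      s <- strides[l]
      hm <- dim(outputs[[l]])[1L]; wm <- dim(outputs[[l]])[2L]
      i <- min(max(floor(lab$cy[t] * image_size / s) + 1L, 1L), hm)
      j <- min(max(floor(lab$cx[t] * image_size / s) + 1L, 1L), wm)
      cl <- lab$class_id[t] + 1L
      # positive class cell: flip BCE target from 0 to 1
      z <- outputs[[l]][i, j, cls_idx[cl], b]
      sg <- 1 / (1 + exp(-z))
      loss_cls <- loss_cls - z        # -log(s) minus the -log(1-s) added above
      grads[[l]][i, j, cls_idx[cl], b] <- (sg - 1) / n_cls_el
      # box distances from the cell center, in stride units
      cx <- (j - 0.5) * s; cy <- (i - 0.5) * s
      x1 <- (lab$cx[t] - lab$w[t] / 2) * image_size
      y1 <- (lab$cy[t] - lab$h[t] / 2) * image_size
      x2 <- (lab$cx[t] + lab$w[t] / 2) * image_size
      y2 <- (lab$cy[t] + lab$h[t] / 2) * image_size
      tgt <- c(cx - x1, cy - y1, x2 - cx, y2 - cy) / s
      tgt <- pmin(pmax(tgt, 0), reg_max - 1 - 1e-3)
      for (side in 1:4) {
        idx <- (side - 1L) * reg_max + seq_len(reg_max)
        zb <- outputs[[l]][i, j, idx, b]
        p <- softmax(zb)
        e <- sum(p * bins01)
        err <- e - tgt[side]
        loss_box <- loss_box + abs(err)
        grads[[l]][i, j, idx, b] <- grads[[l]][i, j, idx, b] +
          sign(err) * p * (bins01 - e)
        npos <- npos + 1L
      }
    }
  }
  loss_cls <- loss_cls / n_cls_el
  if (npos > 0L) {
    loss_box <- loss_box / npos
    for (l in seq_len(nlv)) {
      bidx <- seq_len(4L * reg_max)
      grads[[l]][, , bidx, ] <- grads[[l]][, , bidx, ] / npos
    }
  }
  list(loss = loss_cls + loss_box, loss_cls = loss_cls, loss_box = loss_box,
       grads = grads)
}

# one SGD-with-momentum step over every trainable parameter
sgd_step <- function(model, lr = 0.01, momentum = 0.937,
                     weight_decay = 5e-4) {
  walk_layers(model, function(m) {
    if (isTRUE(m$frozen) || length(m$pars) == 0L) return(invisible(NULL))
    if (is.null(m$vel)) m$vel <- lapply(m$pars, zero_like)
    for (nm in names(m$pars)) {
      g <- m$grads[[nm]]
      if (nm == "w") g <- g + weight_decay * m$pars[[nm]]
      m$vel[[nm]] <- momentum * m$vel[[nm]] + g
      m$pars[[nm]] <- m$pars[[nm]] - lr * m$vel[[nm]]
    }
    invisible(NULL)
  })
  invisible(model)
}

#' Short optimization run on synthetic scenes
#'
#' Runs `steps` SGD-with-momentum iterations of the simplified detection
#' objective on pre-generated scenes, recording the per-step loss and a
#' running-mean smoothed series. Default hyper-parameters follow the
#' standard recipe for this detector family (SGD, lr 0.01, momentum 0.937,
#' weight decay 5e-4).
#'
#' @param model a `ywl_model` (typically a reduced-width variant via
#'   [scale_manifest()]).
#' @param scenes list of `list(image =, annotation =)` as produced by
#'   [generate_scene()].
#' @param steps number of SGD steps.
#' @param batch_size scenes per step (cycled deterministically).
#' @param lr,momentum,weight_decay optimizer hyper-parameters.
#' @param smooth_window running-mean window for the smoothed series.
#' @return list with `losses`, `smoothed`, and the trained `model`.
#' @export
smoke_train <- function(model, scenes, steps = 200L, batch_size = 8L,
                        lr = 0.01, momentum = 0.937, weight_decay = 5e-4,
                        smooth_window = 25L) {
  image_size <- dim(scenes[[1L]]$image)[1L]
  ns <- length(scenes)
  losses <- numeric(steps)
  for (st in seq_len(steps)) {
    idx <- ((st - 1L) * batch_size + seq_len(batch_size) - 1L) %% ns + 1L
    x <- array(0, dim = c(image_size, image_size, 3L, batch_size))
    labs <- vector("list", batch_size)
    for (b in seq_len(batch_size)) {
      x[, , , b] <- scenes[[idx[b]]]$image
      labs[[b]] <- scenes[[idx[b]]]$annotation
    }
    zero_grads(model)
    outs <- model$forward(x, training = TRUE)
    ls <- detection_loss(outs, labs, image_size, model$strides,
                         nc = model$nc, reg_max = model$reg_max)
    if (!is.finite(ls$loss)) stop("training diverged: non-finite loss at step ", st)
    model$backward(ls$grads)
    sgd_step(model, lr, momentum, weight_decay)
    losses[st] <- ls$loss
  }
  if (steps > 0L) {
    k <- min(smooth_window, steps)
    smoothed <- stats::filter(losses, rep(1 / k, k), sides = 1)
    smoothed <- as.numeric(smoothed[!is.na(smoothed)])
  } else smoothed <- numeric(0)
  list(losses = losses, smoothed = smoothed, model = model)
}

#' Save / load model weights
#'
#' Checkpoints are single files holding every parameter array, the batch-norm
#' running statistics and the manifest hash; loading verifies the hash.
#'
#' @param model a `ywl_model`.
#' @param path checkpoint file.
#' @return `path` / the model, invisibly.
#' @export
save_weights <- function(model, path) {
  pars <- list(); bufs <- list()
  i <- 0L
  walk_layers(model, function(m) {
    i <<- i + 1L
    if (length(m$pars)) pars[[as.character(i)]] <<- m$pars
    if (length(m$buffers)) bufs[[as.character(i)]] <<- m$buffers
    invisible(NULL)
  })
  saveRDS(list(pars = pars, buffers = bufs, hash = model$hash), path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(model, path) {
  ck <- readRDS(path)
  if (!identical(ck$hash, model$hash))
    stop("checkpoint manifest hash does not match the model")
  i <- 0L
  walk_layers(model, function(m) {
    i <<- i + 1L
    key <- as.character(i)
    if (!is.null(ck$pars[[key]])) m$pars <- ck$pars[[key]]
    if (!is.null(ck$buffers[[key]])) m$buffers <- ck$buffers[[key]]
    invisible(NULL)
  })
  invisible(model)
}
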