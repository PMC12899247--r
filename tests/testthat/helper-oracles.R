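# Independent reference implementations used as oracles. These deliberately
# share no code with the package: NMS by explicit pairwise comparison, AP by
# exhaustive threshold sweep, IoU recomputed from scratch.

ref_iou <- function(a, b) {
  w <- min(a[3], b[3]) - max(a[1], b[1])
  h <- min(a[4], b[4]) - max(a[2], b[2])
  if (w <= 0 || h <= 0) return(0)
  inter <- w * h
  inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) -
             inter)
}

# O(n^2) greedy NMS reference
ref_nms <- function(dets, thr) {
  keep <- integer(0)
  for (img in unique(dets$image_id)) for (cl in unique(dets$class_id)) {
    idx <- which(dets$image_id == img & dets$class_id == cl)
    if (length(idx) == 0) next
    idx <- idx[order(-dets$score[idx], idx)]
    taken <- list()
    for (i in idx) {
      b <- as.numeric(dets[i, c("x1", "y1", "x2", "y2")])
      ok <- TRUE
      for (t in taken) if (ref_iou(b, t) > thr) { ok <- FALSE; break }
      if (ok) { keep <- c(keep, i); taken[[length(taken) + 1]] <- b }
    }
  }
  dets[sort(keep), , drop = FALSE]
}

# reference AP: greedy match at full ranking, then exhaustive threshold sweep
ref_ap <- function(dets, gts, cl, thr) {
  g <- gts[gts$class_id == cl, , drop = FALSE]
  if (nrow(g) == 0) return(NULL)
  d <- dets[dets$class_id == cl, , drop = FALSE]
  if (nrow(d) == 0) return(0)
  d <- d[order(-d$score, seq_len(nrow(d))), , drop = FALSE]
  used <- rep(FALSE, nrow(g))
  tp <- rep(FALSE, nrow(d))
  for (i in seq_len(nrow(d))) {
    best <- 0; bj <- 0
    for (j in seq_len(nrow(g))) {
      if (used[j] || g$image_id[j] != d$image_id[i]) next
      v <- ref_iou(as.numeric(d[i, c("x1", "y1", "x2", "y2")]),
                   as.numeric(g[j, c("x1", "y1", "x2", "y2")]))
      if (v > best) { best <- v; bj <- j }
    }
    if (bj > 0 && best >= thr) { tp[i] <- TRUE; used[bj] <- TRUE }
  }
  # precision at every rank, monotone envelope by explicit max over suffixes
  n <- nrow(d)
  prec <- cumsum(tp) / seq_len(n)
  rec <- cumsum(tp) / nrow(g)
  ap <- 0
  prev_r <- 0
  for (i in seq_len(n)) {
    p_env <- max(prec[i:n])
    ap <- ap + (rec[i] - prev_r) * p_env
    prev_r <- rec[i]
  }
  ap
}

ref_map50 <- function(dets, gts) {
  cls <- sort(unique(gts$class_id))
  mean(vapply(cls, function(cl) ref_ap(dets, gts, cl, 0.5), numeric(1)))
}

# random detection/ground-truth instances for oracle-agreement tests
random_instance <- function(n_det = 20, n_gt = 8, n_class = 3, size = 100) {
  gts <- data.frame(
    image_id = 1L, class_id = sample.int(n_class, n_gt, TRUE) - 1L,
    x1 = runif(n_gt, 0, size * 0.8), y1 = runif(n_gt, 0, size * 0.8))
  gts$x2 <- gts$x1 + runif(n_gt, 2, size * 0.2)
  gts$y2 <- gts$y1 + runif(n_gt, 2, size * 0.2)
  base <- gts[sample.int(n_gt, n_det, TRUE), , drop = FALSE]
  dets <- data.frame(
    image_id = 1L, class_id = ifelse(runif(n_det) < 0.8, base$class_id,
                                     sample.int(n_class, n_det, TRUE) - 1L),
    score = runif(n_det),
    x1 = base$x1 + rnorm(n_det, 0, 3), y1 = base$y1 + rnorm(n_det, 0, 3))
  dets$x2 <- pmax(dets$x1 + 1, base$x2 + rnorm(n_det, 0, 3))
  dets$y2 <- pmax(dets$y1 + 1, base$y2 + rnorm(n_det, 0, 3))
  rownames(dets) <- NULL
  list(dets = dets, gts = gts)
}

# numeric-vs-analytic gradient check over a layer's parameters
grad_check_layer <- function(make_layer, din, n_probe = 3, eps = 1e-6,
                             listin = FALSE) {
  m <- make_layer()
  x <- if (listin) lapply(din, function(d) array(rnorm(prod(d)), dim = d))
       else array(rnorm(prod(din)), dim = din)
  fwd <- function() m$forward(x, training = TRUE)
  y0 <- fwd()
  w <- if (is.list(y0)) lapply(y0, function(o) array(rnorm(length(o)),
                                                     dim = dim(o)))
       else array(rnorm(length(y0)), dim = dim(y0))
  loss <- function() {
    y <- fwd()
    if (is.list(y)) sum(mapply(function(a, b) sum(a * b), y, w))
    else sum(y * w)
  }
  yolowl:::zero_grads(m)
  fwd()
  m$backward(w)
  worst <- 0
  chk <- function(mm) {
    for (nm in names(mm$pars)) {
      p <- mm$pars[[nm]]
      n <- length(p)
      for (ii in unique(round(seq(1, n, length.out = min(n_probe, n))))) {
        old <- p[ii]
        mm$pars[[nm]][ii] <- old + eps; lp <- loss()
        mm$pars[[nm]][ii] <- old - eps; lm <- loss()
        mm$pars[[nm]][ii] <- old
        num <- (lp - lm) / (2 * eps)
        ana <- mm$grads[[nm]][ii]
        worst <<- max(worst, abs(num - ana) / max(1, abs(num) + abs(ana)))
      }
    }
    for (s in mm$sub) chk(s)
  }
  chk(m)
  worst
}

tiny_manifest <- function(width_mult = 0.25) {
  scale_manifest(parse_manifest(default_manifest_path()), width_mult)
}
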