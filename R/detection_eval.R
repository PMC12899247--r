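#' Intersection over union of two boxes
#'
#' @param a,b boxes as `c(x1, y1, x2, y2)` with `x2 > x1`, `y2 > y1`.
#' @return IoU in \[0, 1\].
#' @export
iou <- function(a, b) {
  ix <- max(0, min(a[3L], b[3L]) - max(a[1L], b[1L]))
  iy <- max(0, min(a[4L], b[4L]) - max(a[2L], b[2L]))
  inter <- ix * iy
  union <- (a[3L] - a[1L]) * (a[4L] - a[2L]) +
    (b[3L] - b[1L]) * (b[4L] - b[2L]) - inter
  if (union <= 0) return(0)
  inter / union
}

# IoU of one box against a matrix of boxes (rows x1,y1,x2,y2)
iou_vec <- function(a, m) {
  ix <- pmax(0, pmin(a[3L], m[, 3L]) - pmax(a[1L], m[, 1L]))
  iy <- pmax(0, pmin(a[4L], m[, 4L]) - pmax(a[2L], m[, 2L]))
  inter <- ix * iy
  union <- (a[3L] - a[1L]) * (a[4L] - a[2L]) +
    (m[, 3L] - m[, 1L]) * (m[, 4L] - m[, 2L]) - inter
  ifelse(union <= 0, 0, inter / union)
}

empty_detections <- function() {
  data.frame(image_id = integer(0), class_id = integer(0),
             score = numeric(0), x1 = numeric(0), y1 = numeric(0),
             x2 = numeric(0), y2 = numeric(0))
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Decode raw head outputs into detections
#'
#' Each head cell predicts, per box side, a discrete distribution over
#' `reg_max` bins whose softmax expectation (in stride units) gives the
#' distance from the cell center to the box edge; class scores come from a
#' sigmoid over the class logits.
#'
#' @param outputs list of per-level arrays (H, W, 4*reg_max + nc, 1).
#' @param strides per-level strides (default c(4, 8, 16)).
#' @param reg_max bins per side (default 16).
#' @param conf_threshold minimum class score to keep a detection.
#' @param image_id id recorded in the output.
#' @return data frame with columns image_id, class_id, score, x1, y1, x2, y2
#'   (pixel units).
#' @export
decode_detections <- function(outputs, strides = c(4L, 8L, 16L),
                              reg_max = 16L, conf_threshold = 0.25,
                              image_id = 1L) {
  if (length(outputs) != length(strides))
    stop("outputs and strides length mismatch")
  res <- list()
  for (l in seq_along(outputs)) {
    o <- outputs[[l]]
    d <- dim(o)
    if (is.null(d) || length(d) != 4L || d[4L] != 1L)
      stop("decode expects single-image rank-4 level outputs")
    nc <- d[3L] - 4L * reg_max
    if (nc < 1L) stop("level output channels inconsistent with reg_max")
    s <- strides[l]
    hm <- d[1L]; wm <- d[2L]
    cls <- 1 / (1 + exp(-o[, , 4L * reg_max + seq_len(nc), 1L, drop = FALSE]))
    cls <- array(cls, dim = c(hm, wm, nc))
    best <- apply(cls, c(1L, 2L), max)
    bestc <- apply(cls, c(1L, 2L), which.max)
    keep <- which(best >= conf_threshold, arr.ind = TRUE)
    if (nrow(keep) == 0L) next
    for (r in seq_len(nrow(keep))) {
      i <- keep[r, 1L]; j <- keep[r, 2L]
      bins <- o[i, j, seq_len(4L * reg_max), 1L]
      dist <- vapply(0:3, function(side) {
        p <- softmax(bins[side * reg_max + seq_len(reg_max)])
        sum(p * (0:(reg_max - 1L)))
      }, numeric(1L))
      cx <- (j - 0.5) * s
      cy <- (i - 0.5) * s
      res[[length(res) + 1L]] <- data.frame(
        image_id = image_id, class_id = bestc[i, j] - 1L,
        score = best[i, j],
        x1 = cx - dist[1L] * s, y1 = cy - dist[2L] * s,
        x2 = cx + dist[3L] * s, y2 = cy + dist[4L] * s)
    }
  }
  if (length(res) == 0L) return(empty_detections())
  do.call(rbind, res)
}

#' Greedy non-maximum suppression
#'
#' Class-wise greedy suppression by descending score; ties broken by row
#' order. Idempotent: `nms(nms(d, t), t)` equals `nms(d, t)`.
#'
#' @param dets detection data frame (see [decode_detections()]).
#' @param iou_threshold suppression threshold (default 0.45).
#' @return subset of `dets`.
#' @export
nms <- function(dets, iou_threshold = 0.45) {
  if (nrow(dets) == 0L) return(dets)
  keep_all <- integer(0)
  for (img in unique(dets$image_id)) {
    for (cl in unique(dets$class_id[dets$image_id == img])) {
      idx <- which(dets$image_id == img & dets$class_id == cl)
      ord <- idx[order(-dets$score[idx], idx)]
      boxes <- as.matrix(dets[ord, c("x1", "y1", "x2", "y2")])
      alive <- rep(TRUE, length(ord))
      for (i in seq_along(ord)) {
        if (!alive[i]) next
        keep_all <- c(keep_all, ord[i])
        if (i < length(ord)) {
          rest <- (i + 1L):length(ord)
          ious <- iou_vec(boxes[i, ], boxes[rest, , drop = FALSE])
          alive[rest][ious > iou_threshold] <- FALSE
        }
      }
    }
  }
  dets[sort(keep_all), , drop = FALSE]
}

# greedy matching of ranked detections to ground truths; returns tp flags
match_detections <- function(dets, gts, iou_threshold) {
  ord <- order(-dets$score, seq_len(nrow(dets)))
  tp <- logical(nrow(dets))
  used <- logical(nrow(gts))
  gtb <- as.matrix(gts[, c("x1", "y1", "x2", "y2")])
  for (i in ord) {
    cand <- which(!used & gts$image_id == dets$image_id[i] &
                    gts$class_id == dets$class_id[i])
    if (length(cand) == 0L) next
    ious <- iou_vec(as.numeric(dets[i, c("x1", "y1", "x2", "y2")]),
                    gtb[cand, , drop = FALSE])
    j <- which.max(ious)
    if (ious[j] >= iou_threshold) {
      tp[i] <- TRUE
      used[cand[j]] <- TRUE
    }
  }
  list(order = ord, tp = tp)
}

#' Precision-recall curve and average precision for one class
#'
#' Detections are ranked by score; each ground truth is matchable at most
#' once (greedy by score, same class and image, IoU >= threshold). AP is the
#' area under the monotone (ceiling-from-the-right) interpolated curve over
#' all points.
#'
#' @param dets detection data frame (any classes; filtered internally).
#' @param gts ground-truth data frame with image_id, class_id, x1..y2.
#' @param class_id class to evaluate.
#' @param iou_threshold matching threshold.
#' @return list with `recall`, `precision` (ordered by rank) and `ap`;
#'   `NULL` when the class has no ground truths.
#' @export
average_precision <- function(dets, gts, class_id, iou_threshold = 0.5) {
  g <- gts[gts$class_id == class_id, , drop = FALSE]
  if (nrow(g) == 0L) return(NULL)
  d <- dets[dets$class_id == class_id, , drop = FALSE]
  if (nrow(d) == 0L)
    return(list(recall = numeric(0), precision = numeric(0), ap = 0))
  mm <- match_detections(d, g, iou_threshold)
  tp <- as.integer(mm$tp[mm$order])
  fp <- 1L - tp
  ctp <- cumsum(tp); cfp <- cumsum(fp)
  recall <- ctp / nrow(g)
  precision <- ctp / (ctp + cfp)
  # monotone envelope from the right, integrate over recall increments
  penv <- rev(cummax(rev(precision)))
  r <- c(0, recall)
  ap <- sum((r[-1L] - r[-length(r)]) * penv)
  list(recall = recall, precision = precision, ap = ap)
}

#' Mean average precision
#'
#' Unweighted mean of per-class AP over the classes present in the ground
#' truth, at IoU 0.5 (`map50`) and averaged over thresholds 0.50 to 0.95 in
#' steps of 0.05 (`map5095`).
#'
#' @param dets,gts detection / ground-truth data frames.
#' @return list with `map50`, `map5095` and per-class AP at 0.5.
#' @export
mean_ap <- function(dets, gts) {
  if (nrow(gts) == 0L) stop("empty ground truth set")
  classes <- sort(unique(gts$class_id))
  thresholds <- seq(0.5, 0.95, by = 0.05)
  ap_tab <- sapply(thresholds, function(t)
    vapply(classes, function(cl)
      average_precision(dets, gts, cl, t)$ap, numeric(1L)))
  ap_tab <- matrix(ap_tab, nrow = length(classes))
  list(map50 = mean(ap_tab[, 1L]),
       map5095 = mean(ap_tab),
       per_class_ap50 = stats::setNames(ap_tab[, 1L],
                                        paste0("class", classes)))
}

#' Convert normalized YOLO labels to pixel-space corner boxes
#'
#' @param labels data frame with class_id, cx, cy, w, h in \[0, 1\].
#' @param image_size square image side in pixels.
#' @param image_id id to record.
#' @return ground-truth data frame in pixel corners.
#' @export
labels_to_boxes <- function(labels, image_size, image_id = 1L) {
  if (nrow(labels) == 0L)
    return(data.frame(image_id = integer(0), class_id = integer(0),
                      x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0)))
  data.frame(image_id = image_id, class_id = labels$class_id,
             x1 = (labels$cx - labels$w / 2) * image_size,
             y1 = (labels$cy - labels$h / 2) * image_size,
             x2 = (labels$cx + labels$w / 2) * image_size,
             y2 = (labels$cy + labels$h / 2) * image_size)
}
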