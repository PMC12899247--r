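test_that("iou matches hand-computed cases", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
})

make_level <- function(hm, wm, nc = 2, reg_max = 16, fill_cls = -20) {
  array(c(rep(0, hm * wm * 4 * reg_max), rep(fill_cls, hm * wm * nc)),
        dim = c(hm, wm, 4 * reg_max + nc, 1))
}

test_that("decode recovers expectation offsets from bin logits", {
  reg_max <- 16
  lv <- make_level(4, 4)
  # uniform bin logits: expected offset (reg_max - 1) / 2 per side
  lv[2, 3, 4 * reg_max + 1, 1] <- 20       # one confident class-0 cell
  d <- decode_detections(list(lv), strides = 8, conf_threshold = 0.5)
  expect_equal(nrow(d), 1)
  s <- 8
  cx <- (3 - 0.5) * s; cy <- (2 - 0.5) * s
  off <- (reg_max - 1) / 2 * s
  expect_equal(as.numeric(d[1, c("x1", "y1", "x2", "y2")]),
               c(cx - off, cy - off, cx + off, cy + off))
  # one-hot bin j gives offset j * stride
  lv2 <- make_level(4, 4)
  lv2[2, 3, 4 * reg_max + 1, 1] <- 20
  for (side in 0:3) lv2[2, 3, side * reg_max + 4, 1] <- 1e4   # bin j = 3
  d2 <- decode_detections(list(lv2), strides = 8, conf_threshold = 0.5)
  expect_equal(d2$x2 - d2$x1, 2 * 3 * 8, tolerance = 1e-8)
})

test_that("decode-encode round trip recovers a synthetic box", {
  reg_max <- 16; s <- 8
  lv <- make_level(6, 6)
  # target: center of cell (3, 4), distances (2, 1, 3, 2) strides per side
  dist <- c(2, 1, 3, 2)
  for (side in 1:4) lv[3, 4, (side - 1) * reg_max + dist[side] + 1, 1] <- 1e4
  lv[3, 4, 4 * reg_max + 2, 1] <- 15
  d <- decode_detections(list(lv), strides = s, conf_threshold = 0.5)
  cx <- 3.5 * s; cy <- 2.5 * s
  expect_equal(as.numeric(d[1, c("x1", "y1", "x2", "y2")]),
               c(cx - 2 * s, cy - 1 * s, cx + 3 * s, cy + 2 * s),
               tolerance = 1e-4)
  expect_equal(d$class_id, 1)
})

test_that("nms keeps the top scorer among duplicates, all disjoint boxes", {
  d <- data.frame(image_id = 1, class_id = 0, score = c(0.9, 0.8),
                  x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  expect_equal(nms(d, 0.45)$score, 0.9)
  d2 <- data.frame(image_id = 1, class_id = 0, score = c(0.5, 0.9, 0.7),
                   x1 = c(0, 20, 40), y1 = 0, x2 = c(10, 30, 50), y2 = 10)
  expect_equal(nrow(nms(d2, 0.45)), 3)
})

test_that("nms matches the brute-force reference and is idempotent", {
  set.seed(1)
  for (i in 1:100) {
    inst <- random_instance(n_det = sample(5:50, 1))
    got <- nms(inst$dets, 0.45)
    ref <- ref_nms(inst$dets, 0.45)
    expect_equal(got, ref)
    expect_equal(nms(got, 0.45), got)
  }
})

test_that("average precision matches hand-enumerated PR tables", {
  gt <- data.frame(image_id = 1, class_id = 0, x1 = 0, y1 = 0, x2 = 10,
                   y2 = 10)
  # ranked [FP, TP] on one ground truth: precision at recall 1 is 1/2
  d <- data.frame(image_id = 1, class_id = 0, score = c(0.9, 0.8),
                  x1 = c(50, 0), y1 = c(50, 0), x2 = c(60, 10),
                  y2 = c(60, 10))
  pr <- average_precision(d, gt, 0, 0.5)
  expect_equal(pr$ap, 0.5)
  # perfect single detection
  dp <- data.frame(image_id = 1, class_id = 0, score = 1, x1 = 0, y1 = 0,
                   x2 = 10, y2 = 10)
  expect_equal(average_precision(dp, gt, 0, 0.5)$ap, 1)
  # no ground truths of the class: undefined
  expect_null(average_precision(dp, gt, 5, 0.5))
})

test_that("appending low-ranked false positives never raises AP", {
  set.seed(2)
  for (i in 1:30) {
    inst <- random_instance()
    cls <- unique(inst$gts$class_id)[1]
    ap0 <- average_precision(inst$dets, inst$gts, cls, 0.5)$ap
    junk <- data.frame(image_id = 1, class_id = cls,
                       score = min(inst$dets$score) / 2,
                       x1 = 90, y1 = 90, x2 = 99, y2 = 99)
    ap1 <- average_precision(rbind(inst$dets, junk), inst$gts, cls, 0.5)$ap
    expect_lte(ap1, ap0 + 1e-12)
  }
})

test_that("evaluator agrees with the independent brute-force oracle", {
  set.seed(3)
  for (i in 1:100) {
    inst <- random_instance(n_det = sample(5:30, 1), n_gt = sample(3:10, 1))
    got <- mean_ap(inst$dets, inst$gts)$map50
    expect_equal(got, ref_map50(inst$dets, inst$gts), tolerance = 1e-12)
  }
})

test_that("mean AP averages over classes present in the ground truth", {
  gts <- data.frame(image_id = 1, class_id = c(0, 1),
                    x1 = c(0, 50), y1 = c(0, 50), x2 = c(10, 60),
                    y2 = c(10, 60))
  # class 0 perfectly detected, class 1 missed entirely
  dets <- data.frame(image_id = 1, class_id = 0, score = 1, x1 = 0, y1 = 0,
                     x2 = 10, y2 = 10)
  r <- mean_ap(dets, gts)
  expect_equal(r$map50, 0.5)
  # single class: mAP equals its AP
  r1 <- mean_ap(dets, gts[1, ])
  expect_equal(r1$map50, 1)
  expect_equal(r1$map5095, 1)
  expect_error(mean_ap(dets, gts[0, ]), "empty ground truth")
})
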