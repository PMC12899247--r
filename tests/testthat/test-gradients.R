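# Analytic backward passes are verified against central finite differences
# on every layer family (with batch-norm in training mode), tiny widths.

test_that("convolution layers on all execution paths have exact gradients", {
  set.seed(11)
  expect_lt(grad_check_layer(function()
    yolowl:::conv_layer(4, 6, 3, bias = TRUE, bn = TRUE), c(6, 6, 4, 2)),
    1e-5)
  expect_lt(grad_check_layer(function()
    yolowl:::conv_layer(4, 8, 1, bias = TRUE, bn = TRUE, act = "relu"),
    c(6, 6, 4, 2)), 1e-5)
  expect_lt(grad_check_layer(function()
    yolowl:::conv_layer(4, 4, 3, groups = 4, dilation = 2, bias = TRUE,
                        bn = FALSE, act = "none"), c(8, 8, 4, 2)), 1e-5)
  expect_lt(grad_check_layer(function()
    yolowl:::conv_layer(4, 8, 3, stride = 2, bias = FALSE, bn = TRUE),
    c(8, 8, 4, 2)), 1e-5)
})

test_that("pooling and attention layers have exact gradients", {
  set.seed(12)
  expect_lt(grad_check_layer(function() yolowl:::maxpool_layer(3),
                             c(6, 6, 4, 2)), 1e-5)
  expect_lt(grad_check_layer(function() yolowl:::chpool_layer(),
                             c(6, 6, 4, 2)), 1e-5)
  expect_lt(grad_check_layer(function() mlksa_block(6), c(16, 16, 6, 2)),
            1e-5)
})

test_that("composite blocks have exact gradients", {
  set.seed(13)
  expect_lt(grad_check_layer(function() c2f_block(6, 8, 2), c(6, 6, 6, 2)),
            1e-5)
  expect_lt(grad_check_layer(function() sppf_block(8, 8, 5), c(8, 8, 8, 2)),
            1e-5)
  expect_lt(grad_check_layer(function()
    yolowl:::msddsc_unit(8, c2f_msddsc_config()), c(8, 8, 8, 2)), 1e-5)
  expect_lt(grad_check_layer(function() msddsc_block(6), c(8, 8, 6, 2)),
            1e-5)
})

test_that("fusion junctions and the head have exact gradients", {
  set.seed(14)
  expect_lt(grad_check_layer(function() sgf_block(sgf_config(3)),
                             list(c(8, 8, 4, 2), c(8, 8, 6, 2),
                                  c(8, 8, 4, 2)), listin = TRUE), 1e-5)
  expect_lt(grad_check_layer(function() detect_head(3, c(8, 16, 32), 4),
                             list(c(8, 8, 8, 2), c(4, 4, 16, 2),
                                  c(2, 2, 32, 2)), listin = TRUE), 1e-5)
})

test_that("detection loss gradients match finite differences", {
  set.seed(15)
  reg_max <- 4; nc <- 3
  outs <- list(array(rnorm(8 * 8 * (4 * reg_max + nc) * 2),
                     dim = c(8, 8, 4 * reg_max + nc, 2)),
               array(rnorm(4 * 4 * (4 * reg_max + nc) * 2),
                     dim = c(4, 4, 4 * reg_max + nc, 2)),
               array(rnorm(2 * 2 * (4 * reg_max + nc) * 2),
                     dim = c(2, 2, 4 * reg_max + nc, 2)))
  labs <- list(data.frame(class_id = c(0L, 2L), cx = c(0.3, 0.7),
                          cy = c(0.4, 0.6), w = c(0.1, 0.3),
                          h = c(0.12, 0.25)),
               data.frame(class_id = 1L, cx = 0.5, cy = 0.5, w = 0.05,
                          h = 0.05))
  ls <- detection_loss(outs, labs, 64, strides = c(8, 16, 32), nc = nc,
                       reg_max = reg_max)
  eps <- 1e-6
  worst <- 0
  set.seed(16)
  for (probe in 1:40) {
    l <- sample(1:3, 1)
    ii <- sample(length(outs[[l]]), 1)
    o2 <- outs
    o2[[l]][ii] <- outs[[l]][ii] + eps
    lp <- detection_loss(o2, labs, 64, c(8, 16, 32), nc, reg_max)$loss
    o2[[l]][ii] <- outs[[l]][ii] - eps
    lm <- detection_loss(o2, labs, 64, c(8, 16, 32), nc, reg_max)$loss
    num <- (lp - lm) / (2 * eps)
    ana <- ls$grads[[l]][ii]
    worst <- max(worst, abs(num - ana) / max(1, abs(num) + abs(ana)))
  }
  expect_lt(worst, 1e-5)
})
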