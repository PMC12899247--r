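test_that("conv_param_count matches closed form and rejects bad groups", {
  expect_equal(conv_param_count(conv_spec(3, 16, 3, 2)), 464)
  expect_equal(conv_param_count(conv_spec(256, 128, 1)), 33024)
  # depthwise 1x1 without norm: one weight per channel
  for (ch in c(3, 16, 64))
    expect_equal(conv_param_count(conv_spec(ch, ch, 1, groups = ch,
                                            has_bn = FALSE)), ch)
  expect_error(conv_spec(6, 16, 3, groups = 4), "divisible")
})

test_that("gcd grouping rule reproduces the published GCBS counts", {
  expect_equal(gcbs_groups(16, 32), 16)
  expect_equal(gcbs_groups(3, 16), 1)
  expect_equal(gcbs_groups(128, 128), 128)
  cases <- list(list(3, 16, 464), list(16, 32, 352), list(32, 64, 704),
                list(64, 128, 1408), list(128, 128, 1408))
  for (cs in cases)
    expect_equal(layer_param_count(yolowl:::gcbs_block(cs[[1]], cs[[2]], 3, 2)),
                 cs[[3]], info = paste(cs[[1]], cs[[2]]))
})

test_that("built conv blocks obey the spatial shape law and count oracle", {
  set.seed(1)
  # stride-2 k=3 halves a 64x64 input
  blk <- make_conv_block(conv_spec(3, 8, 3, 2))
  y <- blk$forward(feature_map(rnorm(64 * 64 * 3 * 2), c(64, 64, 3, 2)))
  expect_equal(dim(y), c(32, 32, 8, 2))
  expect_equal(layer_param_count(make_conv_block(conv_spec(32, 32, 3, 2))),
               9280)
  # dilation-2 k=3 stride-1 preserves shape with padding 2
  blk2 <- make_conv_block(conv_spec(4, 4, 3, dilation = 2))
  expect_equal(blk2$pad, 2L)
  y2 <- blk2$forward(feature_map(rnorm(10 * 10 * 4), c(10, 10, 4, 1)))
  expect_equal(dim(y2), c(10, 10, 4, 1))
  # oracle equivalence over a grid of specs
  set.seed(2)
  for (i in 1:20) {
    g <- sample(c(1, 2, 4), 1)
    cin <- g * sample(1:4, 1); cout <- g * sample(1:4, 1)
    sp <- conv_spec(cin, cout, sample(c(1, 3, 5), 1),
                    stride = sample(1:2, 1), groups = g,
                    dilation = sample(1:3, 1),
                    has_bias = runif(1) < 0.5, has_bn = runif(1) < 0.5)
    expect_equal(layer_param_count(make_conv_block(sp)), conv_param_count(sp))
  }
  # spatial law over strides/dilations
  for (s in 1:2) for (dl in 1:3) {
    sp <- conv_spec(2, 3, 3, stride = s, dilation = dl)
    b <- make_conv_block(sp)
    for (n in c(12, 17)) {
      y <- b$forward(feature_map(rnorm(n * n * 2), c(n, n, 2, 1)))
      expect_equal(dim(y)[1], conv_out_size(n, 3, s, b$pad, dl))
    }
  }
})

test_that("blocks are deterministic given fixed weights", {
  set.seed(3)
  blk <- c2f_block(8, 8, 2)
  x <- feature_map(rnorm(16 * 16 * 8), c(16, 16, 8, 1))
  expect_identical(blk$forward(x), blk$forward(x))
})

test_that("c2f block reproduces the published counts", {
  expect_equal(layer_param_count(c2f_block(256, 128, 1)), 131840)
  expect_equal(layer_param_count(c2f_block(96, 32, 1)), 9408)   # 3136+2*2336+1600
  expect_equal(layer_param_count(c2f_block(320, 128, 1)), 140032)
  expect_equal(layer_param_count(c2f_block(192, 64, 1)), 37248)
  expect_equal(layer_param_count(c2f_block(160, 64, 1)), 35200)
  expect_error(c2f_block(16, 15), "even")
  # decomposition of the (96, 32, 1) case by the conv count oracle
  h <- 16
  expect_equal(conv_param_count(conv_spec(96, 32, 1)) +
                 2 * conv_param_count(conv_spec(16, 16, 3)) +
                 conv_param_count(conv_spec(48, 32, 1)), 9408)
})

test_that("sppf block matches count and pooling invariants", {
  expect_equal(layer_param_count(sppf_block(128, 128, 5)), 41344)
  set.seed(4)
  blk <- sppf_block(8, 8, 5)
  x <- feature_map(rnorm(12 * 12 * 8), c(12, 12, 8, 1))
  expect_equal(dim(blk$forward(x)), c(12, 12, 8, 1))
  # stride-1 max pooling of a constant field returns the constant field
  mp <- yolowl:::maxpool_layer(5)
  cx <- feature_map(rep(2.5, 9 * 9 * 2), c(9, 9, 2, 1))
  expect_equal(mp$forward(cx), cx)
})
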