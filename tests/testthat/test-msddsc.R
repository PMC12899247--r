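test_that("compression width follows floor(e*C) with guard", {
  set.seed(1)
  x <- feature_map(rnorm(6 * 6 * 16), c(6, 6, 16, 1))
  expect_equal(dim(compress(x, msddsc_config(compression_ratio = 1)))[3], 16)
  expect_equal(dim(compress(x, msddsc_config(compression_ratio = 0.5)))[3], 8)
  x3 <- feature_map(rnorm(6 * 6 * 3), c(6, 6, 3, 1))
  expect_error(compress(x3, msddsc_config(compression_ratio = 0.25)),
               ">= 1")
})

test_that("dilated depthwise conv equals a dense zero-inserted kernel", {
  # a rate-2 3x3 depthwise conv is a 5x5 conv with taps at even offsets
  set.seed(2)
  for (rep in 1:5) {
    dw <- yolowl:::conv_layer(1, 1, 3, dilation = 2, groups = 1,
                              bias = FALSE, bn = FALSE, act = "none")
    x <- feature_map(rnorm(8 * 8), c(8, 8, 1, 1))
    y <- dw$forward(x)
    dense <- yolowl:::conv_layer(1, 1, 5, bias = FALSE, bn = FALSE,
                                 act = "none")
    wd <- array(0, dim = c(5, 5, 1, 1))
    wd[c(1, 3, 5), c(1, 3, 5), 1, 1] <- dw$pars$w[, , 1, 1]
    dense$pars$w <- wd
    y2 <- dense$forward(x)
    expect_lt(max(abs(y - y2)) / max(abs(y)), 1e-5)
  }
})

test_that("branch parameter count follows the separable decomposition", {
  # C'=16, BN on the pointwise conv only, no biases: 9*16 + 16*16 + 2*16
  blk <- yolowl:::dilated_dw_separable_block(16, 2, msddsc_config())
  expect_equal(layer_param_count(blk), 432)
  # rate 1 is a plain depthwise separable conv (padding 1)
  blk1 <- yolowl:::dilated_dw_separable_block(4, 1, msddsc_config())
  expect_equal(blk1$sub[[1]]$pad, 1L)
})

test_that("zeroing the integration conv makes msddsc_forward the identity", {
  set.seed(3)
  blk <- msddsc_block(8, msddsc_config())
  ic <- blk$sub[[length(blk$sub)]]
  ic$pars$w[] <- 0
  ic$pars$beta[] <- 0
  x <- feature_map(rnorm(10 * 10 * 8), c(10, 10, 8, 1))
  expect_equal(max(abs(msddsc_forward(x, block = blk) - x)), 0)
})

test_that("branch concatenation carries n * C' channels", {
  cfg <- msddsc_config(dilation_rates = 1:4)
  set.seed(4)
  x <- feature_map(rnorm(6 * 6 * 8), c(6, 6, 8, 1))
  xc <- compress(x, cfg)
  zs <- lapply(cfg$dilation_rates, function(r) dilated_dw_separable(xc, r, cfg))
  expect_equal(dim(yolowl:::concat_channels(zs))[3], 4 * 8)
})

test_that("rate-r branch has effective receptive field 2r+1 (impulse test)", {
  for (r in 1:3) {
    dw <- yolowl:::conv_layer(1, 1, 3, dilation = r, groups = 1,
                              bias = FALSE, bn = FALSE, act = "none")
    dw$pars$w[] <- 1
    n <- 15
    x <- array(0, dim = c(n, n, 1, 1))
    mid <- (n + 1) / 2
    x[mid, mid, 1, 1] <- 1
    y <- dw$forward(x)
    nz <- which(y != 0, arr.ind = TRUE)
    span <- max(nz[, 1]) - min(nz[, 1]) + 1
    expect_equal(span, 2 * r + 1)
  }
})

test_that("C2f-MSDDSC closed-form counts match built blocks and the table", {
  scfg <- c2f_msddsc_config()
  cases <- list(list(32, 32, 1, 11882), list(64, 64, 2, 82916),
                list(128, 128, 2, 325380), list(128, 128, 1, 179330))
  for (cs in cases) {
    expect_equal(c2f_msddsc_param_count(cs[[1]], cs[[2]], cs[[3]], scfg),
                 cs[[4]])
    expect_equal(layer_param_count(c2f_msddsc_block(cs[[1]], cs[[2]],
                                                    cs[[3]], scfg)),
                 cs[[4]])
  }
  # shape contract
  set.seed(5)
  blk <- c2f_msddsc_block(8, 8, 1, scfg)
  x <- feature_map(rnorm(16 * 16 * 8), c(16, 16, 8, 1))
  expect_equal(dim(blk$forward(x)), c(16, 16, 8, 1))
  # stacking n=2 adds exactly one repeated unit plus one merge-conv slice
  d <- c2f_msddsc_param_count(32, 32, 2, scfg) -
    c2f_msddsc_param_count(32, 32, 1, scfg)
  h <- 16
  expect_equal(d, yolowl:::msddsc_unit_param_count(h, scfg) + h * 32)
})

test_that("configuration search recovers a planted configuration", {
  planted <- c2f_msddsc_config(e_pre = 1, n_rates = 4, e_pw = 1,
                               keep_bottleneck = 1, dw_norm = "bn",
                               pw_norm = "bn", int_kernel = 1,
                               int_norm = "bias+bn", gate_kernel = 5)
  targets <- data.frame(cin = c(32, 64, 128, 128), cout = c(32, 64, 128, 128),
                        n = c(1, 2, 2, 1))
  targets$expected <- mapply(c2f_msddsc_param_count, targets$cin,
                             targets$cout, targets$n,
                             MoreArgs = list(scfg = planted))
  sr <- search_msddsc_config(targets)
  expect_equal(sr$total_abs_deviation, 0)
  expect_equal(mapply(c2f_msddsc_param_count, targets$cin, targets$cout,
                      targets$n, MoreArgs = list(scfg = sr$config)),
               targets$expected)
  expect_error(search_msddsc_config(list()), "empty")
  # deterministic: repeated runs return the identical configuration
  sr2 <- search_msddsc_config(targets)
  expect_identical(sr$config, sr2$config)
})

test_that("search against the shipped manifest resolves with zero deviation", {
  man <- parse_manifest(default_manifest_path())
  sr <- search_msddsc_config(msddsc_targets_from_manifest(man))
  expect_equal(sr$total_abs_deviation, 0)
  expect_identical(unclass(sr$config), unclass(c2f_msddsc_config()))
})

test_that("msddsc output is finite and shape-preserving for random configs", {
  set.seed(6)
  for (e in c(0.5, 1)) {
    cfg <- msddsc_config(compression_ratio = e, dilation_rates = 1:2,
                         residual_projection = e != 1)
    x <- feature_map(rnorm(8 * 8 * 6), c(8, 8, 6, 1))
    y <- msddsc_forward(x, cfg)
    expect_equal(dim(y), dim(x))
    expect_true(all(is.finite(y)))
  }
})
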