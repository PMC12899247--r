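test_that("the shipped manifest parses, validates and round-trips", {
  man <- parse_manifest(default_manifest_path())
  expect_s3_class(man, "ywl_manifest")
  expect_length(man$rows, 29)
  expect_equal(man$rows[[29]]$module, "Detect")
  f <- withr::local_tempfile(fileext = ".yaml")
  serialize_manifest(man, f)
  expect_equal(parse_manifest(f), man)
})

test_that("dangling from-references and unknown modules are rejected", {
  man <- parse_manifest(default_manifest_path())
  f <- withr::local_tempfile(fileext = ".yaml")
  bad <- man
  bad$rows[[4]]$from <- 99L
  serialize_manifest(bad, f)
  expect_error(parse_manifest(f), "dangling")
  doc <- yaml::read_yaml(default_manifest_path())
  doc$layers[[2]]$module <- "Wavelet"
  yaml::write_yaml(doc, f)
  expect_error(parse_manifest(f), "unknown module")
})

test_that("printed per-row sum with row 5 reconciled equals the printed total", {
  # static self-consistency of the manifest, independent of any build
  man <- parse_manifest(default_manifest_path())
  per_row <- vapply(man$rows, function(r)
    if (!is.na(r$corrected_params)) r$corrected_params else r$expected_params,
    numeric(1))
  expect_equal(sum(per_row), man$summary$total_params)
  expect_equal(man$summary$total_params - man$summary$trainable_params, 16)
})

test_that("every built row matches its reconciled expected count", {
  model <- build_model()
  audit <- audit_parameters(model)
  expect_true(all(audit$rows$delta == 0))
  expect_equal(audit$totals$built, 1394688)
  expect_equal(audit$totals$trainable, 1394672)
  expect_equal(audit$totals$frozen, 16)
  expect_match(paste(audit$notes, collapse = " "), "row 5")
})

test_that("detect head reproduces the published count decomposition", {
  dh <- detect_head(6, c(32, 64, 128), 16)
  expect_equal(layer_param_count(dh), 346018)
  # per-level decomposition verified by closed form
  lv <- vapply(1:3, function(i)
    layer_param_count(dh$sub[[paste0("box", i)]]) +
      layer_param_count(dh$sub[[paste0("cls", i)]]), numeric(1))
  expect_equal(lv, c(78470, 106118, 161414))
  # frozen expectation projection explains total - trainable = 16
  for (nc in c(1, 6, 20)) {
    d <- detect_head(nc, c(32, 64, 128), 16)
    expect_equal(layer_param_count(d) - layer_trainable_count(d), 16)
  }
  # single-class head shrinks only the class-branch final conv
  d1 <- detect_head(1, c(32, 64, 128), 16)
  expect_equal(layer_param_count(detect_head(6, c(32, 64, 128))) -
                 layer_param_count(d1), 3 * (32 * 5 + 5))
})

test_that("forward pass yields three head outputs at strides 4/8/16", {
  model <- build_model(tiny_manifest(), seed = 1)
  set.seed(1)
  x <- feature_map(rnorm(96 * 96 * 3), c(96, 96, 3, 1))
  outs <- model$forward(x)
  expect_equal(vapply(outs, function(o) dim(o)[1], numeric(1)),
               c(24, 12, 6))
  expect_error(model$forward(feature_map(rnorm(100 * 100 * 3),
                                         c(100, 100, 3, 1))),
               "divisible by 32")
  expect_error(model$forward(feature_map(rnorm(32 * 32 * 4),
                                         c(32, 32, 4, 1))),
               "3 channels")
})

test_that("analytic FLOP counting follows the 2*MACs convention", {
  model <- build_model()
  gf <- count_flops(model, 640)
  per_row <- attr(gf, "per_row")
  # stem conv: 2 * 16 * 320^2 * 3 * 9 FLOPs
  expect_equal(per_row[1], 2 * 16 * 320 * 320 * 3 * 9 / 1e9)
  # doubling the input side quadruples convolution FLOPs
  gf320 <- count_flops(model, 320)
  expect_equal(attr(gf320, "per_row")[1] * 4, per_row[1])
  expect_equal(as.numeric(gf) / as.numeric(gf320), 4, tolerance = 1e-9)
  expect_error(count_flops(model, 100), "divisible")
})

test_that("audit reports are deterministic and JSON round-trips", {
  model <- build_model()
  a1 <- audit_parameters(model)
  a2 <- audit_parameters(model)
  expect_identical(a1$rows, a2$rows)
  f <- withr::local_tempfile(fileext = ".json")
  write_audit_json(a1, f)
  back <- read_audit_json(f)
  expect_equal(back$totals$built, a1$totals$built)
  expect_equal(nrow(back$rows), nrow(a1$rows))
})

test_that("width scaling preserves graph validity", {
  man <- tiny_manifest(0.25)
  model <- build_model(man, seed = 2, reg_max = 4)
  set.seed(2)
  x <- feature_map(rnorm(64 * 64 * 3), c(64, 64, 3, 1))
  outs <- model$forward(x)
  expect_equal(dim(outs[[1]])[3], 4 * 4 + 6)
})
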