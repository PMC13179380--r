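test_that("canonical backbone parameter counts match the reference values", {
  # frozen counts of the published 1000-class architectures
  expect_equal(count_backbone_params("VGG16"), 138357544)
  expect_equal(count_backbone_params("VGG16", "trunk"), 14714688)
  expect_equal(count_backbone_params("EfficientNetB0"), 5288548)
  expect_equal(count_backbone_params("ResNeXt50_32x4d"), 25028904)
  expect_error(count_backbone_params("AlexNet"),
               class = "stressfuse_backbone_error")
})

test_that("adapters output projection_dim features; counting agrees with builds", {
  set.seed(1)
  x <- array(stats::rnorm(2 * 64 * 64 * 3), c(2, 64, 64, 3))
  for (b in backbone_names()) {
    ad <- build_backbone_adapter(
      backbone_adapter_spec(b, 64, 96, depth = "compact"))
    y <- nn_forward(ad, x)
    expect_equal(dim(y), c(2, 96))
    expect_true(all(is.finite(y)))
  }
  # analytic plan counts equal materialized counts (compact VGG16 trunk)
  plan <- stressfuse:::compact_trunk_plan("VGG16")
  built <- stressfuse:::plan_materialize(plan)
  expect_equal(stressfuse:::plan_param_count(plan), nn_count_params(built))
  expect_error(backbone_adapter_spec("VGG16", pretrained = TRUE),
               class = "stressfuse_weights_error")
})

test_that("EEG path concatenates 3 projections and reduces to the embedding", {
  prof <- model_profile("full")
  specs <- lapply(backbone_names(), function(b) {
    backbone_adapter_spec(b, prof$input_size, prof$eeg_proj)
  })
  path <- build_eeg_path(specs, prof$embed)
  expect_equal(path$concat_dim, 1536)
  expect_equal(path$embed_dim, 512)

  specs_t <- lapply(backbone_names(), function(b) {
    backbone_adapter_spec(b, 64, 128, depth = "compact")
  })
  path_t <- build_eeg_path(specs_t, 128)
  expect_equal(path_t$concat_dim, 384)
  x <- array(stats::rnorm(64 * 64 * 3), c(1, 64, 64, 3))
  f1 <- nn_forward(path_t, x)
  f2 <- nn_forward(path_t, x)
  expect_equal(ncol(f1), 128)
  expect_identical(f1, f2) # inference is deterministic
})

test_that("ECG raw path: 768-dim contract, 256 conv filters, length guard", {
  prof <- model_profile("full")
  specs <- lapply(backbone_names(), function(b) {
    backbone_adapter_spec(b, 64, 256, depth = "compact")
  })
  path <- build_ecg_raw_path(specs, prof)
  expect_equal(path$out_dim, 768)
  expect_equal(path$conv_out_channels, 256)
  x <- array(stats::rnorm(7000), c(1, 7000, 1))
  expect_equal(dim(ecg_raw_forward(path, x)), c(1, 768))
  bad <- array(stats::rnorm(6999), c(1, 6999, 1))
  expect_error(ecg_raw_forward(path, bad),
               class = "stressfuse_shape_error")
})

test_that("HRV path has the stated widths and maps 25 -> 256", {
  path <- build_hrv_path()
  expect_equal(path$widths, c(64, 128, 256))
  z <- nn_forward(path, matrix(0, 1, 25))
  expect_equal(ncol(z), 256)
  expect_true(all(is.finite(z)))
})

test_that("intra-ECG fusion concatenates (raw, hrv) and projects to 512", {
  fus <- build_ecg_fusion(768, 256, 512)
  expect_identical(fus$concat_order, c("raw", "hrv"))
  raw <- matrix(stats::rnorm(2 * 768), 2)
  hrv <- matrix(stats::rnorm(2 * 256), 2)
  y <- nn_forward(fus, cbind(raw, hrv), training = TRUE)
  expect_equal(dim(y), c(2, 512))
  # gradient flows to both input blocks
  stressfuse:::nn_zero_grads(fus)
  dcat <- nn_backward(fus, y)
  expect_gt(sum(dcat[, 1:768]^2), 0)
  expect_gt(sum(dcat[, 769:1024]^2), 0)
})

test_that("token self-attention: row-stochastic weights, uniform limit, shapes", {
  set.seed(2)
  att <- self_attention_params(512, 8)
  expect_equal(att$d_k, 64)
  f <- stats::rnorm(512)
  A <- attention_weights(att, f)
  expect_equal(rowSums(A), rep(1, 8), tolerance = 1e-6)
  expect_length(self_attend(f, att), 512)

  # zero Q/K projections and identity V: uniform attention averages tokens
  att0 <- self_attention_params(8, 4)
  att0$params$Wq[] <- 0
  att0$params$Wk[] <- 0
  att0$params$Wv <- diag(2)
  y <- self_attend(1:8, att0)
  tok <- matrix(1:8, 4, 2, byrow = TRUE)
  expect_equal(matrix(y, 4, 2, byrow = TRUE),
               matrix(colMeans(tok), 4, 2, byrow = TRUE))

  expect_error(self_attention_params(100, 8),
               class = "stressfuse_shape_error")
})

test_that("cross-modal gate: symmetry, normalization, closed-form softmax", {
  set.seed(3)
  gate <- cross_modal_gate_params(512)
  f <- stats::rnorm(512)
  g_same <- cross_modal_gate(f, f, gate)
  expect_equal(g_same$alpha_eeg, 0.5)
  expect_equal(g_same$alpha_ecg, 0.5)

  f2 <- stats::rnorm(512)
  g <- cross_modal_gate(f, f2, gate)
  expect_true(g$alpha_eeg > 0 && g$alpha_eeg < 1)
  expect_equal(g$alpha_eeg + g$alpha_ecg, 1)
  gs <- cross_modal_gate(f2, f, gate)
  expect_equal(gs$alpha_eeg, g$alpha_ecg) # swapping inputs swaps alphas

  # logit difference of ln 3 gives alpha = 0.75: route the first embedding
  # coordinate through an identity-like MLP and read it with w_a = e1
  gate2 <- cross_modal_gate_params(512, c(256, 128))
  for (l in stressfuse:::nn_layers(gate2$mlp)) {
    if (l$kind == "dense") {
      l$params$W[] <- 0
      l$params$W[cbind(1:min(dim(l$params$W)), 1:min(dim(l$params$W)))] <- 1
      l$params$b[] <- 0
    }
  }
  gate2$params$w_a[] <- 0
  gate2$params$w_a[1] <- 1
  g3 <- cross_modal_gate(c(log(3), numeric(511)), numeric(512), gate2)
  expect_equal(g3$alpha_eeg, 0.75, tolerance = 1e-12)
})

test_that("fusion is the stated convex combination", {
  a_eeg <- stats::rnorm(512)
  a_ecg <- stats::rnorm(512)
  st1 <- fusion_state(a_eeg, a_ecg, a_eeg, a_ecg, 1, 0)
  expect_identical(fuse(st1), a_eeg)
  st2 <- fusion_state(a_eeg, a_ecg, a_eeg, -a_eeg, 0.5, 0.5)
  expect_equal(fuse(st2), numeric(512))
  for (k in 1:10) {
    al <- stats::runif(1)
    st <- fusion_state(a_eeg, a_ecg, a_eeg, a_ecg, al, 1 - al)
    lhs <- sqrt(sum(fuse(st)^2))
    rhs <- al * sqrt(sum(a_eeg^2)) + (1 - al) * sqrt(sum(a_ecg^2))
    expect_lte(lhs, rhs + 1e-12)
  }
  expect_error(fusion_state(a_eeg, a_ecg, a_eeg, a_ecg, 0.7, 0.7),
               class = "stressfuse_error")
})

test_that("full test-profile model builds, runs fast, and is self-consistent", {
  m <- build_full_model(model_config(profile = "test", variant = "full",
                                     seed = 1))
  N <- 3
  batch <- list(
    scalogram = array(stats::rnorm(N * 64 * 64 * 3), c(N, 64, 64, 3)),
    ecg = array(stats::rnorm(N * 7000), c(N, 7000, 1)),
    hrv = matrix(stats::rnorm(N * 25), N))
  t0 <- Sys.time()
  out <- stressfuse:::model_forward(m, batch)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_lt(elapsed, 5)
  expect_equal(rowSums(out$probs), rep(1, N), tolerance = 1e-6)
  expect_true(all(out$alpha_eeg > 0 & out$alpha_eeg < 1))
  expect_equal(out$alpha_eeg + out$alpha_ecg, rep(1, N))
  # reported alphas match a recomputation from the saved embeddings
  g <- cross_modal_gate(out$f_eeg, out$f_ecg, m$gate)
  expect_equal(g$alpha_eeg, out$alpha_eeg, tolerance = 1e-12)
})

test_that("ablation variants rewire the model as documented", {
  N <- 2
  batch <- list(
    scalogram = array(stats::rnorm(N * 64 * 64 * 3), c(N, 64, 64, 3)),
    ecg = array(stats::rnorm(N * 7000), c(N, 7000, 1)),
    hrv = matrix(stats::rnorm(N * 25), N))
  mna <- build_full_model(model_config(variant = "no_attention", seed = 2))
  outna <- stressfuse:::model_forward(mna, batch)
  expect_equal(outna$alpha_eeg, rep(0.5, N))

  meeg <- build_full_model(model_config(variant = "eeg_only", seed = 2))
  outeeg <- stressfuse:::model_forward(meeg, batch)
  expect_equal(meeg$counters$ecg_reads, 0L) # never touches ECG tensors
  expect_equal(rowSums(outeeg$probs), rep(1, N), tolerance = 1e-6)

  mearly <- build_full_model(model_config(variant = "early_fusion",
                                          seed = 2))
  oute <- stressfuse:::model_forward(mearly, batch)
  expect_equal(rowSums(oute$probs), rep(1, N), tolerance = 1e-6)

  mdrop <- build_full_model(model_config(variant = "drop_backbone",
                                         drop = "VGG16", seed = 2))
  expect_equal(mdrop$eeg_path$concat_dim, 2 * 128)
  outd <- stressfuse:::model_forward(mdrop, batch)
  expect_equal(rowSums(outd$probs), rep(1, N), tolerance = 1e-6)

  expect_error(model_config(variant = "bogus"),
               class = "stressfuse_variant_error")
})

test_that("weights round-trip through model_state/model_restore", {
  m1 <- build_full_model(model_config(seed = 1))
  m2 <- build_full_model(model_config(seed = 2))
  batch <- list(
    scalogram = array(stats::rnorm(64 * 64 * 3), c(1, 64, 64, 3)),
    ecg = array(stats::rnorm(7000), c(1, 7000, 1)),
    hrv = matrix(stats::rnorm(25), 1))
  y1 <- stressfuse:::model_forward(m1, batch)$logits
  st <- model_state(stressfuse:::model_modules(m1))
  model_restore(stressfuse:::model_modules(m2), st)
  y2 <- stressfuse:::model_forward(m2, batch)$logits
  expect_equal(y1, y2, tolerance = 1e-12)
})
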