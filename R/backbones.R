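# Canonical CNN backbones as declarative plans.
#
# Each architecture is described once as a nested list of layer descriptors;
# the same plan drives (a) analytic parameter counting without allocating
# weights and (b) materialization into live engine layers. Counting follows
# the usual convention: conv/dense weights + biases + batch-norm affine
# parameters (gamma, beta) are trainable; running statistics are not.

p_conv2d <- function(in_c, out_c, k, stride = 1, pad = "same", groups = 1,
                     bias = TRUE) {
  list(op = "conv2d", in_c = in_c, out_c = out_c, k = k, stride = stride,
       pad = pad, groups = groups, bias = bias)
}
p_dense <- function(d_in, d_out, bias = TRUE) {
  list(op = "dense", d_in = d_in, d_out = d_out, bias = bias)
}
p_bn <- function(c) list(op = "bn", c = c)
p_relu <- function() list(op = "relu")
p_swish <- function() list(op = "swish")
p_maxpool <- function(k = 2, stride = k, pad = 0) {
  list(op = "maxpool", k = k, stride = stride, pad = pad)
}
p_gap <- function() list(op = "gap")
p_dropout <- function(p) list(op = "dropout", p = p)
p_se <- function(c, se_c) list(op = "se", c = c, se_c = se_c)
p_residual <- function(layers, shortcut = NULL) {
  list(op = "residual", layers = layers, shortcut = shortcut)
}

plan_param_count <- function(plan) {
  total <- 0
  for (l in plan) {
    total <- total + switch(l$op,
      conv2d = {
        kk <- if (length(l$k) == 1) l$k^2 else prod(l$k)
        kk * (l$in_c %/% l$groups) * l$out_c + if (l$bias) l$out_c else 0
      },
      dense = l$d_in * l$d_out + if (l$bias) l$d_out else 0,
      bn = 2 * l$c,
      se = l$c * l$se_c + l$se_c + l$se_c * l$c + l$c,
      residual = plan_param_count(l$layers) +
        plan_param_count(l$shortcut %||% list()),
      0)
  }
  total
}

plan_materialize <- function(plan) {
  layers <- lapply(plan, function(l) {
    switch(l$op,
      conv2d = nn_conv2d(l$in_c, l$out_c, l$k, l$stride, l$pad, l$groups,
                         l$bias),
      dense = nn_dense(l$d_in, l$d_out, l$bias),
      bn = nn_batchnorm(l$c),
      relu = nn_relu(),
      swish = nn_swish(),
      maxpool = nn_maxpool2d(l$k, l$stride, l$pad),
      gap = nn_gap2d(),
      dropout = nn_dropout(l$p),
      se = nn_se_block(l$c, l$se_c),
      residual = nn_residual(
        plan_materialize(l$layers)$layers,
        if (is.null(l$shortcut)) NULL else
          plan_materialize(l$shortcut)$layers),
      sf_stop(sprintf("unknown plan op '%s'", l$op)))
  })
  nn_sequential(layers)
}

## ---- VGG16 ------------------------------------------------------------

# 13 conv layers (3x3, pad 1, with bias), five 2x2 max-pools.
vgg16_trunk_plan <- function() {
  cfg <- list(64, 64, "M", 128, 128, "M", 256, 256, 256, "M",
              512, 512, 512, "M", 512, 512, 512, "M")
  plan <- list()
  in_c <- 3
  for (v in cfg) {
    if (identical(v, "M")) {
      plan <- c(plan, list(p_maxpool(2)))
    } else {
      plan <- c(plan, list(p_conv2d(in_c, v, 3, 1, 1), p_relu()))
      in_c <- v
    }
  }
  plan
}

# Canonical 1000-class classifier head (7x7x512 feature map flattened).
vgg16_classifier_plan <- function() {
  c(vgg16_trunk_plan(), list(
    p_dense(512 * 7 * 7, 4096), p_relu(), p_dropout(0.5),
    p_dense(4096, 4096), p_relu(), p_dropout(0.5),
    p_dense(4096, 1000)))
}

## ---- EfficientNetB0 ---------------------------------------------------

mbconv_plan <- function(in_c, out_c, expand, k, stride) {
  exp_c <- in_c * expand
  se_c <- max(1L, in_c %/% 4L)
  body <- list()
  if (expand != 1) {
    body <- c(body, list(p_conv2d(in_c, exp_c, 1, 1, 0, bias = FALSE),
                         p_bn(exp_c), p_swish()))
  }
  body <- c(body, list(
    p_conv2d(exp_c, exp_c, k, stride, (k - 1) %/% 2, groups = exp_c,
             bias = FALSE),
    p_bn(exp_c), p_swish(),
    p_se(exp_c, se_c),
    p_conv2d(exp_c, out_c, 1, 1, 0, bias = FALSE), p_bn(out_c)))
  if (stride == 1 && in_c == out_c) list(p_residual(body)) else body
}

efficientnet_b0_trunk_plan <- function() {
  plan <- list(p_conv2d(3, 32, 3, 2, 1, bias = FALSE), p_bn(32), p_swish())
  blocks <- list( # expand, out, repeats, stride, kernel
    c(1, 16, 1, 1, 3), c(6, 24, 2, 2, 3), c(6, 40, 2, 2, 5),
    c(6, 80, 3, 2, 3), c(6, 112, 3, 1, 5), c(6, 192, 4, 2, 5),
    c(6, 320, 1, 1, 3))
  in_c <- 32
  for (b in blocks) {
    for (r in seq_len(b[3])) {
      s <- if (r == 1) b[4] else 1
      plan <- c(plan, mbconv_plan(in_c, b[2], b[1], b[5], s))
      in_c <- b[2]
    }
  }
  c(plan, list(p_conv2d(320, 1280, 1, 1, 0, bias = FALSE), p_bn(1280),
               p_swish()))
}

efficientnet_b0_classifier_plan <- function() {
  c(efficientnet_b0_trunk_plan(),
    list(p_gap(), p_dropout(0.2), p_dense(1280, 1000)))
}

## ---- ResNeXt50-32x4d --------------------------------------------------

resnext_block_plan <- function(in_c, width, out_c, stride, groups = 32) {
  body <- list(
    p_conv2d(in_c, width, 1, 1, 0, bias = FALSE), p_bn(width), p_relu(),
    p_conv2d(width, width, 3, stride, 1, groups = groups, bias = FALSE),
    p_bn(width), p_relu(),
    p_conv2d(width, out_c, 1, 1, 0, bias = FALSE), p_bn(out_c))
  shortcut <- if (stride != 1 || in_c != out_c) {
    list(p_conv2d(in_c, out_c, 1, stride, 0, bias = FALSE), p_bn(out_c))
  } else NULL
  # trailing ReLU after the residual sum is handled by the caller
  list(p_residual(body, shortcut), p_relu())
}

resnext50_trunk_plan <- function() {
  plan <- list(p_conv2d(3, 64, 7, 2, 3, bias = FALSE), p_bn(64), p_relu(),
               p_maxpool(3, 2, 1))
  stages <- list( # width, out, blocks, first stride
    c(128, 256, 3, 1), c(256, 512, 4, 2),
    c(512, 1024, 6, 2), c(1024, 2048, 3, 2))
  in_c <- 64
  for (st in stages) {
    for (b in seq_len(st[3])) {
      s <- if (b == 1) st[4] else 1
      plan <- c(plan, resnext_block_plan(in_c, st[1], st[2], s))
      in_c <- st[2]
    }
  }
  plan
}

resnext50_classifier_plan <- function() {
  c(resnext50_trunk_plan(), list(p_gap(), p_dense(2048, 1000)))
}

## ---- compact trunks (test profile) ------------------------------------

# Reduced-depth stand-ins used by the CPU-scale test profile. Each keeps the
# flavor of its namesake (plain stacked 3x3 convs; depthwise-separable with
# SE; grouped-convolution residual) behind the identical adapter surface.
compact_trunk_plan <- function(backbone) {
  switch(backbone,
    VGG16 = list(
      p_conv2d(3, 8, 3, 1, 1), p_relu(), p_maxpool(2),
      p_conv2d(8, 16, 3, 1, 1), p_relu(), p_maxpool(2),
      p_conv2d(16, 32, 3, 1, 1), p_relu(), p_maxpool(2)),
    EfficientNetB0 = list(
      p_conv2d(3, 8, 3, 2, 1, bias = FALSE), p_bn(8), p_swish(),
      p_conv2d(8, 8, 3, 1, 1, groups = 8, bias = FALSE), p_bn(8),
      p_swish(), p_se(8, 2),
      p_conv2d(8, 16, 1, 1, 0, bias = FALSE), p_bn(16), p_swish(),
      p_conv2d(16, 32, 3, 2, 1, bias = FALSE), p_bn(32), p_swish()),
    ResNeXt50_32x4d = list(
      p_conv2d(3, 16, 3, 2, 1, bias = FALSE), p_bn(16), p_relu(),
      p_residual(
        list(p_conv2d(16, 16, 3, 1, 1, groups = 4, bias = FALSE),
             p_bn(16), p_relu(),
             p_conv2d(16, 32, 1, 1, 0, bias = FALSE), p_bn(32)),
        list(p_conv2d(16, 32, 1, 1, 0, bias = FALSE), p_bn(32))),
      p_relu(), p_maxpool(2)),
    sf_stop(sprintf("unknown backbone '%s'", backbone),
            class = "stressfuse_backbone_error"))
}

#' Names of the supported backbone architectures
#' @return Character vector of the three backbone names.
#' @export
backbone_names <- function() c("VGG16", "EfficientNetB0", "ResNeXt50_32x4d")

trunk_out_channels <- function(backbone, depth) {
  if (depth == "compact") return(32)
  switch(backbone, VGG16 = 512, EfficientNetB0 = 1280,
         ResNeXt50_32x4d = 2048)
}

#' Parameter counts of the canonical backbone architectures
#'
#' Counts trainable parameters (convolution and dense weights and biases,
#' batch-norm affine terms, squeeze-excitation projections) of the named
#' canonical architecture, computed analytically from the layer plan.
#'
#' @param backbone One of "VGG16", "EfficientNetB0", "ResNeXt50_32x4d".
#' @param variant "classifier" for the canonical 1000-class ImageNet network,
#'   "trunk" for the convolutional feature extractor only.
#' @return Integer parameter count.
#' @export
count_backbone_params <- function(backbone,
                                  variant = c("classifier", "trunk")) {
  variant <- match.arg(variant)
  plan <- switch(backbone,
    VGG16 = if (variant == "trunk") vgg16_trunk_plan() else
      vgg16_classifier_plan(),
    EfficientNetB0 = if (variant == "trunk") efficientnet_b0_trunk_plan()
      else efficientnet_b0_classifier_plan(),
    ResNeXt50_32x4d = if (variant == "trunk") resnext50_trunk_plan() else
      resnext50_classifier_plan(),
    sf_stop(sprintf("unknown backbone '%s'", backbone),
            class = "stressfuse_backbone_error"))
  plan_param_count(plan)
}

#' Backbone adapter specification
#'
#' @param backbone One of "VGG16", "EfficientNetB0", "ResNeXt50_32x4d".
#' @param input_size Input image side length in pixels (square, 3 channels).
#' @param projection_dim Width of the replacement projection head (256 or
#'   512 in the full-size profile; smaller in the test profile).
#' @param pretrained Load pretrained trunk weights from `weights_file`.
#'   Random (He) initialization is the default; parameter counts and all
#'   structural contracts are weight-independent.
#' @param weights_file Optional RDS file with a saved parameter list (as
#'   produced by [model_state()]).
#' @param depth "canonical" for the full published trunk; "compact" for the
#'   reduced-depth test-profile trunk.
#' @return An object of class `backbone_adapter_spec`.
#' @export
backbone_adapter_spec <- function(backbone, input_size = 128,
                                  projection_dim = 512, pretrained = FALSE,
                                  weights_file = NULL,
                                  depth = c("canonical", "compact")) {
  depth <- match.arg(depth)
  sf_assert(backbone %in% backbone_names(),
            sprintf("unknown backbone '%s'", backbone),
            class = "stressfuse_backbone_error")
  sf_assert(input_size >= 32, "input_size must be at least 32")
  if (pretrained && is.null(weights_file)) {
    sf_stop("pretrained = TRUE requires a weights_file",
            class = "stressfuse_weights_error")
  }
  structure(list(backbone = backbone, input_size = input_size,
                 projection_dim = projection_dim, pretrained = pretrained,
                 weights_file = weights_file, depth = depth),
            class = "backbone_adapter_spec")
}

#' Build a backbone feature-extractor adapter
#'
#' Materializes the named convolutional trunk with its classifier replaced
#' by global average pooling and a dense projection with ReLU, mapping a
#' 3-channel square image to a `projection_dim` feature vector.
#'
#' @param spec A [backbone_adapter_spec()].
#' @return An engine module; apply with [nn_forward()] on an
#'   (N, input_size, input_size, 3) array.
#' @export
build_backbone_adapter <- function(spec) {
  sf_assert(inherits(spec, "backbone_adapter_spec"),
            "backbone_adapter_spec required")
  trunk_plan <- if (spec$depth == "compact") {
    compact_trunk_plan(spec$backbone)
  } else {
    switch(spec$backbone,
      VGG16 = vgg16_trunk_plan(),
      EfficientNetB0 = efficientnet_b0_trunk_plan(),
      ResNeXt50_32x4d = resnext50_trunk_plan())
  }
  out_c <- trunk_out_channels(spec$backbone, spec$depth)
  mod <- plan_materialize(c(trunk_plan, list(
    p_gap(), p_dense(out_c, spec$projection_dim), p_relu())))
  mod$input_size <- spec$input_size
  mod$backbone <- spec$backbone
  mod$projection_dim <- spec$projection_dim
  if (spec$pretrained) {
    st <- readRDS(spec$weights_file)
    model_restore(mod, st)
  }
  mod
}

## ---- weight save/load --------------------------------------------------

#' Extract all parameters of a model as a plain list
#' @param module A built model/module.
#' @return List of parameter arrays, one entry per layer.
#' @export
model_state <- function(module) {
  lapply(nn_layers(module), function(l) {
    c(l$params,
      if (l$kind == "batchnorm") {
        list(.run_mean = l$run_mean, .run_var = l$run_var)
      })
  })
}

#' Restore parameters saved by [model_state()]
#' @param module A built model/module with identical architecture.
#' @param state A list from [model_state()].
#' @export
model_restore <- function(module, state) {
  layers <- nn_layers(module)
  sf_assert(length(layers) == length(state),
            "state does not match the architecture",
            class = "stressfuse_weights_error")
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (nm in names(state[[i]])) {
      if (nm == ".run_mean") l$run_mean <- state[[i]][[nm]]
      else if (nm == ".run_var") l$run_var <- state[[i]][[nm]]
      else {
        sf_assert(length(l$params[[nm]]) == length(state[[i]][[nm]]),
                  "parameter shape mismatch",
                  class = "stressfuse_weights_error")
        l$params[[nm]] <- state[[i]][[nm]]
      }
    }
  }
  invisible(module)
}
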