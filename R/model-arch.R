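# Dual-pathway architecture: EEG scalogram path through three backbone
# adapters, ECG raw + HRV paths, per-modality token self-attention, a
# learned cross-modal softmax gate, convex fusion, and the classification
# head.

#' Model size profiles
#'
#' The `full` profile carries the full published dimensions: 128x128x3 scalogram
#' input, three canonical backbones projected to 512 each (1536 concatenated,
#' reduced to a 512 embedding), ECG conv blocks of 64/128/256 filters with
#' three 256-wide adapters (768), HRV MLP 25-64-128-256, ECG fusion to 512,
#' 8x64 attention tokens, and a 256-128-3 head. The `test` profile keeps the
#' identical topology at reduced width (input 64, projections 128, embedding
#' 128, compact trunks) so end-to-end training runs on one CPU in minutes.
#'
#' @param name "full" or "test".
#' @return Named list of profile dimensions.
#' @export
model_profile <- function(name = c("full", "test")) {
  name <- match.arg(name)
  if (name == "full") {
    list(name = "full", input_size = 128, depth = "canonical",
         eeg_proj = 512, embed = 512, token_count = 8,
         ecg_blocks = c(64, 128, 256), ecg_kernels = c(15, 7, 3),
         ecg_strides = c(2, 2, 1), ecg_proj = 256, ecg_len = 7000,
         hrv_widths = c(64, 128, 256), head_widths = c(256, 128),
         gate_widths = c(256, 128))
  } else {
    list(name = "test", input_size = 64, depth = "compact",
         eeg_proj = 128, embed = 128, token_count = 8,
         ecg_blocks = c(8, 16, 32), ecg_kernels = c(15, 7, 3),
         ecg_strides = c(2, 2, 1), ecg_proj = 64, ecg_len = 7000,
         hrv_widths = c(32, 64, 64), head_widths = c(64, 32),
         gate_widths = c(64, 32))
  }
}

## ---- parallel-concat container ----------------------------------------

nn_parallel_concat <- function(modules) {
  new_layer("parallel", modules = modules)
}

#' @export
nn_forward.layer_parallel <- function(layer, x, training = FALSE) {
  outs <- lapply(layer$modules, nn_forward, x = x, training = training)
  layer$dims <- vapply(outs, ncol, numeric(1))
  do.call(cbind, outs)
}

#' @export
nn_backward.layer_parallel <- function(layer, dy) {
  ends <- cumsum(layer$dims)
  starts <- c(1, utils::head(ends, -1) + 1)
  dx <- NULL
  for (i in seq_along(layer$modules)) {
    d <- nn_backward(layer$modules[[i]],
                     dy[, starts[i]:ends[i], drop = FALSE])
    dx <- if (is.null(dx)) d else dx + d
  }
  dx
}

# (N, L, C) feature map -> (N, L, C, 3): the 1-D conv output is read as a
# single-channel time x channel image and replicated to three channels.
nn_map_to_image <- function() new_layer("map2img")

#' @export
nn_forward.layer_map2img <- function(layer, x, training = FALSE) {
  d <- dim(x)
  y <- array(0, c(d, 3))
  for (k in 1:3) y[, , , k] <- x
  y
}

#' @export
nn_backward.layer_map2img <- function(layer, dy) {
  dy[, , , 1] + dy[, , , 2] + dy[, , , 3]
}

## ---- EEG path -----------------------------------------------------------

#' Build the EEG pathway
#'
#' Three backbone adapters applied in parallel to the scalogram image; their
#' projections are concatenated (3 x 512 = 1536 in the full-size profile) and
#' reduced by a dense + ReLU layer to the modality embedding (512).
#'
#' @param backbone_specs List of three [backbone_adapter_spec()] objects
#'   with equal `projection_dim`.
#' @param embed_dim Width of the modality embedding.
#' @return Engine module mapping (N, s, s, 3) scalograms to (N, embed_dim).
#' @export
build_eeg_path <- function(backbone_specs, embed_dim = 512) {
  sf_assert(length(backbone_specs) >= 1, "at least one adapter required")
  proj <- vapply(backbone_specs, `[[`, numeric(1), "projection_dim")
  sf_assert(length(unique(proj)) == 1,
            "adapters must share one projection_dim",
            class = "stressfuse_shape_error")
  adapters <- lapply(backbone_specs, build_backbone_adapter)
  mod <- nn_sequential(list(
    nn_parallel_concat(adapters),
    nn_dense(sum(proj), embed_dim), nn_relu()))
  mod$concat_dim <- sum(proj)
  mod$embed_dim <- embed_dim
  mod$input_size <- backbone_specs[[1]]$input_size
  mod
}

#' Build the ECG raw-signal pathway
#'
#' Three 1-D convolution blocks (64 filters/kernel 15/stride 2; 128/7/2;
#' 256/3/1 in the full-size profile, each with batch norm, ReLU and max-pooling)
#' encode the 7000-sample segment; the resulting time x channel map is read
#' as a single-channel 2-D image, replicated to 3 channels, bilinearly
#' resized to the adapter input size, and passed through the same three
#' backbone architectures with 256-wide projections, concatenated to 768.
#'
#' @param backbone_specs List of three [backbone_adapter_spec()] objects.
#' @param profile A [model_profile()] (controls block widths and lengths).
#' @return Engine module mapping (N, 7000, 1) segments to (N, 3 * proj).
#' @export
build_ecg_raw_path <- function(backbone_specs, profile = model_profile()) {
  blocks <- list()
  in_c <- 1
  for (i in seq_along(profile$ecg_blocks)) {
    blocks <- c(blocks, list(
      nn_conv1d(in_c, profile$ecg_blocks[i], profile$ecg_kernels[i],
                profile$ecg_strides[i]),
      nn_batchnorm(profile$ecg_blocks[i]), nn_relu(),
      nn_maxpool1d(2)))
    in_c <- profile$ecg_blocks[i]
  }
  adapters <- lapply(backbone_specs, build_backbone_adapter)
  mod <- nn_sequential(c(blocks, list(
    nn_map_to_image(),
    nn_resize_bilinear(backbone_specs[[1]]$input_size,
                       backbone_specs[[1]]$input_size),
    nn_parallel_concat(adapters))))
  mod$expected_len <- profile$ecg_len
  mod$out_dim <- sum(vapply(backbone_specs, `[[`, numeric(1),
                            "projection_dim"))
  mod$conv_out_channels <- in_c
  mod
}

#' Validated forward pass of the ECG raw path
#' @param path Module from [build_ecg_raw_path()].
#' @param x (N, samples, 1) array; `samples` must equal the expected
#'   segment length (7000).
#' @param training Training mode flag.
#' @return (N, out_dim) matrix.
#' @export
ecg_raw_forward <- function(path, x, training = FALSE) {
  sf_assert(length(dim(x)) == 3 && dim(x)[2] == path$expected_len,
            sprintf("ECG raw path expects %d-sample segments, got %d",
                    path$expected_len, dim(x)[2]),
            class = "stressfuse_shape_error")
  nn_forward(path, x, training)
}

#' Build the HRV feature pathway
#'
#' A three-layer fully connected network over the 25-feature HRV panel:
#' 25 -> 64 (ReLU, dropout 0.3) -> 128 (ReLU, dropout 0.3) -> 256 (ReLU)
#' in the full-size profile.
#'
#' @param widths Hidden widths of the three layers.
#' @param dropout Dropout rate after the first two layers.
#' @return Engine module mapping (N, 25) to (N, widths[3]).
#' @export
build_hrv_path <- function(widths = c(64, 128, 256), dropout = 0.3) {
  mod <- nn_sequential(list(
    nn_dense(25, widths[1]), nn_relu(), nn_dropout(dropout),
    nn_dense(widths[1], widths[2]), nn_relu(), nn_dropout(dropout),
    nn_dense(widths[2], widths[3]), nn_relu()))
  mod$widths <- widths
  mod$out_dim <- widths[3]
  mod
}

#' Build the intra-ECG fusion layer
#'
#' Concatenates the raw-path vector (768) and HRV vector (256), in that
#' fixed order, and projects to the unified ECG embedding (512) with ReLU.
#'
#' @param raw_dim,hrv_dim Input widths.
#' @param embed_dim Output embedding width.
#' @return Engine module mapping (N, raw_dim + hrv_dim) to (N, embed_dim).
#' @export
build_ecg_fusion <- function(raw_dim = 768, hrv_dim = 256,
                             embed_dim = 512) {
  mod <- nn_sequential(list(nn_dense(raw_dim + hrv_dim, embed_dim),
                            nn_relu()))
  mod$raw_dim <- raw_dim
  mod$hrv_dim <- hrv_dim
  mod$embed_dim <- embed_dim
  mod$concat_order <- c("raw", "hrv")
  mod
}

## ---- token self-attention ----------------------------------------------

#' Token self-attention parameters
#'
#' The modality embedding is reshaped into `token_count` tokens (8 x 64 for
#' a 512 embedding) and scaled dot-product attention is applied with learned
#' token-wise Q, K, V projections; the key dimension equals the token width
#' (d_k = 64), and the result is flattened back to the embedding width.
#'
#' @param dim Embedding width (must be divisible by `token_count`).
#' @param token_count Number of tokens.
#' @return An attention module (engine layer of kind `self_attention`).
#' @export
self_attention_params <- function(dim = 512, token_count = 8) {
  sf_assert(dim %% token_count == 0,
            "embedding width must be divisible by the token count",
            class = "stressfuse_shape_error")
  dt <- dim %/% token_count
  l <- new_layer("self_attention", dim = dim, token_count = token_count,
                 d_k = dt)
  set_param(l, "Wq", he_normal(c(dt, dt), dt))
  set_param(l, "Wk", he_normal(c(dt, dt), dt))
  set_param(l, "Wv", he_normal(c(dt, dt), dt))
  l
}

row_softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' @export
nn_forward.layer_self_attention <- function(layer, x, training = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  N <- nrow(x)
  T_ <- layer$token_count
  dt <- layer$d_k
  sf_assert(ncol(x) == layer$dim,
            sprintf("self-attention expects width %d, got %d",
                    layer$dim, ncol(x)),
            class = "stressfuse_shape_error")
  xt <- array(x, c(N, dt, T_)) # [n, j, t]: token t = columns (t-1)*dt+1..
  y <- matrix(0, N, layer$dim)
  cache <- if (training) vector("list", N) else NULL
  for (n in seq_len(N)) {
    Xn <- t(xt[n, , , drop = TRUE]) # T x dt
    if (dt == 1) Xn <- matrix(xt[n, , ], T_, dt)
    Q <- Xn %*% layer$params$Wq
    K <- Xn %*% layer$params$Wk
    V <- Xn %*% layer$params$Wv
    S <- Q %*% t(K) / sqrt(dt)
    A <- row_softmax(S)
    On <- A %*% V # T x dt
    y[n, ] <- as.vector(t(On))
    if (training) cache[[n]] <- list(Xn = Xn, Q = Q, K = K, V = V, A = A)
  }
  if (training) layer$cache <- cache
  y
}

#' Attention weight matrix of one sample
#'
#' @param params Module from [self_attention_params()].
#' @param f A single embedding vector (or 1-row matrix).
#' @return token_count x token_count row-stochastic attention matrix.
#' @export
attention_weights <- function(params, f) {
  if (!is.null(dim(f))) f <- f[1, ]
  T_ <- params$token_count; dt <- params$d_k
  Xn <- t(array(f, c(dt, T_)))
  Q <- Xn %*% params$params$Wq
  K <- Xn %*% params$params$Wk
  row_softmax(Q %*% t(K) / sqrt(dt))
}

#' @export
nn_backward.layer_self_attention <- function(layer, dy) {
  N <- nrow(dy)
  T_ <- layer$token_count
  dt <- layer$d_k
  dx <- matrix(0, N, layer$dim)
  dWq <- layer$grads$Wq * 0; dWk <- dWq; dWv <- dWq
  for (n in seq_len(N)) {
    cc <- layer$cache[[n]]
    dOn <- t(array(dy[n, ], c(dt, T_))) # T x dt
    dA <- dOn %*% t(cc$V)
    dV <- t(cc$A) %*% dOn
    # softmax backward, rowwise
    dS <- cc$A * (dA - rowSums(dA * cc$A))
    dS <- dS / sqrt(dt)
    dQ <- dS %*% cc$K
    dK <- t(dS) %*% cc$Q
    dWq <- dWq + t(cc$Xn) %*% dQ
    dWk <- dWk + t(cc$Xn) %*% dK
    dWv <- dWv + t(cc$Xn) %*% dV
    dXn <- dQ %*% t(layer$params$Wq) + dK %*% t(layer$params$Wk) +
      dV %*% t(layer$params$Wv)
    dx[n, ] <- as.vector(t(dXn))
  }
  layer$grads$Wq <- layer$grads$Wq + dWq
  layer$grads$Wk <- layer$grads$Wk + dWk
  layer$grads$Wv <- layer$grads$Wv + dWv
  dx
}

#' Apply token self-attention to modality embeddings
#'
#' @param f (N, dim) matrix or length-dim vector of embeddings.
#' @param params Module from [self_attention_params()].
#' @return Attended embeddings of the same shape.
#' @export
self_attend <- function(f, params) {
  vec <- is.null(dim(f))
  y <- nn_forward(params, if (vec) matrix(f, 1) else f)
  if (vec) as.numeric(y) else y
}

## ---- cross-modal gate ----------------------------------------------------

#' Cross-modal gate parameters
#'
#' A two-layer perceptron (512-256-128 in the full-size profile) shared between
#' the modalities, followed by a learned attention vector w_a of length 128;
#' the two scalar logits pass through a two-way softmax so the gate weights
#' satisfy alpha_EEG + alpha_ECG = 1 exactly.
#'
#' @param dim Embedding width.
#' @param widths Hidden widths of the shared MLP.
#' @return A gate module (engine layer of kind `gate`).
#' @export
cross_modal_gate_params <- function(dim = 512, widths = c(256, 128)) {
  l <- new_layer("gate", dim = dim, widths = widths)
  l$mlp <- nn_sequential(list(
    nn_dense(dim, widths[1]), nn_relu(),
    nn_dense(widths[1], widths[2]), nn_relu()))
  set_param(l, "w_a", he_normal(c(widths[2], 1), widths[2]))
  l
}

gate_forward <- function(gate, f_eeg, f_ecg, training = FALSE) {
  N <- nrow(f_eeg)
  h <- nn_forward(gate$mlp, rbind(f_eeg, f_ecg), training)
  z <- as.numeric(h %*% gate$params$w_a)
  z_eeg <- z[seq_len(N)]
  z_ecg <- z[N + seq_len(N)]
  alpha_eeg <- 1 / (1 + exp(z_ecg - z_eeg)) # two-way softmax
  if (training) gate$cache <- list(h = h, N = N, alpha = alpha_eeg)
  list(alpha_eeg = alpha_eeg, alpha_ecg = 1 - alpha_eeg)
}

gate_backward <- function(gate, dalpha_eeg) {
  cc <- gate$cache
  a <- cc$alpha
  dz_eeg <- dalpha_eeg * a * (1 - a)
  dz <- c(dz_eeg, -dz_eeg)
  gate$grads$w_a <- gate$grads$w_a + crossprod(cc$h, dz)
  dh <- dz %*% t(gate$params$w_a)
  dstack <- nn_backward(gate$mlp, dh)
  list(d_eeg = dstack[seq_len(cc$N), , drop = FALSE],
       d_ecg = dstack[cc$N + seq_len(cc$N), , drop = FALSE])
}

#' Compute cross-modal gate weights
#'
#' @param f_eeg,f_ecg (N, dim) matrices or length-dim vectors.
#' @param params Module from [cross_modal_gate_params()].
#' @return List with `alpha_eeg` and `alpha_ecg` (each in (0, 1), summing
#'   to 1 exactly).
#' @export
cross_modal_gate <- function(f_eeg, f_ecg, params) {
  if (is.null(dim(f_eeg))) f_eeg <- matrix(f_eeg, 1)
  if (is.null(dim(f_ecg))) f_ecg <- matrix(f_ecg, 1)
  out <- gate_forward(params, f_eeg, f_ecg)
  if (length(out$alpha_eeg) == 1) {
    list(alpha_eeg = out$alpha_eeg[[1]], alpha_ecg = out$alpha_ecg[[1]])
  } else out
}

#' Per-sample fusion state
#'
#' @param f_eeg,f_ecg Modality embeddings.
#' @param a_eeg,a_ecg Self-attention outputs.
#' @param alpha_eeg,alpha_ecg Scalar gate weights (must sum to 1).
#' @return An object of class `fusion_state`.
#' @export
fusion_state <- function(f_eeg, f_ecg, a_eeg, a_ecg, alpha_eeg,
                         alpha_ecg) {
  sf_assert(abs(alpha_eeg + alpha_ecg - 1) < 1e-12,
            "gate weights must sum to 1")
  sf_assert(alpha_eeg >= 0 && alpha_ecg >= 0, "gate weights must be >= 0")
  structure(list(f_eeg = f_eeg, f_ecg = f_ecg, a_eeg = a_eeg,
                 a_ecg = a_ecg, alpha_eeg = alpha_eeg,
                 alpha_ecg = alpha_ecg),
            class = "fusion_state")
}

#' Fused representation (convex combination of attended embeddings)
#'
#' @param state A [fusion_state()].
#' @return Numeric vector `alpha_eeg * a_eeg + alpha_ecg * a_ecg`.
#' @export
fuse <- function(state) {
  sf_assert(inherits(state, "fusion_state"), "fusion_state required")
  state$alpha_eeg * state$a_eeg + state$alpha_ecg * state$a_ecg
}

## ---- classification head -------------------------------------------------

build_head <- function(in_dim, widths = c(256, 128), n_classes = 3,
                       dropout = 0.5) {
  nn_sequential(list(
    nn_dense(in_dim, widths[1]), nn_batchnorm(widths[1]), nn_relu(),
    nn_dropout(dropout),
    nn_dense(widths[1], widths[2]), nn_batchnorm(widths[2]), nn_relu(),
    nn_dropout(dropout),
    nn_dense(widths[2], n_classes)))
}

softmax_rows <- function(z) row_softmax(as.matrix(z))

#' Model configuration
#'
#' @param profile "full" or "test"; see [model_profile()].
#' @param variant Model variant: "full" (attention fusion), "no_attention"
#'   (identity attention, fixed 0.5 gates -- the late-average ablation;
#'   alias "late_fusion_average"), "early_fusion" (embedding concatenation,
#'   single head), "eeg_only", "ecg_only_hrv", "ecg_only_raw", or
#'   "drop_backbone" (one named adapter removed from both pathways).
#' @param backbones Character vector of backbone names for the EEG/ECG
#'   adapters.
#' @param eeg_backbone Backbone used by the "eeg_only" variant.
#' @param drop Backbone name removed by the "drop_backbone" variant.
#' @param seed Integer seed governing all weight initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(profile = "test", variant = "full",
                         backbones = backbone_names(),
                         eeg_backbone = "VGG16", drop = NULL,
                         seed = 1L) {
  prof <- if (is.list(profile)) profile else model_profile(profile)
  valid <- c("full", "no_attention", "late_fusion_average", "early_fusion",
             "eeg_only", "ecg_only_hrv", "ecg_only_raw", "drop_backbone")
  sf_assert(variant %in% valid,
            sprintf("unknown variant '%s'", variant),
            class = "stressfuse_variant_error")
  if (variant == "late_fusion_average") variant <- "no_attention"
  dropped <- NULL
  if (variant == "drop_backbone") {
    sf_assert(!is.null(drop) && drop %in% backbones,
              "drop_backbone needs `drop` naming one configured backbone")
    backbones <- setdiff(backbones, drop)
    dropped <- drop
    variant <- "full" # same wiring, one adapter fewer in both pathways
  }
  structure(list(profile = prof, variant = variant, backbones = backbones,
                 eeg_backbone = eeg_backbone, dropped = dropped,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Build the full dual-pathway fusion model (or an ablation variant)
#'
#' Composes the EEG path, the ECG raw and HRV paths with intra-ECG fusion,
#' per-modality token self-attention, the cross-modal gate, convex fusion,
#' and the classification head into a trainable model. Ablation variants
#' rewire the same components (see [model_config()]).
#'
#' @param config A [model_config()].
#' @return An object of class `stress_model` with `$predict(batch)` for
#'   inference; train with [train_model()].
#' @export
build_full_model <- function(config = model_config()) {
  sf_assert(inherits(config, "model_config"), "model_config required")
  prof <- config$profile
  m <- new.env(parent = emptyenv())
  m$config <- config
  m$counters <- new.env(parent = emptyenv())
  m$counters$eeg_reads <- 0L
  m$counters$ecg_reads <- 0L
  with_seed(config$seed, {
    specs_eeg <- lapply(config$backbones, function(b) {
      backbone_adapter_spec(b, prof$input_size, prof$eeg_proj,
                            depth = prof$depth)
    })
    specs_ecg <- lapply(config$backbones, function(b) {
      backbone_adapter_spec(b, prof$input_size, prof$ecg_proj,
                            depth = prof$depth)
    })
    if (config$variant == "eeg_only") {
      specs_eeg <- list(backbone_adapter_spec(
        config$eeg_backbone, prof$input_size, prof$eeg_proj,
        depth = prof$depth))
    }
    needs_eeg <- config$variant %in% c("full", "no_attention",
                                       "early_fusion", "eeg_only")
    needs_ecg <- config$variant %in% c("full", "no_attention",
                                       "early_fusion", "ecg_only_hrv",
                                       "ecg_only_raw")
    if (needs_eeg) {
      m$eeg_path <- build_eeg_path(specs_eeg, prof$embed)
    }
    if (needs_ecg && config$variant != "ecg_only_hrv") {
      m$ecg_raw <- build_ecg_raw_path(specs_ecg, prof)
    }
    if (needs_ecg && config$variant != "ecg_only_raw") {
      m$hrv_path <- build_hrv_path(prof$hrv_widths)
    }
    if (needs_ecg && !config$variant %in% c("ecg_only_hrv",
                                            "ecg_only_raw")) {
      m$ecg_fuse <- build_ecg_fusion(m$ecg_raw$out_dim,
                                     m$hrv_path$out_dim, prof$embed)
    }
    if (config$variant == "full") {
      m$att_eeg <- self_attention_params(prof$embed, prof$token_count)
      m$att_ecg <- self_attention_params(prof$embed, prof$token_count)
      m$gate <- cross_modal_gate_params(prof$embed, prof$gate_widths)
    }
    head_in <- switch(config$variant,
      full = prof$embed,
      no_attention = prof$embed,
      early_fusion = 2 * prof$embed,
      eeg_only = prof$embed,
      ecg_only_hrv = prof$hrv_widths[length(prof$hrv_widths)],
      ecg_only_raw = m$ecg_raw$out_dim)
    m$head <- build_head(head_in, prof$head_widths)
  })
  class(m) <- "stress_model"
  m$predict <- function(batch) model_forward(m, batch, training = FALSE)
  m
}

model_modules <- function(m) {
  mods <- list()
  for (nm in c("eeg_path", "ecg_raw", "hrv_path", "ecg_fuse", "att_eeg",
               "att_ecg", "gate", "head")) {
    if (!is.null(m[[nm]])) mods[[nm]] <- m[[nm]]
  }
  mods
}

#' @export
print.stress_model <- function(x, ...) {
  np <- sum(vapply(model_modules(x), nn_count_params, numeric(1)))
  cat(sprintf("<stress_model> %s profile, variant '%s', %s parameters\n",
              x$config$profile$name, x$config$variant,
              format(np, big.mark = ",")))
  invisible(x)
}

# Forward pass. `batch` is a list with elements (as required by variant):
# scalogram (N, s, s, 3), ecg (N, 7000, 1), hrv (N, 25).
model_forward <- function(m, batch, training = FALSE) {
  v <- m$config$variant
  out <- list()
  f_eeg <- NULL; f_ecg <- NULL
  if (!is.null(m$eeg_path)) {
    m$counters$eeg_reads <- m$counters$eeg_reads + 1L
    f_eeg <- nn_forward(m$eeg_path, batch$scalogram, training)
  }
  if (v %in% c("full", "no_attention", "early_fusion")) {
    m$counters$ecg_reads <- m$counters$ecg_reads + 1L
    raw <- ecg_raw_forward(m$ecg_raw, batch$ecg, training)
    hrv <- nn_forward(m$hrv_path, batch$hrv, training)
    f_ecg <- nn_forward(m$ecg_fuse, cbind(raw, hrv), training)
  } else if (v == "ecg_only_hrv") {
    m$counters$ecg_reads <- m$counters$ecg_reads + 1L
    f_ecg <- nn_forward(m$hrv_path, batch$hrv, training)
  } else if (v == "ecg_only_raw") {
    m$counters$ecg_reads <- m$counters$ecg_reads + 1L
    f_ecg <- ecg_raw_forward(m$ecg_raw, batch$ecg, training)
  }
  if (v == "full") {
    a_eeg <- nn_forward(m$att_eeg, f_eeg, training)
    a_ecg <- nn_forward(m$att_ecg, f_ecg, training)
    g <- gate_forward(m$gate, f_eeg, f_ecg, training)
    fused <- g$alpha_eeg * a_eeg + (1 - g$alpha_eeg) * a_ecg
    out$alpha_eeg <- g$alpha_eeg
    out$alpha_ecg <- g$alpha_ecg
    if (training) m$fuse_cache <- list(a_eeg = a_eeg, a_ecg = a_ecg,
                                       alpha = g$alpha_eeg)
  } else if (v == "no_attention") {
    fused <- 0.5 * f_eeg + 0.5 * f_ecg
    out$alpha_eeg <- rep(0.5, nrow(f_eeg))
    out$alpha_ecg <- rep(0.5, nrow(f_eeg))
  } else if (v == "early_fusion") {
    fused <- cbind(f_eeg, f_ecg)
  } else if (v == "eeg_only") {
    fused <- f_eeg
  } else {
    fused <- f_ecg
  }
  logits <- nn_forward(m$head, fused, training)
  out$f_eeg <- f_eeg
  out$f_ecg <- f_ecg
  out$logits <- logits
  out$probs <- softmax_rows(logits)
  out
}

# Backward pass from d(loss)/d(logits); accumulates gradients in place.
model_backward <- function(m, dlogits) {
  v <- m$config$variant
  dfused <- nn_backward(m$head, dlogits)
  d_feeg <- NULL; d_fecg <- NULL
  if (v == "full") {
    cc <- m$fuse_cache
    da_eeg <- dfused * cc$alpha
    da_ecg <- dfused * (1 - cc$alpha)
    dalpha <- rowSums(dfused * (cc$a_eeg - cc$a_ecg))
    d_feeg <- nn_backward(m$att_eeg, da_eeg)
    d_fecg <- nn_backward(m$att_ecg, da_ecg)
    dg <- gate_backward(m$gate, dalpha)
    d_feeg <- d_feeg + dg$d_eeg
    d_fecg <- d_fecg + dg$d_ecg
  } else if (v == "no_attention") {
    d_feeg <- 0.5 * dfused
    d_fecg <- 0.5 * dfused
  } else if (v == "early_fusion") {
    E <- m$config$profile$embed
    d_feeg <- dfused[, seq_len(E), drop = FALSE]
    d_fecg <- dfused[, E + seq_len(E), drop = FALSE]
  } else if (v == "eeg_only") {
    d_feeg <- dfused
  } else {
    d_fecg <- dfused
  }
  if (!is.null(d_feeg) && !is.null(m$eeg_path)) {
    nn_backward(m$eeg_path, d_feeg)
  }
  if (!is.null(d_fecg)) {
    if (v %in% c("full", "no_attention", "early_fusion")) {
      dcat <- nn_backward(m$ecg_fuse, d_fecg)
      rd <- m$ecg_raw$out_dim
      nn_backward(m$ecg_raw, dcat[, seq_len(rd), drop = FALSE])
      nn_backward(m$hrv_path, dcat[, rd + seq_len(m$hrv_path$out_dim),
                                   drop = FALSE])
    } else if (v == "ecg_only_hrv") {
      nn_backward(m$hrv_path, d_fecg)
    } else {
      nn_backward(m$ecg_raw, d_fecg)
    }
  }
  invisible(NULL)
}
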