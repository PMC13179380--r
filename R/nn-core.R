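# Minimal neural-network engine.
#
# Layers are environments carrying parameters, gradients and forward caches;
# matrix work is delegated to BLAS via im2col. Data layouts: dense (N, D),
# 1-D feature maps (N, L, C), 2-D feature maps (N, H, W, C), all column-major
# R arrays. Every layer implements nn_forward() and nn_backward(); containers
# (sequential, residual) recurse.

new_layer <- function(kind, ...) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$params <- list()
  e$grads <- list()
  e$decay <- logical(0) # per-param: subject to L2 weight decay?
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(paste0("layer_", kind), "nn_layer")
  e
}

he_normal <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

set_param <- function(layer, name, value, decay = TRUE) {
  layer$params[[name]] <- value
  layer$grads[[name]] <- array(0, dim(value) %||% length(value))
  layer$decay[name] <- decay
  invisible(layer)
}

#' @export
nn_forward <- function(layer, x, training = FALSE) UseMethod("nn_forward")
#' @export
nn_backward <- function(layer, dy) UseMethod("nn_backward")

# Flat list of parameterized layer environments inside a module.
nn_layers <- function(module) {
  if (inherits(module, "nn_layer")) {
    inner <- switch(module$kind,
      sequential = unlist(lapply(module$layers, nn_layers)),
      residual = c(unlist(lapply(module$layers, nn_layers)),
                   unlist(lapply(module$shortcut %||% list(), nn_layers))),
      conv1d = list(module$inner),
      maxpool1d = list(module$inner),
      parallel = unlist(lapply(module$modules, nn_layers)),
      gate = c(nn_layers(module$mlp), list(module)),
      list(module))
    if (module$kind %in% c("sequential", "residual", "conv1d",
                           "maxpool1d", "parallel", "gate")) {
      return(inner)
    }
    return(list(module))
  }
  if (is.list(module)) return(unlist(lapply(module, nn_layers)))
  list()
}

#' Count trainable parameters of a built module
#' @param module A layer/container built by the model constructors.
#' @return Integer count of trainable parameter values.
#' @export
nn_count_params <- function(module) {
  sum(vapply(nn_layers(module), function(l) {
    sum(vapply(l$params, length, numeric(1)))
  }, numeric(1)))
}

nn_zero_grads <- function(module) {
  for (l in nn_layers(module)) {
    for (nm in names(l$grads)) l$grads[[nm]][] <- 0
  }
  invisible(NULL)
}

# L2 penalty and its gradient contribution, decayed params only.
nn_l2_penalty <- function(module, lambda) {
  if (lambda <= 0) return(0)
  tot <- 0
  for (l in nn_layers(module)) {
    for (nm in names(l$params)) {
      if (isTRUE(l$decay[nm])) tot <- tot + sum(l$params[[nm]]^2)
    }
  }
  lambda * tot
}

nn_add_l2_grads <- function(module, lambda) {
  if (lambda <= 0) return(invisible(NULL))
  for (l in nn_layers(module)) {
    for (nm in names(l$params)) {
      if (isTRUE(l$decay[nm])) {
        l$grads[[nm]] <- l$grads[[nm]] + 2 * lambda * l$params[[nm]]
      }
    }
  }
  invisible(NULL)
}

## ---- containers ------------------------------------------------------

nn_sequential <- function(...) {
  layers <- list(...)
  if (length(layers) == 1 && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "nn_layer")) layers <- layers[[1]]
  new_layer("sequential", layers = layers)
}

#' @export
nn_forward.layer_sequential <- function(layer, x, training = FALSE) {
  for (l in layer$layers) x <- nn_forward(l, x, training)
  x
}

#' @export
nn_backward.layer_sequential <- function(layer, dy) {
  for (l in rev(layer$layers)) dy <- nn_backward(l, dy)
  dy
}

# y = F(x) + S(x); S is identity when shortcut is NULL.
nn_residual <- function(layers, shortcut = NULL) {
  new_layer("residual", layers = layers, shortcut = shortcut)
}

#' @export
nn_forward.layer_residual <- function(layer, x, training = FALSE) {
  main <- x
  for (l in layer$layers) main <- nn_forward(l, main, training)
  side <- x
  if (!is.null(layer$shortcut)) {
    for (l in layer$shortcut) side <- nn_forward(l, side, training)
  }
  main + side
}

#' @export
nn_backward.layer_residual <- function(layer, dy) {
  dmain <- dy
  for (l in rev(layer$layers)) dmain <- nn_backward(l, dmain)
  dside <- dy
  if (!is.null(layer$shortcut)) {
    for (l in rev(layer$shortcut)) dside <- nn_backward(l, dside)
  }
  dmain + dside
}

## ---- dense -----------------------------------------------------------

nn_dense <- function(d_in, d_out, bias = TRUE) {
  l <- new_layer("dense", d_in = d_in, d_out = d_out, bias = bias)
  set_param(l, "W", he_normal(c(d_in, d_out), d_in), decay = TRUE)
  if (bias) set_param(l, "b", numeric(d_out), decay = FALSE)
  l
}

#' @export
nn_forward.layer_dense <- function(layer, x, training = FALSE) {
  if (training) layer$cache_x <- x
  y <- x %*% layer$params$W
  if (layer$bias) y <- sweep(y, 2, layer$params$b, "+")
  y
}

#' @export
nn_backward.layer_dense <- function(layer, dy) {
  layer$grads$W <- layer$grads$W + crossprod(layer$cache_x, dy)
  if (layer$bias) layer$grads$b <- layer$grads$b + colSums(dy)
  dy %*% t(layer$params$W)
}

## ---- elementwise activations ----------------------------------------

nn_relu <- function() new_layer("relu")

#' @export
nn_forward.layer_relu <- function(layer, x, training = FALSE) {
  y <- pmax(x, 0)
  if (training) layer$cache_pos <- x > 0
  y
}

#' @export
nn_backward.layer_relu <- function(layer, dy) dy * layer$cache_pos

nn_swish <- function() new_layer("swish")

#' @export
nn_forward.layer_swish <- function(layer, x, training = FALSE) {
  s <- 1 / (1 + exp(-x))
  if (training) { layer$cache_x <- x; layer$cache_s <- s }
  x * s
}

#' @export
nn_backward.layer_swish <- function(layer, dy) {
  s <- layer$cache_s
  dy * (s + layer$cache_x * s * (1 - s))
}

nn_dropout <- function(p) new_layer("dropout", p = p)

#' @export
nn_forward.layer_dropout <- function(layer, x, training = FALSE) {
  if (!training || layer$p <= 0) return(x)
  mask <- array(stats::runif(length(x)) >= layer$p, dim(x) %||% length(x))
  layer$cache_mask <- mask / (1 - layer$p)
  x * layer$cache_mask
}

#' @export
nn_backward.layer_dropout <- function(layer, dy) {
  if (is.null(layer$cache_mask)) return(dy)
  dy * layer$cache_mask
}

## ---- batch normalization --------------------------------------------

# Channel = last array dimension (or the columns of a dense matrix).
nn_batchnorm <- function(channels, momentum = 0.1, eps = 1e-5) {
  l <- new_layer("batchnorm", channels = channels, momentum = momentum,
                 eps = eps,
                 run_mean = numeric(channels), run_var = rep(1, channels))
  set_param(l, "gamma", rep(1, channels), decay = FALSE)
  set_param(l, "beta", numeric(channels), decay = FALSE)
  l
}

bn_collapse <- function(x, channels) {
  d <- dim(x)
  if (is.null(d)) return(as.matrix(x))
  if (length(d) > 2) dim(x) <- c(prod(d[-length(d)]), channels)
  x
}

#' @export
nn_forward.layer_batchnorm <- function(layer, x, training = FALSE) {
  d <- dim(x)
  xm <- bn_collapse(x, layer$channels)
  m <- nrow(xm)
  if (training) {
    mu <- colMeans(xm)
    vr <- colMeans(xm^2) - mu^2
    layer$run_mean <- (1 - layer$momentum) * layer$run_mean +
      layer$momentum * mu
    layer$run_var <- (1 - layer$momentum) * layer$run_var +
      layer$momentum * vr
  } else {
    mu <- layer$run_mean
    vr <- layer$run_var
  }
  inv <- 1 / sqrt(vr + layer$eps)
  xhat <- (xm - rep(mu, each = m)) * rep(inv, each = m)
  y <- xhat * rep(layer$params$gamma, each = m) +
    rep(layer$params$beta, each = m)
  if (training) {
    layer$cache_xhat <- xhat
    layer$cache_inv <- inv
    layer$cache_dim <- d
  }
  if (!is.null(d) && length(d) > 2) dim(y) <- d
  y
}

#' @export
nn_backward.layer_batchnorm <- function(layer, dy) {
  d <- layer$cache_dim
  dym <- bn_collapse(dy, layer$channels)
  xhat <- layer$cache_xhat
  m <- nrow(dym)
  layer$grads$gamma <- layer$grads$gamma + colSums(dym * xhat)
  layer$grads$beta <- layer$grads$beta + colSums(dym)
  dxhat <- dym * rep(layer$params$gamma, each = m)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dx <- (dxhat - rep(s1 / m, each = m) - xhat * rep(s2 / m, each = m)) *
    rep(layer$cache_inv, each = m)
  if (!is.null(d) && length(d) > 2) dim(dx) <- d
  dx
}

## ---- 2-D convolution (im2col) ---------------------------------------

# 0-based offsets into the padded (Hp x Wp) plane for each output position
# (rows, oh fastest) and kernel tap (columns).
im2col_plane_index <- function(H, W, k, stride, pad) {
  Hp <- H + 2 * pad[1]; Wp <- W + 2 * pad[2]
  oh <- (Hp - k[1]) %/% stride[1] + 1
  ow <- (Wp - k[2]) %/% stride[2] + 1
  base_h <- (seq_len(oh) - 1) * stride[1]
  base_w <- (seq_len(ow) - 1) * stride[2]
  pos <- as.vector(outer(base_h, base_w * Hp, "+")) # oh fastest
  taps <- as.vector(outer(seq_len(k[1]) - 1, (seq_len(k[2]) - 1) * Hp, "+"))
  list(idx = outer(pos, taps, "+"), oh = oh, ow = ow, Hp = Hp, Wp = Wp)
}

pad_input <- function(x, pad) {
  if (all(pad == 0)) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2 * pad[1], d[3] + 2 * pad[2], d[4]))
  xp[, pad[1] + seq_len(d[2]), pad[2] + seq_len(d[3]), ] <- x
  xp
}

nn_conv2d <- function(in_c, out_c, kernel, stride = 1, pad = "same",
                      groups = 1, bias = TRUE) {
  if (length(kernel) == 1) kernel <- c(kernel, kernel)
  if (length(stride) == 1) stride <- c(stride, stride)
  if (identical(pad, "same")) pad <- (kernel - 1) %/% 2
  if (length(pad) == 1) pad <- c(pad, pad)
  sf_assert(in_c %% groups == 0 && out_c %% groups == 0,
            "channels must divide groups")
  depthwise <- groups == in_c && in_c == out_c
  l <- new_layer("conv2d", in_c = in_c, out_c = out_c, kernel = kernel,
                 stride = stride, pad = pad, groups = groups,
                 depthwise = depthwise, bias = bias)
  icg <- in_c %/% groups
  fan_in <- prod(kernel) * icg
  if (depthwise) {
    set_param(l, "W", he_normal(c(prod(kernel), in_c), fan_in))
  } else {
    # one weight matrix per group: (k*k*icg) x (out_c/groups), stacked
    set_param(l, "W", he_normal(c(prod(kernel) * icg, out_c), fan_in))
  }
  if (bias) set_param(l, "b", numeric(out_c), decay = FALSE)
  l
}

#' @export
nn_forward.layer_conv2d <- function(layer, x, training = FALSE) {
  d <- dim(x)
  N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  sf_assert(C == layer$in_c, sprintf("conv2d expects %d channels, got %d",
                                     layer$in_c, C),
            class = "stressfuse_shape_error")
  ii <- im2col_plane_index(H, W, layer$kernel, layer$stride, layer$pad)
  xm <- pad_input(x, layer$pad)
  dim(xm) <- c(N, ii$Hp * ii$Wp * C) # copy-free reshape
  P <- ii$oh * ii$ow
  kk <- prod(layer$kernel)
  plane <- ii$Hp * ii$Wp
  if (training) {
    layer$cache <- list(ii = ii, N = N, H = H, W = W, C = C, P = P, kk = kk)
  }
  if (layer$depthwise) {
    idx_all <- as.vector(outer(as.vector(ii$idx), (seq_len(C) - 1) * plane,
                               "+")) + 1
    Xc <- xm[, idx_all, drop = FALSE]
    dim(Xc) <- c(N * P, kk, C)
    y <- matrix(0, N * P, C)
    Wm <- layer$params$W
    for (q in seq_len(kk)) {
      y <- y + Xc[, q, ] * matrix(Wm[q, ], N * P, C, byrow = TRUE)
    }
    if (training) layer$cache$Xc <- Xc
  } else {
    icg <- layer$in_c %/% layer$groups
    ocg <- layer$out_c %/% layer$groups
    y <- matrix(0, N * P, layer$out_c)
    Xcols <- vector("list", layer$groups)
    for (g in seq_len(layer$groups)) {
      chans <- ((g - 1) * icg + 1):(g * icg)
      idx_g <- as.vector(outer(as.vector(ii$idx),
                               (chans - 1) * plane, "+")) + 1
      Xg <- xm[, idx_g, drop = FALSE]
      dim(Xg) <- c(N * P, kk * icg)
      wcols <- ((g - 1) * ocg + 1):(g * ocg)
      y[, wcols] <- Xg %*% layer$params$W[, wcols, drop = FALSE]
      if (training) Xcols[[g]] <- Xg
    }
    if (training) layer$cache$Xcols <- Xcols
  }
  if (layer$bias) y <- y + rep(layer$params$b, each = N * P)
  dim(y) <- c(N, ii$oh, ii$ow, layer$out_c)
  y
}

#' @export
nn_backward.layer_conv2d <- function(layer, dy) {
  cc <- layer$cache
  ii <- cc$ii; N <- cc$N; P <- cc$P; kk <- cc$kk; C <- cc$C
  plane <- ii$Hp * ii$Wp
  dym <- dy
  dim(dym) <- c(N * P, layer$out_c)
  if (layer$bias) layer$grads$b <- layer$grads$b + colSums(dym)
  dxm <- matrix(0, N, plane * C)
  if (layer$depthwise) {
    Xc <- cc$Xc
    dW <- layer$grads$W
    for (q in seq_len(kk)) {
      dW[q, ] <- dW[q, ] + colSums(Xc[, q, ] * dym)
    }
    layer$grads$W <- dW
    Wm <- layer$params$W
    for (q in seq_len(kk)) {
      contrib <- dym * matrix(Wm[q, ], N * P, C, byrow = TRUE) # (N*P, C)
      dim(contrib) <- c(N, P * C)
      cols <- as.vector(outer(ii$idx[, q], (seq_len(C) - 1) * plane,
                              "+")) + 1
      dxm[, cols] <- dxm[, cols] + contrib
    }
  } else {
    icg <- layer$in_c %/% layer$groups
    ocg <- layer$out_c %/% layer$groups
    for (g in seq_len(layer$groups)) {
      chans <- ((g - 1) * icg + 1):(g * icg)
      wcols <- ((g - 1) * ocg + 1):(g * ocg)
      dyg <- dym[, wcols, drop = FALSE]
      Xg <- cc$Xcols[[g]]
      layer$grads$W[, wcols] <- layer$grads$W[, wcols, drop = FALSE] +
        crossprod(Xg, dyg)
      dXg <- dyg %*% t(layer$params$W[, wcols, drop = FALSE])
      dim(dXg) <- c(N, P, kk * icg)
      idx_g <- outer(as.vector(ii$idx), (chans - 1) * plane, "+") + 1
      dim(idx_g) <- c(P, kk * icg)
      for (q in seq_len(kk * icg)) {
        dxm[, idx_g[, q]] <- dxm[, idx_g[, q]] + dXg[, , q]
      }
    }
  }
  dim(dxm) <- c(N, ii$Hp, ii$Wp, C)
  p <- layer$pad
  if (all(p == 0)) return(dxm)
  dxm[, p[1] + seq_len(cc$H), p[2] + seq_len(cc$W), , drop = FALSE]
}

## ---- pooling / reshaping --------------------------------------------

nn_maxpool2d <- function(kernel = 2, stride = kernel, pad = 0) {
  if (length(kernel) == 1) kernel <- c(kernel, kernel)
  if (length(stride) == 1) stride <- c(stride, stride)
  if (length(pad) == 1) pad <- c(pad, pad)
  new_layer("maxpool2d", kernel = kernel, stride = stride, pad = pad)
}

#' @export
nn_forward.layer_maxpool2d <- function(layer, x, training = FALSE) {
  d <- dim(x)
  N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  ii <- im2col_plane_index(H, W, layer$kernel, layer$stride, layer$pad)
  xp <- pad_input(x, layer$pad)
  if (any(layer$pad > 0)) {
    # padded cells must never win the max
    xp_min <- min(x) - 1
    mask <- array(TRUE, dim(xp))
    mask[, layer$pad[1] + seq_len(H), layer$pad[2] + seq_len(W), ] <- FALSE
    xp[mask] <- xp_min
  }
  plane <- ii$Hp * ii$Wp
  P <- ii$oh * ii$ow
  kk <- prod(layer$kernel)
  xm <- xp
  dim(xm) <- c(N, plane * C)
  idx_all <- as.vector(outer(as.vector(ii$idx), (seq_len(C) - 1) * plane,
                             "+")) + 1
  Xc <- xm[, idx_all, drop = FALSE]
  dim(Xc) <- c(N * P, kk, C)
  best <- Xc[, 1, , drop = TRUE]
  if (is.null(dim(best))) best <- matrix(best, N * P, C)
  argm <- matrix(1L, N * P, C)
  for (q in seq_len(kk)[-1]) {
    cand <- Xc[, q, ]
    if (is.null(dim(cand))) cand <- matrix(cand, N * P, C)
    upd <- cand > best
    best[upd] <- cand[upd]
    argm[upd] <- q
  }
  if (training) {
    layer$cache <- list(ii = ii, argm = argm, N = N, H = H, W = W, C = C,
                        P = P, kk = kk)
  }
  dim(best) <- c(N, ii$oh, ii$ow, C)
  best
}

#' @export
nn_backward.layer_maxpool2d <- function(layer, dy) {
  cc <- layer$cache
  ii <- cc$ii; N <- cc$N; P <- cc$P; C <- cc$C
  plane <- ii$Hp * ii$Wp
  dym <- dy
  dim(dym) <- c(N * P, C)
  dxm <- matrix(0, N, plane * C)
  for (q in seq_len(cc$kk)) {
    sel <- cc$argm == q
    if (!any(sel)) next
    contrib <- dym * sel
    dim(contrib) <- c(N, P * C)
    cols <- as.vector(outer(ii$idx[, q], (seq_len(C) - 1) * plane, "+")) + 1
    dxm[, cols] <- dxm[, cols] + contrib
  }
  dim(dxm) <- c(N, ii$Hp, ii$Wp, C)
  p <- layer$pad
  if (all(p == 0)) return(dxm)
  dxm[, p[1] + seq_len(cc$H), p[2] + seq_len(cc$W), , drop = FALSE]
}

# channel slab of an (N, hw, C) array as an (N, hw) matrix, drop-safe
chan_slab <- function(xm, c) {
  m <- xm[, , c]
  if (is.null(dim(m))) dim(m) <- c(dim(xm)[1], dim(xm)[2])
  m
}

# Channel-wise spatial means without transposition: (N, H, W, C) -> (N, C)
spatial_means <- function(x) {
  d <- dim(x)
  hw <- d[2] * d[3]
  xm <- x
  dim(xm) <- c(d[1], hw, d[4])
  y <- matrix(0, d[1], d[4])
  for (c in seq_len(d[4])) y[, c] <- rowMeans(chan_slab(xm, c))
  y
}

# Global average pooling (N, H, W, C) -> (N, C)
nn_gap2d <- function() new_layer("gap2d")

#' @export
nn_forward.layer_gap2d <- function(layer, x, training = FALSE) {
  if (training) layer$cache_dim <- dim(x)
  spatial_means(x)
}

#' @export
nn_backward.layer_gap2d <- function(layer, dy) {
  d <- layer$cache_dim
  hw <- d[2] * d[3]
  g <- array(0, c(d[1], hw, d[4]))
  for (c in seq_len(d[4])) g[, , c] <- dy[, c] / hw
  dim(g) <- d
  g
}

# Squeeze-and-excitation: channel gating s = sigmoid(W2 swish(W1 z)).
nn_se_block <- function(channels, se_channels) {
  l <- new_layer("se", channels = channels, se_channels = se_channels)
  set_param(l, "W1", he_normal(c(channels, se_channels), channels))
  set_param(l, "b1", numeric(se_channels), decay = FALSE)
  set_param(l, "W2", he_normal(c(se_channels, channels), se_channels))
  set_param(l, "b2", numeric(channels), decay = FALSE)
  l
}

#' @export
nn_forward.layer_se <- function(layer, x, training = FALSE) {
  d <- dim(x)
  N <- d[1]; C <- d[4]; hw <- d[2] * d[3]
  z <- spatial_means(x)
  a <- z %*% layer$params$W1 + rep(layer$params$b1, each = N)
  sa <- 1 / (1 + exp(-a))
  h <- a * sa # swish
  o <- h %*% layer$params$W2 + rep(layer$params$b2, each = N)
  s <- 1 / (1 + exp(-o)) # (N, C) channel gates
  y <- x
  dim(y) <- c(N, hw, C)
  for (c in seq_len(C)) y[, , c] <- y[, , c] * s[, c]
  dim(y) <- d
  if (training) {
    layer$cache <- list(x = x, z = z, a = a, sa = sa, h = h, s = s, d = d)
  }
  y
}

#' @export
nn_backward.layer_se <- function(layer, dy) {
  cc <- layer$cache
  d <- cc$d; N <- d[1]; C <- d[4]; hw <- d[2] * d[3]
  dym <- dy
  dim(dym) <- c(N, hw, C)
  xm <- cc$x
  dim(xm) <- c(N, hw, C)
  dx <- array(0, c(N, hw, C))
  ds <- matrix(0, N, C)
  for (c in seq_len(C)) {
    dx[, , c] <- chan_slab(dym, c) * cc$s[, c]
    ds[, c] <- rowSums(chan_slab(dym, c) * chan_slab(xm, c))
  }
  do_ <- ds * cc$s * (1 - cc$s)
  layer$grads$W2 <- layer$grads$W2 + crossprod(cc$h, do_)
  layer$grads$b2 <- layer$grads$b2 + colSums(do_)
  dh <- do_ %*% t(layer$params$W2)
  da <- dh * (cc$sa + cc$a * cc$sa * (1 - cc$sa))
  layer$grads$W1 <- layer$grads$W1 + crossprod(cc$z, da)
  layer$grads$b1 <- layer$grads$b1 + colSums(da)
  dz <- da %*% t(layer$params$W1)
  for (c in seq_len(C)) dx[, , c] <- dx[, , c] + dz[, c] / hw
  dim(dx) <- d
  dx
}

# Fixed bilinear resize (N, H, W, C) -> (N, out_h, out_w, C); linear operator.
nn_resize_bilinear <- function(out_h, out_w) {
  new_layer("resize", out_h = out_h, out_w = out_w)
}

resize_weights <- function(n_in, n_out) {
  # align-corners mapping; degenerate inputs map everything to sample 1
  R <- matrix(0, n_out, n_in)
  if (n_in == 1) { R[, 1] <- 1; return(R) }
  pos <- seq(0, n_in - 1, length.out = n_out)
  lo <- pmin(floor(pos), n_in - 2)
  fr <- pos - lo
  for (i in seq_len(n_out)) {
    R[i, lo[i] + 1] <- 1 - fr[i]
    R[i, lo[i] + 2] <- fr[i]
  }
  R
}

resize_apply <- function(x, Rh, Rw) {
  d <- dim(x)
  N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  oh <- nrow(Rh); ow <- nrow(Rw)
  out <- array(0, c(N, oh, ow, C))
  for (c in seq_len(C)) {
    xc <- x[, , , c, drop = FALSE]
    dim(xc) <- c(N * H, W)
    y1 <- xc %*% t(Rw) # contract W
    dim(y1) <- c(N, H, ow)
    m <- aperm(y1, c(2, 1, 3))
    dim(m) <- c(H, N * ow)
    r <- Rh %*% m # contract H
    dim(r) <- c(oh, N, ow)
    out[, , , c] <- aperm(r, c(2, 1, 3))
  }
  out
}

#' @export
nn_forward.layer_resize <- function(layer, x, training = FALSE) {
  d <- dim(x)
  Rh <- resize_weights(d[2], layer$out_h)
  Rw <- resize_weights(d[3], layer$out_w)
  if (training) layer$cache <- list(Rh = Rh, Rw = Rw)
  resize_apply(x, Rh, Rw)
}

#' @export
nn_backward.layer_resize <- function(layer, dy) {
  resize_apply(dy, t(layer$cache$Rh), t(layer$cache$Rw))
}

## ---- 1-D wrappers (as 2-D with H = 1) ---------------------------------

# copy-free: (N, L, C) <-> (N, 1, L, C) reshapes are layout-compatible only
# when the second dimension is a singleton inserted/removed at position 2;
# column-major order means (N, 1, L, C) and (N, L, C) share one layout.
as4d <- function(x) { d <- dim(x); dim(x) <- c(d[1], 1, d[2], d[3]); x }
as3d <- function(x) { d <- dim(x); dim(x) <- c(d[1], d[3], d[4]); x }

nn_conv1d <- function(in_c, out_c, kernel, stride = 1, pad = "same",
                      bias = TRUE) {
  if (identical(pad, "same")) pad <- (kernel - 1) %/% 2
  inner <- nn_conv2d(in_c, out_c, c(1, kernel), c(1, stride), c(0, pad),
                     bias = bias)
  new_layer("conv1d", inner = inner) # params live in inner
}

#' @export
nn_forward.layer_conv1d <- function(layer, x, training = FALSE) {
  as3d(nn_forward(layer$inner, as4d(x), training))
}

#' @export
nn_backward.layer_conv1d <- function(layer, dy) {
  as3d(nn_backward(layer$inner, as4d(dy)))
}

nn_maxpool1d <- function(kernel = 2, stride = kernel) {
  inner <- nn_maxpool2d(c(1, kernel), c(1, stride))
  new_layer("maxpool1d", inner = inner)
}

#' @export
nn_forward.layer_maxpool1d <- function(layer, x, training = FALSE) {
  as3d(nn_forward(layer$inner, as4d(x), training))
}

#' @export
nn_backward.layer_maxpool1d <- function(layer, dy) {
  as3d(nn_backward(layer$inner, as4d(dy)))
}

## ---- optimizer --------------------------------------------------------

#' Adam optimizer state
#'
#' @param beta1,beta2,eps Adam moment coefficients and stabilizer.
#' @return An optimizer environment for [adam_step()].
#' @export
adam_optimizer <- function(beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  e <- new.env(parent = emptyenv())
  e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps; e$t <- 0
  e$state <- list()
  class(e) <- "adam_optimizer"
  e
}

#' One Adam update over all trainable parameters
#' @param opt An [adam_optimizer()].
#' @param module A built model/module.
#' @param lr Learning rate for this step.
#' @export
adam_step <- function(opt, module, lr) {
  opt$t <- opt$t + 1
  layers <- nn_layers(module)
  for (li in seq_along(layers)) {
    l <- layers[[li]]
    for (nm in names(l$params)) {
      key <- paste0(li, ".", nm)
      g <- l$grads[[nm]]
      st <- opt$state[[key]]
      if (is.null(st)) st <- list(m = g * 0, v = g * 0)
      st$m <- opt$beta1 * st$m + (1 - opt$beta1) * g
      st$v <- opt$beta2 * st$v + (1 - opt$beta2) * g^2
      opt$state[[key]] <- st
      mhat <- st$m / (1 - opt$beta1^opt$t)
      vhat <- st$v / (1 - opt$beta2^opt$t)
      l$params[[nm]] <- l$params[[nm]] - lr * mhat / (sqrt(vhat) + opt$eps)
    }
  }
  invisible(NULL)
}
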