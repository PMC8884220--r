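# Content-aware multi-focus fusion network.
#
# Architecture: every focal plane I_i is passed through one shared
# convolutional encoder E (NL stride-2 stages) and a chain of residual
# blocks R; the D transformed feature tensors are fused by an element-wise
# maximum; a decoder C of NL transposed-convolution stages maps the fused
# tensor back to image space with a tanh output:
#
#   O = tanh( C( max( R(E(I_1)), ..., R(E(I_D)) ) ) )
#
# Because the encoder weights are shared and max is commutative, the output
# is exactly invariant to plane order and the parameter count is independent
# of D: one trained model fuses 3, 7 or 14 planes alike.
#
# The network is implemented directly on matrices (feature maps stored as
# (H*W) x C, column-major pixels) with im2col gathers feeding BLAS matrix
# multiplies; gradients are hand-derived. No deep-learning runtime is
# needed, and training is fully deterministic given the seed.

#' Fusion network configuration
#'
#' @param NL number of stride-2 encoder stages (spatial downsampling
#'   2^NL); the decoder mirrors them with transposed convolutions.
#' @param Ed encoder channel depth at the bottleneck; must be divisible by
#'   `2^(NL-1)` (stage channels are Ed/2^(NL-1), ..., Ed/2, Ed).
#' @param n_res_blocks number of residual blocks before the fusion (default 5).
#' @param kernel_size convolution kernel size (default 3).
#' @param up_kernel_size transposed-convolution kernel size in the decoder
#'   (default 4: even kernels overlap uniformly at stride 2, avoiding
#'   checkerboard artifacts).
#' @param patch_size training crop size in pixels; must be divisible by
#'   `2^NL`. 256 is the full-scale default; 64 suits desk-scale runs.
#' @param loss_weights weights (lambda1, lambda2, lambda3) of the MAE, SSIM
#'   and FFT loss components; defaults 1.0, 0.1, 0.5.
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param batch_size training batch size (default 2).
#' @param seed master seed controlling initialization, data order and crops.
#' @return An object of class `fusion_net_config`.
#' @export
fusion_net_config <- function(NL = 2L, Ed = 64L, n_res_blocks = 5L,
                              kernel_size = 3L, up_kernel_size = 4L,
                              patch_size = 256L,
                              loss_weights = c(1.0, 0.1, 0.5),
                              learning_rate = 1e-4, batch_size = 2L,
                              seed = 1L) {
  NL <- as.integer(NL); Ed <- as.integer(Ed)
  stopifnot(NL >= 1L, n_res_blocks >= 1L, length(loss_weights) == 3L,
            all(loss_weights >= 0))
  if (patch_size %% 2L^NL != 0L)
    stop("patch_size must be divisible by 2^NL")
  if (Ed %% 2L^(NL - 1L) != 0L)
    stop("Ed must be divisible by 2^(NL-1)")
  structure(list(NL = NL, Ed = Ed, n_res_blocks = as.integer(n_res_blocks),
                 kernel_size = as.integer(kernel_size),
                 up_kernel_size = as.integer(up_kernel_size),
                 patch_size = as.integer(patch_size),
                 loss_weights = as.numeric(loss_weights),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "fusion_net_config")
}

#' Small-scale fusion network configuration
#'
#' A reduced configuration for CPU-scale experiments on simulated data:
#' NL = 2 encoder stages, Ed = 16 bottleneck channels, 64-px patches, and a
#' short-schedule Adam learning rate of 4e-3 (a few hundred updates of a
#' ~30k-parameter model; the full-scale default of 1e-4 is matched to long
#' schedules on 256-px patches). All other fields follow the full-scale
#' defaults.
#'
#' @param seed master seed.
#' @param ... overrides passed on to [fusion_net_config()].
#' @return a [fusion_net_config].
#' @export
small_net_config <- function(seed = 1L, ...) {
  fusion_net_config(NL = 2L, Ed = 16L, n_res_blocks = 5L, patch_size = 64L,
                    learning_rate = 4e-3, batch_size = 2L, seed = seed, ...)
}

# ---------------------------------------------------------------------------
# convolution plans: cached im2col index matrices per input geometry

.plan_cache <- new.env(parent = emptyenv())

conv_plan <- function(h, w, k, stride, pad) {
  key <- paste(h, w, k, stride, pad, sep = "_")
  hit <- .plan_cache[[key]]
  if (!is.null(hit)) return(hit)
  hout <- (h + 2L * pad - k) %/% stride + 1L
  wout <- (w + 2L * pad - k) %/% stride + 1L
  ro <- rep(seq_len(hout), times = wout)
  co <- rep(seq_len(wout), each = hout)
  nout <- hout * wout
  idx <- matrix(1L, nout, k * k)           # 1 = zero-padding row
  tap <- 0L
  for (dc in 0L:(k - 1L)) for (dr in 0L:(k - 1L)) {
    tap <- tap + 1L
    ri <- (ro - 1L) * stride + 1L - pad + dr
    ci <- (co - 1L) * stride + 1L - pad + dc
    ok <- ri >= 1L & ri <= h & ci >= 1L & ci <= w
    idx[ok, tap] <- (ci[ok] - 1L) * h + ri[ok] + 1L
  }
  idxv <- as.vector(idx)
  plan <- list(h = h, w = w, hout = hout, wout = wout, nout = nout,
               k2 = k * k, npix = h * w, idx = idx, idxv = idxv,
               scatter_rows = sort(unique(idxv)))
  .plan_cache[[key]] <- plan
  plan
}

# gather im2col columns: X is npix x C -> nout x (k2*C)
conv_gather <- function(X, plan) {
  Xp <- rbind(0, X)
  g <- Xp[plan$idxv, , drop = FALSE]
  dim(g) <- c(plan$nout, plan$k2 * ncol(X))
  g
}

# scatter-add: M is (nout*k2) x C rows ordered (outpix fastest, then tap)
conv_scatter <- function(M, plan) {
  gs <- rowsum(M, group = plan$idxv, reorder = TRUE)
  out <- matrix(0, plan$npix + 1L, ncol(M))
  out[plan$scatter_rows, ] <- gs
  out[-1L, , drop = FALSE]
}

conv_forward <- function(X, W, b, plan) {
  Y <- conv_gather(X, plan) %*% W
  Y + rep(b, each = nrow(Y))
}

conv_backward <- function(X, W, plan, dY) {
  cols <- conv_gather(X, plan)
  dcols <- dY %*% t(W)
  dim(dcols) <- c(plan$nout * plan$k2, ncol(X))
  list(dX = conv_scatter(dcols, plan),
       dW = crossprod(cols, dY),
       db = colSums(dY))
}

# transposed convolution: adjoint of the stride-2 conv described by `plan`
# (which maps the big grid to the small grid). X: nsmall x Cin,
# W: (k2*Cout) x Cin, output: npix_big x Cout.
convt_forward <- function(X, W, b, plan) {
  Z <- X %*% t(W)                              # nsmall x (k2*Cout)
  cout <- ncol(Z) %/% plan$k2
  dim(Z) <- c(nrow(X) * plan$k2, cout)
  Y <- conv_scatter(Z, plan)
  Y + rep(b, each = nrow(Y))
}

convt_backward <- function(X, W, plan, dY) {
  dZ <- conv_gather(dY, plan)                  # nsmall x (k2*Cout)
  list(dX = dZ %*% W,
       dW = crossprod(dZ, X),
       db = colSums(dY))
}

lrelu <- function(x, slope = 0.2) { x[x < 0] <- slope * x[x < 0]; x }
lrelu_grad <- function(x, dy, slope = 0.2) { dy[x < 0] <- slope * dy[x < 0]; dy }

# ---------------------------------------------------------------------------
# parameters

enc_channels <- function(cfg) {
  c(3L, cfg$Ed %/% 2L^((cfg$NL - 1L):0L))
}

dec_channels <- function(cfg) {
  chans <- cfg$Ed %/% 2L^(0:(cfg$NL - 1L))
  c(chans, 3L)
}

#' Initialize fusion network parameters
#'
#' He-normal weight initialization, zero biases; fully determined by
#' `cfg$seed`. The parameter count does not depend on the number of focal
#' planes D, because the encoder and residual blocks are shared across
#' planes.
#'
#' @param cfg a [fusion_net_config].
#' @return An object of class `cami_params`: the config plus a named flat
#'   list of weight/bias arrays.
#' @export
init_params <- function(cfg) {
  set.seed(cfg$seed)
  k2 <- cfg$kernel_size^2
  he <- function(rows, cols, fan_in)
    matrix(stats::rnorm(rows * cols, sd = sqrt(2 / fan_in)), rows, cols)
  w <- list()
  ec <- enc_channels(cfg)
  for (i in seq_len(cfg$NL)) {
    w[[paste0("enc", i, "_W")]] <- he(k2 * ec[i], ec[i + 1L], k2 * ec[i])
    w[[paste0("enc", i, "_b")]] <- numeric(ec[i + 1L])
  }
  for (j in seq_len(cfg$n_res_blocks)) {
    w[[paste0("res", j, "_1_W")]] <- he(k2 * cfg$Ed, cfg$Ed, k2 * cfg$Ed)
    w[[paste0("res", j, "_1_b")]] <- numeric(cfg$Ed)
    # zero-init the residual branch output so every block starts as the
    # identity: keeps the feature scale bounded through deep block chains
    w[[paste0("res", j, "_2_W")]] <- matrix(0, k2 * cfg$Ed, cfg$Ed)
    w[[paste0("res", j, "_2_b")]] <- numeric(cfg$Ed)
  }
  dc <- dec_channels(cfg)
  uk2 <- cfg$up_kernel_size^2
  for (i in seq_len(cfg$NL)) {
    # transposed conv: W is (uk2 * Cout) x Cin
    w[[paste0("dec", i, "_W")]] <- he(uk2 * dc[i + 1L], dc[i], uk2 * dc[i])
    w[[paste0("dec", i, "_b")]] <- numeric(dc[i + 1L])
  }
  structure(list(cfg = cfg, weights = w), class = "cami_params")
}

#' @export
print.cami_params <- function(x, ...) {
  n <- sum(vapply(x$weights, length, numeric(1)))
  cat(sprintf("cami_params: NL=%d, Ed=%d, %d residual blocks, %d parameters\n",
              x$cfg$NL, x$cfg$Ed, x$cfg$n_res_blocks, n))
  invisible(x)
}

#' Total number of learnable parameters
#' @param params a `cami_params` object.
#' @return integer count (independent of the number of fused planes).
#' @export
n_parameters <- function(params) sum(vapply(params$weights, length, numeric(1)))

# ---------------------------------------------------------------------------
# forward passes (matrix form, with caches for backprop)

mat_from_img <- function(img) { d <- dim(img); dim(img) <- c(d[1L] * d[2L], d[3L]); img }
img_from_mat <- function(m, h, w) array(m, c(h, w, ncol(m)))

encode_mat <- function(X, h, w, params) {
  cfg <- params$cfg; k <- cfg$kernel_size; pad <- (k - 1L) %/% 2L
  cache <- list(); hh <- h; ww <- w
  for (i in seq_len(cfg$NL)) {
    plan <- conv_plan(hh, ww, k, 2L, pad)
    pre <- conv_forward(X, params$weights[[paste0("enc", i, "_W")]],
                        params$weights[[paste0("enc", i, "_b")]], plan)
    cache[[i]] <- list(X = X, pre = pre, plan = plan)
    X <- lrelu(pre)
    hh <- plan$hout; ww <- plan$wout
  }
  list(out = X, h = hh, w = ww, cache = cache)
}

encode_mat_backward <- function(cache, params, dY) {
  cfg <- params$cfg
  grads <- list()
  for (i in rev(seq_len(cfg$NL))) {
    st <- cache[[i]]
    dpre <- lrelu_grad(st$pre, dY)
    bw <- conv_backward(st$X, params$weights[[paste0("enc", i, "_W")]], st$plan, dpre)
    grads[[paste0("enc", i, "_W")]] <- bw$dW
    grads[[paste0("enc", i, "_b")]] <- bw$db
    dY <- bw$dX
  }
  list(dX = dY, grads = grads)
}

res_mat <- function(X, h, w, params) {
  cfg <- params$cfg; k <- cfg$kernel_size; pad <- (k - 1L) %/% 2L
  plan <- conv_plan(h, w, k, 1L, pad)
  cache <- list()
  for (j in seq_len(cfg$n_res_blocks)) {
    pre1 <- conv_forward(X, params$weights[[paste0("res", j, "_1_W")]],
                         params$weights[[paste0("res", j, "_1_b")]], plan)
    a1 <- lrelu(pre1)
    pre2 <- conv_forward(a1, params$weights[[paste0("res", j, "_2_W")]],
                         params$weights[[paste0("res", j, "_2_b")]], plan)
    cache[[j]] <- list(X = X, pre1 = pre1, a1 = a1)
    X <- X + pre2
  }
  list(out = X, plan = plan, cache = cache)
}

res_mat_backward <- function(cache, plan, params, dY) {
  cfg <- params$cfg
  grads <- list()
  for (j in rev(seq_len(cfg$n_res_blocks))) {
    st <- cache[[j]]
    bw2 <- conv_backward(st$a1, params$weights[[paste0("res", j, "_2_W")]], plan, dY)
    grads[[paste0("res", j, "_2_W")]] <- bw2$dW
    grads[[paste0("res", j, "_2_b")]] <- bw2$db
    dpre1 <- lrelu_grad(st$pre1, bw2$dX)
    bw1 <- conv_backward(st$X, params$weights[[paste0("res", j, "_1_W")]], plan, dpre1)
    grads[[paste0("res", j, "_1_W")]] <- bw1$dW
    grads[[paste0("res", j, "_1_b")]] <- bw1$db
    dY <- dY + bw1$dX                      # skip connection
  }
  list(dX = dY, grads = grads)
}

decode_mat <- function(X, h, w, params) {
  cfg <- params$cfg; k <- cfg$up_kernel_size
  pad <- (k - 2L) %/% 2L                    # stride-2: (h + 2p - k)/2 + 1 = h/2
  cache <- list(); hh <- h; ww <- w
  n <- cfg$NL
  for (i in seq_len(n)) {
    hb <- hh * 2L; wb <- ww * 2L
    plan <- conv_plan(hb, wb, k, 2L, pad)   # big -> small geometry; we adjoin
    pre <- convt_forward(X, params$weights[[paste0("dec", i, "_W")]],
                         params$weights[[paste0("dec", i, "_b")]], plan)
    cache[[i]] <- list(X = X, pre = pre, plan = plan)
    X <- if (i < n) lrelu(pre) else tanh(pre)
    hh <- hb; ww <- wb
  }
  list(out = X, h = hh, w = ww, cache = cache)
}

decode_mat_backward <- function(cache, params, dY, out_final) {
  cfg <- params$cfg; n <- cfg$NL
  grads <- list()
  for (i in rev(seq_len(n))) {
    st <- cache[[i]]
    dpre <- if (i < n) lrelu_grad(st$pre, dY) else dY * (1 - out_final^2)
    bw <- convt_backward(st$X, params$weights[[paste0("dec", i, "_W")]], st$plan, dpre)
    grads[[paste0("dec", i, "_W")]] <- bw$dW
    grads[[paste0("dec", i, "_b")]] <- bw$db
    dY <- bw$dX
  }
  list(dX = dY, grads = grads)
}

# full forward over a list of plane matrices (npix x 3, values in [-1, 1]).
cami_forward_mat <- function(planes, h, w, params, keep_cache = FALSE) {
  feats <- vector("list", length(planes))
  enc_caches <- if (keep_cache) vector("list", length(planes)) else NULL
  res_caches <- if (keep_cache) vector("list", length(planes)) else NULL
  hb <- wb <- NULL; res_plan <- NULL
  for (i in seq_along(planes)) {
    e <- encode_mat(planes[[i]], h, w, params)
    r <- res_mat(e$out, e$h, e$w, params)
    feats[[i]] <- r$out
    hb <- e$h; wb <- e$w; res_plan <- r$plan
    if (keep_cache) { enc_caches[[i]] <- e$cache; res_caches[[i]] <- r$cache }
  }
  fused <- feats[[1L]]
  winner <- matrix(1L, nrow(fused), ncol(fused))
  if (length(feats) > 1L) for (i in 2:length(feats)) {
    w_i <- feats[[i]] > fused
    fused[w_i] <- feats[[i]][w_i]
    winner[w_i] <- i
  }
  dec <- decode_mat(fused, hb, wb, params)
  list(out = dec$out, h = dec$h, w = dec$w,
       cache = if (keep_cache) list(enc = enc_caches, res = res_caches,
                                    winner = winner, res_plan = res_plan,
                                    dec = dec$cache, feats_dim = dim(fused)) else NULL)
}

cami_backward_mat <- function(fw, params, dOut) {
  cache <- fw$cache
  dec_bw <- decode_mat_backward(cache$dec, params, dOut, fw$out)
  grads <- dec_bw$grads
  d_fused <- dec_bw$dX
  n_planes <- max(cache$winner)
  add_grads <- function(acc, g) {
    for (nm in names(g)) acc[[nm]] <- if (is.null(acc[[nm]])) g[[nm]] else acc[[nm]] + g[[nm]]
    acc
  }
  for (i in seq_len(n_planes)) {
    d_feat <- d_fused * (cache$winner == i)
    res_bw <- res_mat_backward(cache$res[[i]], cache$res_plan, params, d_feat)
    grads <- add_grads(grads, res_bw$grads)
    enc_bw <- encode_mat_backward(cache$enc[[i]], params, res_bw$dX)
    grads <- add_grads(grads, enc_bw$grads)
  }
  grads
}

# ---------------------------------------------------------------------------
# user-facing array API

check_divisible <- function(h, w, NL) {
  if (h %% 2L^NL != 0L || w %% 2L^NL != 0L)
    stop("image dimensions (", h, " x ", w, ") must be divisible by 2^NL = ", 2L^NL,
         "; pad upstream")
}

#' Encode one focal plane to its feature tensor
#'
#' @param plane `H x W x 3` array in \[-1, 1\].
#' @param params a `cami_params` object.
#' @return feature array `H/2^NL x W/2^NL x Ed`.
#' @export
encode <- function(plane, params) {
  d <- dim(plane); check_divisible(d[1L], d[2L], params$cfg$NL)
  e <- encode_mat(mat_from_img(plane), d[1L], d[2L], params)
  img_from_mat(e$out, e$h, e$w)
}

#' Apply the residual transform to an encoded feature tensor
#'
#' Each of the `n_res_blocks` blocks computes `x + F(x)` where `F` is
#' conv -> leaky-ReLU -> conv, channel- and shape-preserving; with all-zero
#' block weights the transform is the identity.
#'
#' @param features bottleneck feature array from [encode()].
#' @param params a `cami_params` object.
#' @return feature array of identical shape.
#' @export
residual_transform <- function(features, params) {
  d <- dim(features)
  r <- res_mat(mat_from_img(features), d[1L], d[2L], params)
  img_from_mat(r$out, d[1L], d[2L])
}

#' Element-wise maximum fusion of feature tensors
#'
#' @param feature_tensors list of congruent numeric arrays (one per plane).
#' @return single array: the element-wise maximum. Invariant to the order of
#'   the list; the identity for a single tensor.
#' @export
fuse_max <- function(feature_tensors) {
  stopifnot(length(feature_tensors) >= 1L)
  d <- dim(feature_tensors[[1L]])
  for (f in feature_tensors)
    if (!identical(dim(f), d)) stop("feature tensors must be congruent")
  Reduce(pmax, feature_tensors)
}

#' Decode a fused feature tensor back to an RGB image
#'
#' `NL` transposed-convolution stages upsample back to the input resolution;
#' the final activation is tanh, so outputs lie in (-1, 1).
#'
#' @param fused_features bottleneck feature array.
#' @param params a `cami_params` object.
#' @return `H x W x 3` array in (-1, 1).
#' @export
decode <- function(fused_features, params) {
  d <- dim(fused_features)
  dec <- decode_mat(mat_from_img(fused_features), d[1L], d[2L], params)
  img_from_mat(dec$out, dec$h, dec$w)
}

#' Fuse a z-stack with the content-aware network
#'
#' Runs the full forward pass: each plane is mapped to \[-1, 1\], encoded and
#' residual-transformed with shared weights, the feature tensors are fused by
#' element-wise maximum, and the decoder produces the output image, which is
#' mapped back to \[0, 1\]. Works for any number of planes D >= 1 with the
#' same trained parameters.
#'
#' @param stack a [zstack] (any declared range; mapped internally).
#' @param params a `cami_params` object.
#' @return an [edof_image] with method `"cami"`.
#' @export
cami_fuse <- function(stack, params) {
  stopifnot(inherits(stack, "zstack"), inherits(params, "cami_params"))
  d <- dim(stack$planes[[1L]])
  check_divisible(d[1L], d[2L], params$cfg$NL)
  norm <- normalize_for_network(stack)
  planes <- lapply(norm$planes, mat_from_img)
  fw <- cami_forward_mat(planes, d[1L], d[2L], params)
  out <- denormalize_image(img_from_mat(fw$out, d[1L], d[2L]))
  edof_image(out, "cami", n_planes(stack), stack$axial_step)
}

# ---------------------------------------------------------------------------
# training

#' Sample co-located training patches from a stack/target pair
#'
#' Draws `n` uniform random crop positions (reproducible from `seed`) and
#' extracts the same window from every focal plane and from the target.
#'
#' @param pair list with `input` (a [zstack]) and `target` (an [edof_image]
#'   or `H x W x 3` array in \[0, 1\]).
#' @param patch_size crop side length in pixels.
#' @param n number of patches.
#' @param seed RNG seed.
#' @return list of `n` elements, each `list(planes = <list of arrays>,
#'   target = <array>, row, col)`.
#' @export
sample_patches <- function(pair, patch_size, n, seed) {
  tgt <- if (inherits(pair$target, "edof_image")) pair$target$image else pair$target
  d <- dim(pair$input$planes[[1L]])
  if (d[1L] < patch_size || d[2L] < patch_size)
    stop("stack (", d[1L], " x ", d[2L], ") is smaller than the patch size")
  set.seed(seed)
  rows <- sample.int(d[1L] - patch_size + 1L, n, replace = TRUE)
  cols <- sample.int(d[2L] - patch_size + 1L, n, replace = TRUE)
  lapply(seq_len(n), function(i) {
    r <- rows[i]:(rows[i] + patch_size - 1L)
    cc <- cols[i]:(cols[i] + patch_size - 1L)
    list(planes = lapply(pair$input$planes, function(p) p[r, cc, , drop = FALSE]),
         target = tgt[r, cc, , drop = FALSE],
         row = rows[i], col = cols[i])
  })
}

#' Train the fusion network
#'
#' Runs `n_steps` Adam updates of the combined MAE + SSIM + FFT loss on
#' random 'patch batches: each step samples `cfg$batch_size` stack/target
#' pairs (with replacement) and one random co-located crop per pair. Inputs
#' and targets are mapped to \[-1, 1\]; the loss is computed in that space.
#' Everything (initialization, pair order, crops) derives from `cfg$seed`,
#' so identical configs give identical loss histories.
#'
#' @param dataset non-empty list of pairs, each `list(input = <zstack>,
#'   target = <edof_image or array>)`.
#' @param cfg a [fusion_net_config].
#' @param n_steps number of optimizer updates (0 returns the initialized
#'   parameters and an empty history).
#' @param params optional warm-start `cami_params` (resume training).
#' @param verbose print progress every 50 steps.
#' @return list with `params` (trained `cami_params`) and `history`
#'   (data frame: step, loss, and the three unweighted components).
#' @export
train_fusion_net <- function(dataset, cfg = fusion_net_config(), n_steps,
                             params = NULL, verbose = FALSE) {
  if (length(dataset) == 0L) stop("empty training dataset")
  if (is.null(params)) params <- init_params(cfg)
  ps <- cfg$patch_size
  lam <- cfg$loss_weights
  if (n_steps == 0L)
    return(list(params = params,
                history = data.frame(step = integer(), loss = numeric(),
                                     mae = numeric(), ssim = numeric(),
                                     fft = numeric())))
  adam <- adam_state(params$weights)
  history <- matrix(NA_real_, n_steps, 4L)
  set.seed(cfg$seed + 1L)
  for (step in seq_len(n_steps)) {
    idx <- sample.int(length(dataset), cfg$batch_size, replace = TRUE)
    grads_acc <- NULL
    loss_acc <- c(0, 0, 0, 0)
    for (b in seq_along(idx)) {
      pair <- dataset[[idx[b]]]
      tgt <- if (inherits(pair$target, "edof_image")) pair$target$image else pair$target
      d <- dim(tgt)
      r0 <- sample.int(d[1L] - ps + 1L, 1L); c0 <- sample.int(d[2L] - ps + 1L, 1L)
      rr <- r0:(r0 + ps - 1L); cc <- c0:(c0 + ps - 1L)
      hi <- range_max(pair$input$range)
      planes <- lapply(pair$input$planes, function(p)
        mat_from_img(2 * (p[rr, cc, , drop = FALSE] / hi) - 1))
      target <- 2 * tgt[rr, cc, , drop = FALSE] - 1
      fw <- cami_forward_mat(planes, ps, ps, params, keep_cache = TRUE)
      out_img <- img_from_mat(fw$out, ps, ps)
      lg <- combined_loss_grad(out_img, target, lam)
      if (!is.finite(lg$loss)) stop("non-finite loss at step ", step,
                                    " (components: ", paste(signif(lg$components, 4), collapse = ", "), ")")
      dOut <- mat_from_img(lg$grad) / length(idx)
      g <- cami_backward_mat(fw, params, dOut)
      grads_acc <- if (is.null(grads_acc)) g else {
        for (nm in names(g)) grads_acc[[nm]] <- grads_acc[[nm]] + g[[nm]]
        grads_acc
      }
      loss_acc <- loss_acc + c(lg$loss, lg$components) / length(idx)
    }
    params$weights <- adam_update(adam, params$weights, grads_acc, cfg$learning_rate)
    history[step, ] <- loss_acc
    if (verbose && (step %% 50L == 0L || step == 1L))
      message(sprintf("step %4d  loss %.5f", step, loss_acc[1L]))
  }
  history <- data.frame(step = seq_len(n_steps), loss = history[, 1L],
                        mae = history[, 2L], ssim = history[, 3L],
                        fft = history[, 4L])
  list(params = params, history = history)
}

# Adam optimizer state as an environment (m, v, t).
adam_state <- function(weights) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(weights, function(w) w * 0)
  st$v <- lapply(weights, function(w) w * 0)
  st$t <- 0L
  st
}

adam_update <- function(st, weights, grads, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (nm in names(weights)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    weights[[nm]] <- weights[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  weights
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding the parameters, their
#' config (including the seed) and the training history.
#'
#' @param params a `cami_params` object.
#' @param path file path (conventionally `.rds`).
#' @param history optional loss history to store alongside.
#' @return `path` invisibly ([save_checkpoint()]); a list with `params` and
#'   `history` ([load_checkpoint()]).
#' @export
save_checkpoint <- function(params, path, history = NULL) {
  saveRDS(list(params = params, history = history), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
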