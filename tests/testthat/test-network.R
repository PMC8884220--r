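small_cfg <- function(...) {
  fusion_net_config(NL = 2L, Ed = 8L, n_res_blocks = 2L, patch_size = 32L,
                    seed = 7L, ...)
}

test_that("encoder output follows the W/2^NL x H/2^NL x Ed size formula", {
  cfg <- small_cfg()
  params <- init_params(cfg)
  f <- encode(rand_image(64, seed = 120, lo = -1, hi = 1), params)
  expect_equal(dim(f), c(16L, 16L, 8L))

  cfg3 <- fusion_net_config(NL = 3L, Ed = 8L, n_res_blocks = 1L,
                            patch_size = 64L, seed = 7L)
  f3 <- encode(rand_image(64, seed = 121, lo = -1, hi = 1), init_params(cfg3))
  expect_equal(dim(f3), c(8L, 8L, 8L))

  expect_error(encode(rand_image(63, seed = 122), params), "divisible")
})

test_that("residual blocks are shape-preserving and identity at zero weights", {
  cfg <- small_cfg()
  params <- init_params(cfg)
  feats <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  out <- residual_transform(feats, params)
  expect_equal(dim(out), dim(feats))

  zero <- params
  for (nm in grep("^res", names(zero$weights), value = TRUE))
    zero$weights[[nm]] <- zero$weights[[nm]] * 0
  expect_equal(residual_transform(feats, zero), feats, tolerance = 1e-12)
})

test_that("max fusion: identity for D=1, commutative, dominance", {
  a <- array(0, c(4, 4, 2)); b <- array(1, c(4, 4, 2))
  expect_identical(fuse_max(list(a)), a)
  expect_equal(fuse_max(list(a, b)), b)
  set.seed(123)
  ts <- lapply(1:4, function(i) array(rnorm(32), c(4, 4, 2)))
  expect_identical(fuse_max(ts), fuse_max(ts[c(3, 1, 4, 2)]))
  expect_error(fuse_max(list(a, array(0, c(2, 2, 2)))), "congruent")
})

test_that("decoder inverts the spatial reduction and stays inside (-1, 1)", {
  cfg <- small_cfg()
  params <- init_params(cfg)
  feats <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  img <- decode(feats, params)
  expect_equal(dim(img), c(64L, 64L, 3L))
  expect_true(all(img > -1 & img < 1))

  zero <- params
  for (nm in grep("^dec", names(zero$weights), value = TRUE))
    zero$weights[[nm]] <- zero$weights[[nm]] * 0
  expect_equal(as.vector(decode(feats, zero)), rep(0, 64 * 64 * 3))
})

test_that("full forward: shapes, plane-permutation invariance, any D", {
  cfg <- small_cfg()
  params <- init_params(cfg)
  s3 <- rand_stack(3, h = 32, seed = 130)
  out <- cami_fuse(s3, params)
  expect_s3_class(out, "edof_image")
  expect_equal(out$method, "cami")
  expect_equal(dim(out$image), c(32L, 32L, 3L))
  expect_true(all(out$image >= 0 & out$image <= 1))

  perm <- zstack(s3$planes[c(2, 3, 1)], axial_step = s3$axial_step)
  expect_identical(cami_fuse(perm, params)$image, out$image)

  # single-plane stack works (autoencoder limit); 7 planes too, same params
  expect_equal(dim(cami_fuse(rand_stack(1, h = 32, seed = 131), params)$image),
               c(32L, 32L, 3L))
  expect_equal(dim(cami_fuse(rand_stack(7, h = 32, seed = 132), params)$image),
               c(32L, 32L, 3L))
})

test_that("parameter count is independent of the number of planes", {
  cfg <- small_cfg()
  params <- init_params(cfg)
  n0 <- n_parameters(params)
  for (d in c(1, 3, 14)) {
    cami_fuse(rand_stack(d, h = 32, seed = 140 + d), params)
    expect_equal(n_parameters(params), n0)
  }
})

test_that("network backprop matches finite-difference gradients", {
  ns <- asNamespace("stackfuse")
  cfg <- fusion_net_config(NL = 2L, Ed = 8L, n_res_blocks = 2L,
                           patch_size = 16L, seed = 3L)
  params <- init_params(cfg)
  set.seed(150)
  h <- 16L
  planes <- lapply(1:2, function(i) matrix(stats::runif(h * h * 3, -1, 1), h * h, 3))
  target <- array(stats::runif(h * h * 3, -1, 1), c(h, h, 3))
  lam <- cfg$loss_weights
  loss_of <- function(p) {
    fw <- ns$cami_forward_mat(planes, h, h, p)
    ns$combined_loss_grad(ns$img_from_mat(fw$out, h, h), target, lam)$loss
  }
  fw <- ns$cami_forward_mat(planes, h, h, params, keep_cache = TRUE)
  lg <- ns$combined_loss_grad(ns$img_from_mat(fw$out, h, h), target, lam)
  grads <- ns$cami_backward_mat(fw, params, ns$mat_from_img(lg$grad))
  eps <- 1e-5
  for (nm in c("enc1_W", "res2_1_W", "dec1_W", "dec2_W", "enc2_b")) {
    w <- params$weights[[nm]]
    for (i in sample(length(w), 2)) {
      pp <- params; pp$weights[[nm]][i] <- w[i] + eps
      pm <- params; pm$weights[[nm]][i] <- w[i] - eps
      num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-3)
    }
  }
})

test_that("patch sampling is seeded, in bounds, and exhaustive at full size", {
  s <- rand_stack(3, h = 48, seed = 160)
  tgt <- rand_image(48, seed = 161)
  pair <- list(input = s, target = tgt)
  p1 <- sample_patches(pair, 32, 10, seed = 5)
  p2 <- sample_patches(pair, 32, 10, seed = 5)
  expect_identical(vapply(p1, `[[`, numeric(1), "row"),
                   vapply(p2, `[[`, numeric(1), "row"))
  for (p in p1) {
    expect_true(p$row >= 1 && p$row + 31 <= 48)
    expect_true(p$col >= 1 && p$col + 31 <= 48)
    expect_equal(dim(p$target), c(32L, 32L, 3L))
    expect_length(p$planes, 3L)
    # co-located crops
    expect_equal(p$planes[[2]],
                 s$planes[[2]][p$row:(p$row + 31), p$col:(p$col + 31), , drop = FALSE])
  }
  # patch equal to the image size admits a single crop
  pf <- sample_patches(pair, 48, 3, seed = 6)
  expect_true(all(vapply(pf, `[[`, numeric(1), "row") == 1))
  expect_error(sample_patches(pair, 64, 1, seed = 1), "smaller")
})

test_that("training reduces the loss and is reproducible; 0 steps is a no-op", {
  set.seed(170)
  # tiny deblurring task: targets sharp, inputs blurred two-plane stacks
  dataset <- lapply(1:6, function(i) {
    ref <- generate_scene(seed = 500 + i, field_size = 64)$reference
    planes <- list(gaussian_blur(ref, 1.0), gaussian_blur(ref, 2.0))
    list(input = zstack(planes, axial_step = 1), target = ref)
  })
  cfg <- fusion_net_config(NL = 2L, Ed = 8L, n_res_blocks = 2L,
                           patch_size = 32L, learning_rate = 1e-3,
                           batch_size = 2L, seed = 9L)
  fit0 <- train_fusion_net(dataset, cfg, n_steps = 0)
  expect_equal(nrow(fit0$history), 0L)
  expect_equal(fit0$params$weights, init_params(cfg)$weights)

  fit <- train_fusion_net(dataset, cfg, n_steps = 60)
  expect_equal(nrow(fit$history), 60L)
  expect_lt(mean(fit$history$loss[51:60]), mean(fit$history$loss[1:10]))

  fit2 <- train_fusion_net(dataset, cfg, n_steps = 60)
  expect_identical(fit$history$loss, fit2$history$loss)

  expect_error(train_fusion_net(list(), cfg, 10), "empty")
})

test_that("checkpoints round-trip parameters and history", {
  cfg <- small_cfg()
  params <- init_params(cfg)
  path <- file.path(tempdir(), "ckpt.rds")
  h <- data.frame(step = 1:3, loss = c(3, 2, 1))
  save_checkpoint(params, path, history = h)
  back <- load_checkpoint(path)
  expect_equal(back$params$weights, params$weights)
  expect_equal(back$history, h)
})
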