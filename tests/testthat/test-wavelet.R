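test_that("decompose/reconstruct is a perfect-reconstruction transform", {
  for (wname in c("haar", "db2", "db4", "sym4")) {
    cfg <- wavelet_fusion_config(wavelet_name = wname, levels = 3)
    x <- rand_image(40, 56, channels = 1, seed = 17)   # padding path
    expect_lt(max(abs(wavelet_reconstruct(wavelet_decompose(x, cfg)) - x)),
              1e-8)
  }
  # structure: one detail triple per level plus one approximation
  cfg1 <- wavelet_fusion_config(levels = 1)
  p <- wavelet_decompose(rand_image(32, channels = 1, seed = 1), cfg1)
  expect_length(p$details, 1L)
  expect_named(p$details[[1]], c("lh", "hl", "hh"))
  expect_equal(dim(p$approx), c(16L, 16L))
})

test_that("constant images have vanishing detail coefficients", {
  cfg <- wavelet_fusion_config(levels = 3)
  p <- wavelet_decompose(matrix(0.37, 32, 32), cfg)
  expect_lt(max(abs(unlist(p$details))), 1e-10)
})

test_that("images too small for the level count are refused", {
  cfg <- wavelet_fusion_config(levels = 5)
  expect_error(wavelet_decompose(matrix(0, 16, 16), cfg), "too small")
})

test_that("coefficient selection matches a brute-force argmax oracle", {
  cfg <- wavelet_fusion_config(levels = 3, selection = "max_abs",
                               consistency_radius = 0)
  pyrs <- lapply(1:2, function(i)
    wavelet_decompose(rand_image(64, channels = 1, seed = 20 + i), cfg))
  sel <- select_coefficients(pyrs, cfg)
  for (lev in 1:3) for (band in c("lh", "hl", "hh")) {
    a <- pyrs[[1]]$details[[lev]][[band]]
    b <- pyrs[[2]]$details[[lev]][[band]]
    # brute force: per coefficient, keep the larger |.|, ties -> plane 1
    oracle <- ifelse(abs(b) > abs(a), b, a)
    expect_equal(sel$fused$details[[lev]][[band]], oracle, tolerance = 1e-14)
    expect_true(all(sel$maps[[lev]][[band]] %in% 1:2))
  }
  expect_equal(sel$fused$approx, (pyrs[[1]]$approx + pyrs[[2]]$approx) / 2)

  # local-energy selection on a 2-plane toy: verify against direct box-sum
  cfg_e <- wavelet_fusion_config(levels = 2, selection = "max_local_energy",
                                 consistency_radius = 0)
  pyrs_e <- lapply(1:2, function(i)
    wavelet_decompose(rand_image(32, channels = 1, seed = 30 + i), cfg_e))
  sel_e <- select_coefficients(pyrs_e, cfg_e)
  box3 <- function(m) {
    p <- matrix(0, nrow(m) + 2, ncol(m) + 2)
    p[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
      out[i, j] <- sum(p[i:(i + 2), j:(j + 2)])
    out
  }
  for (band in c("lh", "hh")) {
    e1 <- box3(pyrs_e[[1]]$details[[1]][[band]]^2)
    e2 <- box3(pyrs_e[[2]]$details[[1]][[band]]^2)
    oracle_map <- ifelse(e2 > e1, 2L, 1L)
    expect_equal(sel_e$maps[[1]][[band]], oracle_map)
  }
})

test_that("selection degeneracies: identical and zero pyramids", {
  cfg <- wavelet_fusion_config(levels = 2, consistency_radius = 0)
  p <- wavelet_decompose(rand_image(32, channels = 1, seed = 40), cfg)
  sel <- select_coefficients(list(p, p, p), cfg)
  expect_equal(sel$fused$approx, p$approx)
  for (lev in 1:2)
    expect_equal(sel$fused$details[[lev]], p$details[[lev]])
  # all selections go to plane 1 on ties
  expect_true(all(unlist(sel$maps) == 1L))

  zero <- wavelet_decompose(matrix(0, 32, 32), cfg)
  sel2 <- select_coefficients(list(zero, p), cfg)
  for (lev in 1:2)
    expect_equal(sel2$fused$details[[lev]], p$details[[lev]], tolerance = 1e-10)
  expect_error(select_coefficients(list(p, wavelet_decompose(matrix(0, 64, 64), cfg)), cfg),
               "congruent")
})

test_that("consistency filter removes isolated dissent and respects ties", {
  m <- matrix(1L, 9, 9)
  expect_identical(consistency_filter(m, 2L), m)        # uniform unchanged
  m2 <- m; m2[5, 5] <- 2L
  expect_identical(consistency_filter(m2, 1L), m)       # dissent removed
  expect_identical(consistency_filter(m2, 0L), m2)      # radius 0 = identity
  # exact tie in the window keeps the original value: every 3x3 window of a
  # 2x2 checkerboard sees two of each plane index
  m3 <- matrix(c(1L, 2L, 2L, 1L), 2, 2)
  expect_identical(consistency_filter(m3, 1L), m3)
})

test_that("wavelet fusion degeneracies: identical planes and single plane", {
  plane <- rand_image(48, seed = 50)
  s <- const_stack(plane, 4)
  fused <- fuse_stack_wavelet(s)
  expect_s3_class(fused, "edof_image")
  expect_equal(fused$method, "wavelet")
  expect_equal(fused$source_planes, 4L)
  expect_lt(max(abs(fused$image - plane)), 1e-6)

  s1 <- zstack(list(plane), axial_step = 0.5)
  expect_lt(max(abs(fuse_stack_wavelet(s1)$image - plane)), 1e-6)
})

test_that("fusing a half-sharp pair raises gradient energy above both inputs", {
  s <- half_sharp_pair(64)
  fused <- fuse_stack_wavelet(s)
  ge <- gradient_energy(fused$image)
  expect_gte(ge, gradient_energy(s$planes[[1]]))
  expect_gte(ge, gradient_energy(s$planes[[2]]))
})

test_that("fusion is invariant to plane order (up to argmax ties)", {
  set.seed(60)
  planes <- lapply(1:3, function(i) gaussian_blur(rand_image(32, seed = 60 + i),
                                                  sigma = c(0, 1, 2)[i]))
  s <- zstack(planes, axial_step = 0.5)
  f1 <- fuse_stack_wavelet(s)
  f2 <- fuse_stack_wavelet(zstack(planes[c(3, 1, 2)], axial_step = 0.5))
  expect_equal(f1$image, f2$image, tolerance = 1e-10)
})

test_that("recovering an all-in-focus plane from its blurred copies", {
  ref <- rand_image(64, seed = 70)
  s <- zstack(list(gaussian_blur(ref, 2), ref, gaussian_blur(ref, 1.2)),
              axial_step = 0.5)
  fused <- fuse_stack_wavelet(s)
  ge_ref <- gradient_energy(ref)
  expect_lt(abs(gradient_energy(fused$image) - ge_ref) / ge_ref, 0.05)
})
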