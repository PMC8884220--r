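test_that("scene generation is deterministic and respects object counts", {
  s1 <- generate_scene(seed = 42)
  s2 <- generate_scene(seed = 42)
  expect_identical(s1$reference, s2$reference)
  expect_identical(s1$spec$objects, s2$spec$objects)

  # no objects -> uniform background
  s0 <- generate_scene(n_objects = c(erythrocyte = 0), seed = 1)
  for (ch in 1:3)
    expect_equal(stats::sd(s0$reference[, , ch]), 0)

  n <- vapply(s1$spec$objects, `[[`, character(1), "class")
  expect_equal(sum(n == "erythrocyte"), 6)
  expect_equal(sum(n == "parasite"), 2)
  # all depths inside the slab
  z <- vapply(s1$spec$objects, `[[`, numeric(1), "depth_z")
  expect_true(all(z >= 0 & z <= s1$spec$sample_thickness))
})

test_that("object radii match the stated physical sizes", {
  s <- generate_scene(n_objects = c(erythrocyte = 5, parasite = 5),
                      seed = 3, pixel_size = 0.13, field_size = 256)
  for (obj in s$spec$objects) {
    r_um <- obj$radius * 0.13
    if (obj$class == "erythrocyte") expect_true(r_um >= 3.5 && r_um <= 4.0)
    if (obj$class == "parasite") expect_true(r_um >= 1.0 && r_um <= 1.5)
  }
})

test_that("rendered stacks are deterministic and geometrically labelled", {
  sc <- generate_scene(seed = 7)
  r1 <- render_stack(sc$spec, n_planes = 5, seed = 8)
  r2 <- render_stack(sc$spec, n_planes = 5, seed = 8)
  expect_identical(r1$stack$planes, r2$stack$planes)
  expect_equal(n_planes(r1$stack), 5L)
  # 14 planes at 0.5 um: total depth 6.5 um
  r14 <- render_stack(sc$spec, n_planes = 14, axial_step = 0.5,
                      noise_sigma = 0, seed = 9)
  expect_equal(axial_extent(r14$stack), 6.5)
})

test_that("defocus blur is monotone: objects are sharpest at the nearest plane", {
  hits <- 0
  n_scenes <- 12
  for (i in seq_len(n_scenes)) {
    sc <- generate_scene(n_objects = c(erythrocyte = 1), seed = 600 + i,
                         field_size = 96)
    rs <- render_stack(sc$spec, n_planes = 7, axial_step = 0.5,
                       noise_sigma = 0.01, seed = 700 + i)
    depth <- sc$spec$objects[[1]]$depth_z
    nearest <- which.min(abs((0:6) * 0.5 - depth))
    ge <- vapply(rs$stack$planes, gradient_energy, numeric(1))
    if (which.max(ge) == nearest) hits <- hits + 1
    # noise-free rendering: per-object Laplacian sharpness is unimodal,
    # non-increasing with axial distance from the in-focus plane
    rs0 <- render_stack(sc$spec, n_planes = 7, axial_step = 0.5,
                        noise_sigma = 0, seed = 700 + i)
    obj <- sc$spec$objects[[1]]
    rows <- round(obj$center_xy[2] + seq(-obj$radius, obj$radius))
    cols <- round(obj$center_xy[1] + seq(-obj$radius, obj$radius))
    le <- vapply(rs0$stack$planes, laplacian_energy, numeric(1),
                 rows = rows, cols = cols)
    peak <- which.max(le)
    tol <- 1e-3 * le[peak]
    if (peak > 2) expect_true(all(diff(le[1:(peak - 1)]) > -tol))
    if (peak < 6) expect_true(all(diff(le[(peak + 1):7]) < tol))
  }
  expect_gte(hits, n_scenes - 1)
})

test_that("the wavelet EDoF of a full noise-free stack beats every single plane", {
  # focus-fusion property, isolated from sensor noise
  for (i in 1:3) {
    sc <- generate_scene(seed = 800 + i)
    rs <- render_stack(sc$spec, n_planes = 7, noise_sigma = 0, seed = 900 + i)
    fused <- fuse_stack_wavelet(rs$stack)
    s_fused <- ssim(fused$image, rs$reference)
    s_planes <- vapply(rs$stack$planes, function(p) ssim(p, rs$reference),
                       numeric(1))
    expect_gt(s_fused, max(s_planes))
  }
})

test_that("make_dataset builds reproducible decimated triplets", {
  cfgs <- stack_config(field_size = 64, n_planes = 7,
                       n_objects = c(erythrocyte = 2, parasite = 1))
  d1 <- make_dataset(2, cfgs, decimation_factor = 2, seed = 5)
  d2 <- make_dataset(2, cfgs, decimation_factor = 2, seed = 5)
  expect_identical(d1[[1]]$input$planes, d2[[1]]$input$planes)
  expect_identical(d1[[2]]$target$image, d2[[2]]$target$image)

  expect_equal(n_planes(d1[[1]]$full), 7L)
  expect_equal(n_planes(d1[[1]]$input), 3L)     # 7 planes decimated by 2
  expect_equal(d1[[1]]$input$axial_step, 1.0)
  expect_equal(d1[[1]]$target$method, "wavelet")
  expect_equal(d1[[1]]$target$source_planes, 7L)

  # k = 1 keeps the full stack (upper-bound sanity dataset)
  d3 <- make_dataset(1, cfgs, decimation_factor = 1, seed = 5)
  expect_identical(d3[[1]]$input$planes, d3[[1]]$full$planes)
})
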