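test_that("multi-page TIFF round trip is bit-exact for byte stacks", {
  set.seed(10)
  planes <- lapply(1:5, function(i)
    array(sample(0:255, 24 * 20 * 3, replace = TRUE), c(24, 20, 3)))
  s <- zstack(planes, axial_step = 0.5, range = "byte")
  path <- file.path(tempdir(), "roundtrip.tiff")
  write_stack(s, path)
  r <- read_stack(path)
  expect_equal(n_planes(r), 5L)
  expect_equal(r$axial_step, 0.5)
  expect_identical(r$range, "byte")
  for (i in 1:5) expect_equal(r$planes[[i]], planes[[i]])

  s1 <- zstack(planes[1], axial_step = 1.0, range = "byte")
  write_stack(s1, path)
  expect_equal(n_planes(read_stack(path)), 1L)
})

test_that("degenerate and invalid stacks are rejected at construction", {
  p <- rand_image(16)
  expect_error(zstack(list(), 0.5), "non-empty")
  expect_error(zstack(list(p, rand_image(8)), 0.5), "identical dimensions")
  expect_error(zstack(list(p), -1), "positive")
  expect_error(write_stack(structure(list(planes = list()), class = "zstack"),
                           tempfile()), "refusing")
})

test_that("white balance follows the mean-normalized flat-field formula", {
  set.seed(2)
  plane <- rand_image(16, seed = 2, lo = 0.1, hi = 0.9)
  # uniform reference (any per-channel constant) is the identity
  ref_u <- array(rep(c(0.7, 0.5, 0.9), each = 256), c(16, 16, 3))
  expect_equal(white_balance(plane, ref_u), plane, tolerance = 1e-12)

  # plane == reference -> per-channel constant equal to the channel mean
  ref <- rand_image(16, seed = 3, lo = 0.2, hi = 0.8)
  out <- white_balance(ref, ref)
  for (ch in 1:3)
    expect_equal(as.vector(out[, , ch]), rep(mean(ref[, , ch]), 256),
                 tolerance = 1e-12)

  # scaling one reference channel x2 halves that channel of the output
  # (before the mean renormalization, which is unchanged by scaling)
  ref2 <- ref; ref2[, , 2] <- pmin(1, 2 * ref[, , 2])
  out_base <- white_balance(plane, ref)
  out_scaled <- white_balance(plane, ref2)
  expect_equal(out_scaled[, , 1], out_base[, , 1], tolerance = 1e-12)
  expect_equal(out_scaled[, , 3], out_base[, , 3], tolerance = 1e-12)

  expect_error(white_balance(plane, rand_image(8)), "identical dimensions")
  expect_warning(white_balance(plane, array(0, dim(plane))), "near-zero")
})

test_that("decimation reproduces the printed plane-count triplet", {
  s14 <- rand_stack(14, h = 16, axial_step = 0.5)
  d2 <- decimate_stack(s14, 2)
  expect_equal(n_planes(d2), 7L)
  expect_equal(d2$axial_step, 1.0)
  d4 <- decimate_stack(s14, 4)
  expect_equal(n_planes(d4), 3L)
  expect_equal(d4$axial_step, 2.0)
  s7 <- rand_stack(7, h = 16, axial_step = 0.5)
  expect_equal(n_planes(decimate_stack(s7, 2)), 3L)
  # retained planes are the k-th, 2k-th, ...
  expect_identical(d2$planes, s14$planes[c(2, 4, 6, 8, 10, 12, 14)])
  # identity decimation
  expect_identical(decimate_stack(s7, 1), s7)
  expect_error(decimate_stack(s7, 8), "exceeds")
})

test_that("a 14-plane stack at 0.5 um spans 6.5 um", {
  expect_equal(axial_extent(rand_stack(14, h = 8, axial_step = 0.5)), 6.5)
})

test_that("network normalization maps range endpoints and inverts exactly", {
  z <- zstack(list(array(0, c(8, 8, 3)), array(255, c(8, 8, 3)),
                   array(127.5, c(8, 8, 3))),
              axial_step = 0.5, range = "byte")
  n <- normalize_for_network(z)
  expect_equal(unique(as.vector(n$planes[[1]])), -1)
  expect_equal(unique(as.vector(n$planes[[2]])), 1)
  expect_equal(unique(as.vector(n$planes[[3]])), 0)
  s <- rand_stack(3, h = 12, seed = 5)
  ns <- normalize_for_network(s)
  for (i in 1:3)
    expect_equal(denormalize_image(ns$planes[[i]], ns$meta$norm),
                 s$planes[[i]], tolerance = 1e-6)
})

test_that("acquisition geometry formulas match their definitions", {
  g <- acquisition_geometry(wavelength = 0.53, na = 1.4, sample_thickness = 3.5)
  expect_equal(depth_of_field(g), 0.53 / 1.4^2, tolerance = 1e-12)
  expect_equal(depth_of_field(g), 0.2704, tolerance = 1e-4)
  expect_equal(depth_of_field(acquisition_geometry(1, 1, 1)), 1)
  g2 <- acquisition_geometry(0.53, 0.7, 3.5)
  expect_equal(depth_of_field(g), depth_of_field(g2) / 4)

  # 3.5 um slab at 100x/1.4NA green light: ceil(6.47) = 7 planes
  expect_equal(required_planes(g), 7L)
  # slab of exactly two DoF thicknesses needs one plane
  g1 <- acquisition_geometry(0.5, 1.0, 2 * 0.5 / 1.0^2)
  expect_equal(required_planes(g1), 1L)
  # Np is linear in St before the ceiling
  g3 <- acquisition_geometry(0.53, 1.4, 7.0)
  expect_equal(7.0 * 1.4^2 / (2 * 0.53), 2 * (3.5 * 1.4^2 / (2 * 0.53)))
  expect_equal(required_planes(g3), 13L)
})
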