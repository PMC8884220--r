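# Synthetic thin-blood-film z-stacks with a known all-in-focus reference.
#
# Scenes emulate stained blood films under a high-NA oil objective: sparse
# quasi-circular erythrocytes (pale annuli with central pallor, ~7-8 um
# diameter), small dark-violet ring-stage parasites (~2-3 um), textured
# lobed leukocytes and occasional dark dust specks, each lying at a random
# depth inside a slab a few micrometres thick. Focal planes are rendered
# with a depth-dependent Gaussian defocus blur; the paired reference renders
# every object at the in-focus blur. Everything is seeded and bit-exactly
# reproducible.

#' Depth-dependent defocus blur model
#'
#' Gaussian blur whose width grows linearly with axial defocus:
#' `sigma(dz) = sigma0 + slope * |dz|` pixels. A phenomenological stand-in
#' for the optical defocus PSF: it reproduces the sharp-at-focus /
#' blurred-away-from-focus structure the fusion exploits, not diffraction
#' detail.
#'
#' @param dof nominal depth of field, micrometres (informational).
#' @param sigma0 in-focus blur, pixels (default 0.8).
#' @param slope blur growth, pixels per micrometre of defocus (default 1.5).
#' @return An object of class `psf_model`.
#' @export
psf_model <- function(dof = 0.27, sigma0 = 0.8, slope = 1.5) {
  stopifnot(sigma0 >= 0, slope >= 0)
  structure(list(dof = dof, sigma0 = sigma0, slope = slope),
            class = "psf_model")
}

#' @export
print.psf_model <- function(x, ...) {
  cat(sprintf("psf_model: sigma(dz) = %.2f + %.2f * |dz| px (dz in um)\n",
              x$sigma0, x$slope))
  invisible(x)
}

psf_sigma <- function(psf, dz) psf$sigma0 + psf$slope * abs(dz)

# class palettes: list(color, radius range in um)
SCENE_CLASSES <- list(
  erythrocyte = list(color = c(0.86, 0.60, 0.58), radius_um = c(3.5, 4.0)),
  parasite    = list(color = c(0.42, 0.26, 0.52), radius_um = c(1.0, 1.5)),
  leukocyte   = list(color = c(0.55, 0.40, 0.65), radius_um = c(4.5, 6.0)),
  dust        = list(color = c(0.18, 0.16, 0.15), radius_um = c(0.4, 0.9))
)

#' Generate a synthetic blood-film scene
#'
#' Places the requested number of objects of each class at uniform random
#' positions and depths within the slab, then renders the all-in-focus
#' reference image (every object at the in-focus blur `sigma0`).
#'
#' @param n_objects named counts per class, e.g.
#'   `c(erythrocyte = 6, parasite = 2, leukocyte = 1, dust = 1)`.
#' @param field_size image side length in pixels (square field, >= 64).
#' @param sample_thickness slab thickness St in micrometres; object depths
#'   are uniform on \[0, St\].
#' @param pixel_size lateral sampling, micrometres per pixel. Object radii in
#'   pixels are their physical radii divided by this.
#' @param seed RNG seed; the same seed yields a bit-identical scene.
#' @param psf a [psf_model] used for the reference rendering.
#' @param background_color background RGB triplet.
#' @return list with `spec` (a `scene_spec`: object table plus field
#'   parameters) and `reference` (`H x W x 3` array in \[0, 1\]).
#' @export
generate_scene <- function(n_objects = c(erythrocyte = 6, parasite = 2,
                                         leukocyte = 1, dust = 1),
                           field_size = 128L, sample_thickness = 3.0,
                           pixel_size = 0.13, seed = 1L,
                           psf = psf_model(),
                           background_color = c(0.93, 0.91, 0.95)) {
  stopifnot(field_size >= 64L, sample_thickness > 0)
  set.seed(seed)
  objs <- list()
  margin_frac <- 0.08
  for (cls in names(n_objects)) {
    info <- SCENE_CLASSES[[cls]]
    if (is.null(info)) stop("unknown object class '", cls, "'")
    n <- n_objects[[cls]]
    if (n <= 0) next
    for (i in seq_len(n)) {
      radius_px <- stats::runif(1, info$radius_um[1L], info$radius_um[2L]) / pixel_size
      max_r <- field_size * 0.2
      if (radius_px > max_r) radius_px <- max_r   # packing guard for tiny fields
      lo <- max(field_size * margin_frac, radius_px)
      if (lo >= field_size - lo) lo <- 1
      objs[[length(objs) + 1L]] <- list(
        class = cls,
        center_xy = stats::runif(2, lo, field_size - lo),
        depth_z = stats::runif(1, 0, sample_thickness),
        radius = radius_px,
        color = info$color,
        texture_seed = sample.int(1e6, 1))
    }
  }
  spec <- structure(list(objects = objs, field_size = as.integer(field_size),
                         sample_thickness = sample_thickness,
                         pixel_size = pixel_size, seed = as.integer(seed),
                         background_color = background_color),
                    class = "scene_spec")
  list(spec = spec, reference = render_plane(spec, z = NULL, psf = psf))
}

# Render one object's sprite: local color image and opacity mask on a window.
# Returns list(rows, cols, color (nr x nc x 3), alpha (nr x nc)).
object_sprite <- function(obj, field_size) {
  r <- obj$radius
  pad <- ceiling(r + 2)
  cx <- obj$center_xy[1L]; cy <- obj$center_xy[2L]
  rows <- max(1L, floor(cy - pad)):min(field_size, ceiling(cy + pad))
  cols <- max(1L, floor(cx - pad)):min(field_size, ceiling(cx + pad))
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  dist <- sqrt(dx^2 + dy^2)
  u <- dist / r                                # normalized radius
  edge <- function(x, width = 0.08) {
    v <- pmin(1, pmax(0, (1 - x) / width)); dim(v) <- dim(x); v
  }
  col <- array(0, c(length(rows), length(cols), 3L))
  set.seed(obj$texture_seed)
  if (obj$class == "erythrocyte") {
    alpha <- edge(u)
    # biconcave look: densest in an annulus, central pallor
    profile <- 0.35 + 0.65 * exp(-((u - 0.72) / 0.28)^2)
    for (ch in 1:3) {
      base <- obj$color[ch]
      col[, , ch] <- 1 - (1 - base) * profile
    }
  } else if (obj$class == "parasite") {
    # dark-violet ring with a chromatin dot
    ring <- exp(-((u - 0.65) / 0.25)^2)
    th <- stats::runif(1, 0, 2 * pi)
    dot_c <- 0.65 * r * c(cos(th), sin(th))
    dot <- exp(-(((dx - dot_c[1L])^2 + (dy - dot_c[2L])^2) / (0.18 * r)^2))
    w <- pmin(1, ring + 1.6 * dot); dim(w) <- dim(u)
    alpha <- edge(u, 0.15) * w
    for (ch in 1:3) col[, , ch] <- obj$color[ch]
  } else if (obj$class == "leukocyte") {
    # lobed boundary + granular nucleus texture
    nlobe <- sample(2:4, 1)
    phase <- stats::runif(1, 0, 2 * pi)
    ang <- atan2(dy, dx)
    rmod <- 1 + 0.18 * cos(nlobe * ang + phase)
    alpha <- edge(dist / (r * rmod))
    tex <- matrix(stats::runif(length(rows) * length(cols)), length(rows))
    tex <- sep_conv_same(tex, gaussian_kernel(1.2))
    tex <- 0.75 + 0.5 * (tex - mean(tex)) / (stats::sd(tex) + 1e-9)
    for (ch in 1:3) col[, , ch] <- pmin(1, pmax(0, obj$color[ch] * tex))
  } else {                                     # dust
    alpha <- edge(u, 0.3)
    for (ch in 1:3) col[, , ch] <- obj$color[ch]
  }
  list(rows = rows, cols = cols, color = col, alpha = alpha)
}

# Render one focal plane at axial position z (um); z = NULL renders the
# all-in-focus reference (all objects at sigma0).
render_plane <- function(spec, z, psf) {
  n <- spec$field_size
  img <- array(rep(spec$background_color, each = n * n), c(n, n, 3L))
  for (obj in spec$objects) {
    sp <- object_sprite(obj, n)
    sigma <- if (is.null(z)) psf$sigma0 else psf_sigma(psf, z - obj$depth_z)
    a <- sp$alpha
    ca <- sp$color * as.vector(a)               # premultiplied color
    if (sigma > 0.05) {
      k <- gaussian_kernel(sigma)
      a <- sep_conv_same(a, k)
      for (ch in 1:3) ca[, , ch] <- sep_conv_same(ca[, , ch], k)
    }
    for (ch in 1:3)
      img[sp$rows, sp$cols, ch] <- img[sp$rows, sp$cols, ch] * (1 - a) + ca[, , ch]
  }
  clip01(img)
}

#' Render a z-stack from a scene
#'
#' Plane `i` sits at axial position `(i - 1) * axial_step` micrometres; each
#' object is blurred with `sigma(|z_plane - depth_z|)` from the PSF model,
#' and optional additive Gaussian noise is applied per plane.
#'
#' @param scene a `scene_spec` from [generate_scene()].
#' @param psf a [psf_model].
#' @param n_planes number of focal planes (>= 1).
#' @param axial_step plane spacing, micrometres (default 0.5).
#' @param noise_sigma additive Gaussian noise SD as a fraction of full scale
#'   (default 0.01).
#' @param seed seed for the noise.
#' @return list with `stack` (a [zstack], unit range) and `reference`
#'   (all-in-focus `H x W x 3` array).
#' @export
render_stack <- function(scene, psf = psf_model(), n_planes = 7L,
                         axial_step = 0.5, noise_sigma = 0.01, seed = 1L) {
  stopifnot(inherits(scene, "scene_spec"), n_planes >= 1L)
  planes <- vector("list", n_planes)
  set.seed(seed)
  noise_seeds <- sample.int(.Machine$integer.max, n_planes)
  for (i in seq_len(n_planes)) {
    z <- (i - 1L) * axial_step
    p <- render_plane(scene, z, psf)
    if (noise_sigma > 0) {
      set.seed(noise_seeds[i])
      p <- clip01(p + array(stats::rnorm(length(p), sd = noise_sigma), dim(p)))
    }
    planes[[i]] <- p
  }
  list(stack = zstack(planes, axial_step = axial_step,
                      pixel_size = scene$pixel_size, range = "unit",
                      meta = list(scene_seed = scene$seed)),
       reference = render_plane(scene, z = NULL, psf = psf))
}

#' Default desk-scale stack configuration
#'
#' Conditions for a thin-film slab: 7 planes at a 0.5 um step covering a
#' 3 um slab, 128 px fields at 0.13 um/px (2x2-binned camera sampling), 1%
#' additive noise.
#'
#' @param field_size,n_planes,axial_step,sample_thickness,pixel_size,noise_sigma
#'   see [generate_scene()] and [render_stack()].
#' @param n_objects named object counts per field.
#' @return list of generator settings for [make_dataset()].
#' @export
stack_config <- function(field_size = 128L, n_planes = 7L, axial_step = 0.5,
                         sample_thickness = 3.0, pixel_size = 0.13,
                         noise_sigma = 0.01,
                         n_objects = c(erythrocyte = 6, parasite = 2,
                                       leukocyte = 1, dust = 1)) {
  list(field_size = as.integer(field_size), n_planes = as.integer(n_planes),
       axial_step = axial_step, sample_thickness = sample_thickness,
       pixel_size = pixel_size, noise_sigma = noise_sigma,
       n_objects = n_objects)
}

#' Build a training/evaluation dataset of fusion triplets
#'
#' For each stack: a scene is generated and fully rendered; the wavelet EDoF
#' target is computed from the full stack; the network input is the stack
#' decimated by `k`. Reproducible per seed.
#'
#' @param n_stacks number of stacks.
#' @param stack_cfg a [stack_config()] list.
#' @param decimation_factor integer k passed to [decimate_stack()] (1 keeps
#'   the full stack).
#' @param seed master seed; per-stack seeds derive from it.
#' @param psf a [psf_model].
#' @param wavelet_cfg a [wavelet_fusion_config] for the targets.
#' @return list of `n_stacks` triplets: `list(input = <decimated zstack>,
#'   target = <wavelet edof_image>, reference = <all-in-focus array>,
#'   full = <full zstack>)`.
#' @export
make_dataset <- function(n_stacks, stack_cfg = stack_config(),
                         decimation_factor = 2L, seed = 1L,
                         psf = psf_model(),
                         wavelet_cfg = wavelet_fusion_config()) {
  set.seed(seed)
  seeds <- sample.int(1e9, 2L * n_stacks)
  lapply(seq_len(n_stacks), function(i) {
    sc <- generate_scene(n_objects = stack_cfg$n_objects,
                         field_size = stack_cfg$field_size,
                         sample_thickness = stack_cfg$sample_thickness,
                         pixel_size = stack_cfg$pixel_size,
                         seed = seeds[2L * i - 1L], psf = psf)
    rs <- render_stack(sc$spec, psf = psf, n_planes = stack_cfg$n_planes,
                       axial_step = stack_cfg$axial_step,
                       noise_sigma = stack_cfg$noise_sigma,
                       seed = seeds[2L * i])
    target <- fuse_stack_wavelet(rs$stack, wavelet_cfg)
    list(input = decimate_stack(rs$stack, decimation_factor),
         target = target, reference = rs$reference, full = rs$stack)
  })
}
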