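# Classical multi-scale-decomposition (MSD) fusion: each focal plane is
# decomposed with a separable orthogonal discrete wavelet transform, detail
# coefficients are selected across planes by a sharpness criterion, and the
# fused pyramid is inverted to give the extended-depth-of-field image.
#
# The transform is periodized, so perfect reconstruction holds to machine
# precision for the orthonormal filter banks below. Images whose sides are
# not multiples of 2^levels are symmetrically padded and cropped back.

# Orthonormal analysis low-pass filters (decomposition). The high-pass is the
# quadrature mirror g[m] = (-1)^m h[L - 1 - m].
WAVELET_FILTERS <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2  = c(-0.12940952255126037, 0.2241438680420134,
           0.8365163037378079, 0.48296291314453416),
  db4  = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
           -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
           0.7148465705529157, 0.2303778133088965),
  sym4 = c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
           0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
           -0.012603967262037833, 0.0322231006040427)
)

wavelet_filters <- function(name) {
  h <- WAVELET_FILTERS[[name]]
  if (is.null(h)) stop("unknown wavelet '", name, "'; available: ",
                       paste(names(WAVELET_FILTERS), collapse = ", "))
  m <- seq_along(h) - 1L
  list(lo = h, hi = rev(h) * (-1)^m)
}

#' Configuration of the wavelet EDoF fusion
#'
#' @param wavelet_name filter family: `"sym4"` (default; near-symmetric
#'   orthogonal, 4 vanishing moments), `"db4"`, `"db2"` or `"haar"`.
#' @param levels decomposition depth (>= 1).
#' @param selection coefficient-selection rule across planes:
#'   `"max_local_energy"` (3x3-window energy, default) or `"max_abs"`.
#' @param consistency_radius majority-filter window radius applied to the
#'   plane-selection maps (0 disables; at most 5).
#' @param color_mode `"luminance_guided"` (select on luminance, apply the
#'   same maps to all channels; default) or `"per_channel"`.
#' @return An object of class `wavelet_fusion_config`.
#' @export
wavelet_fusion_config <- function(wavelet_name = "sym4", levels = 4L,
                                  selection = c("max_local_energy", "max_abs"),
                                  consistency_radius = 1L,
                                  color_mode = c("luminance_guided", "per_channel")) {
  selection <- match.arg(selection)
  color_mode <- match.arg(color_mode)
  stopifnot(levels >= 1L, consistency_radius >= 0L, consistency_radius <= 5L)
  wavelet_filters(wavelet_name)  # validate
  structure(list(wavelet_name = wavelet_name, levels = as.integer(levels),
                 selection = selection,
                 consistency_radius = as.integer(consistency_radius),
                 color_mode = color_mode),
            class = "wavelet_fusion_config")
}

# One periodized analysis step along columns: x even-length rows.
dwt_step_cols <- function(x, f) {
  n <- nrow(x)
  half <- n %/% 2L
  lo <- matrix(0, half, ncol(x)); hi <- lo
  base <- 2L * (seq_len(half) - 1L)          # 0-based start per output sample
  for (m in seq_along(f$lo)) {
    idx <- (base + m - 1L) %% n + 1L
    xs <- x[idx, , drop = FALSE]
    lo <- lo + f$lo[m] * xs
    hi <- hi + f$hi[m] * xs
  }
  list(lo = lo, hi = hi)
}

# Inverse of dwt_step_cols (adjoint of the orthonormal analysis).
idwt_step_cols <- function(lo, hi, f) {
  half <- nrow(lo); n <- 2L * half
  x <- matrix(0, n, ncol(lo))
  base <- 2L * (seq_len(half) - 1L)
  for (m in seq_along(f$lo)) {
    idx <- (base + m - 1L) %% n + 1L
    x[idx, ] <- x[idx, ] + f$lo[m] * lo + f$hi[m] * hi
  }
  x
}

dwt2_step <- function(x, f) {
  rows <- dwt_step_cols(x, f)                      # filter along rows (axis 1)
  lo <- dwt_step_cols(t(rows$lo), f)               # then along columns
  hi <- dwt_step_cols(t(rows$hi), f)
  list(ll = t(lo$lo), lh = t(lo$hi), hl = t(hi$lo), hh = t(hi$hi))
}

idwt2_step <- function(bands, f) {
  lo <- t(idwt_step_cols(t(bands$ll), t(bands$lh), f))
  hi <- t(idwt_step_cols(t(bands$hl), t(bands$hh), f))
  idwt_step_cols(lo, hi, f)
}

#' Multi-level 2D wavelet decomposition
#'
#' Periodized separable DWT of a grayscale image. The input is symmetrically
#' padded to a multiple of `2^levels` per side; the padded size is recorded so
#' [wavelet_reconstruct()] can crop back. Round-trip error is at machine
#' precision.
#'
#' @param image numeric matrix.
#' @param cfg a [wavelet_fusion_config].
#' @return a `wavelet_pyramid`: list with `approx` (coarsest LL band) and
#'   `details`, a list (fine to coarse) of `lh`/`hl`/`hh` band triples.
#' @export
wavelet_decompose <- function(image, cfg) {
  stopifnot(is.matrix(image))
  f <- wavelet_filters(cfg$wavelet_name)
  block <- 2L^cfg$levels
  if (min(dim(image)) < block)
    stop("image of ", nrow(image), " x ", ncol(image),
         " is too small for ", cfg$levels, " levels")
  orig <- dim(image)
  nr <- block * ceiling(nrow(image) / block)
  nc <- block * ceiling(ncol(image) / block)
  x <- pad_symmetric(image, nr, nc)
  details <- vector("list", cfg$levels)
  for (lev in seq_len(cfg$levels)) {
    s <- dwt2_step(x, f)
    details[[lev]] <- s[c("lh", "hl", "hh")]
    x <- s$ll
  }
  structure(list(approx = x, details = details, levels = cfg$levels,
                 wavelet_name = cfg$wavelet_name,
                 orig_dim = orig, padded_dim = c(nr, nc)),
            class = "wavelet_pyramid")
}

#' Invert a multi-level 2D wavelet decomposition
#'
#' @param pyr a `wavelet_pyramid` from [wavelet_decompose()].
#' @return the reconstructed matrix, cropped to the original size.
#' @export
wavelet_reconstruct <- function(pyr) {
  f <- wavelet_filters(pyr$wavelet_name)
  x <- pyr$approx
  for (lev in rev(seq_len(pyr$levels)))
    x <- idwt2_step(c(list(ll = x), pyr$details[[lev]]), f)
  x[seq_len(pyr$orig_dim[1L]), seq_len(pyr$orig_dim[2L]), drop = FALSE]
}

# Selection criterion for a detail band: |c| or 3x3 local energy of c.
selection_score <- function(coef, selection) {
  if (selection == "max_abs") abs(coef) else box_sum(coef^2, 1L)
}

#' Select wavelet coefficients across focal planes
#'
#' For each detail coefficient, keeps the value from the plane maximizing the
#' selection criterion (absolute value or local 3x3 energy); ties go to the
#' lowest plane index. The coarsest approximation band is the pixelwise mean
#' across planes. Selection maps (winning plane index per coefficient) are
#' returned for every detail band.
#'
#' @param pyramids list of congruent `wavelet_pyramid`s, one per plane.
#' @param cfg a [wavelet_fusion_config].
#' @return list with `fused` (a `wavelet_pyramid`) and `maps` (per level, per
#'   band, integer matrix of winning plane indices).
#' @export
select_coefficients <- function(pyramids, cfg) {
  stopifnot(length(pyramids) >= 1L)
  p1 <- pyramids[[1L]]
  for (p in pyramids)
    if (!identical(dim(p$approx), dim(p1$approx)) || p$levels != p1$levels)
      stop("pyramids are not congruent")
  d <- length(pyramids)
  maps <- vector("list", p1$levels)
  fused <- p1
  for (lev in seq_len(p1$levels)) {
    maps[[lev]] <- list()
    for (band in c("lh", "hl", "hh")) {
      coefs <- lapply(pyramids, function(p) p$details[[lev]][[band]])
      best_score <- selection_score(coefs[[1L]], cfg$selection)
      best_idx <- matrix(1L, nrow(best_score), ncol(best_score))
      if (d > 1L) for (i in 2:d) {
        sc <- selection_score(coefs[[i]], cfg$selection)
        win <- sc > best_score               # strict: ties keep lower index
        best_score[win] <- sc[win]
        best_idx[win] <- i
      }
      maps[[lev]][[band]] <- best_idx
      fused$details[[lev]][[band]] <- apply_selection(coefs, best_idx)
    }
  }
  fused$approx <- Reduce(`+`, lapply(pyramids, `[[`, "approx")) / d
  list(fused = fused, maps = maps)
}

# Gather coefficients per the selection map.
apply_selection <- function(coefs, map) {
  out <- coefs[[1L]]
  for (i in seq_along(coefs)) {
    pick <- map == i
    if (any(pick)) out[pick] <- coefs[[i]][pick]
  }
  out
}

#' Majority (consistency) filter on a plane-selection map
#'
#' Replaces each entry by the plane index holding the majority in its
#' `(2r+1)^2` neighbourhood; ties keep the original entry. Suppresses the
#' isolated mis-selections that make coefficient-wise fusion sensitive to
#' noise. Radius 0 is the identity.
#'
#' @param map integer matrix of plane indices.
#' @param radius window radius r >= 0.
#' @return filtered integer matrix.
#' @export
consistency_filter <- function(map, radius) {
  stopifnot(radius >= 0L)
  if (radius == 0L) return(map)
  idx <- sort(unique(as.vector(map)))
  if (length(idx) == 1L) return(map)
  best_cnt <- matrix(-1, nrow(map), ncol(map))
  best_val <- map
  n_best <- matrix(0L, nrow(map), ncol(map))
  for (v in idx) {
    cnt <- box_sum((map == v) + 0, radius)
    win <- cnt > best_cnt + 1e-9
    tie <- abs(cnt - best_cnt) <= 1e-9
    n_best[win] <- 1L
    n_best[tie] <- n_best[tie] + 1L
    best_cnt[win] <- cnt[win]
    best_val[win] <- v
  }
  # ambiguous majorities keep the original selection
  out <- best_val
  out[n_best > 1L] <- map[n_best > 1L]
  out
}

#' Wavelet EDoF fusion of a z-stack
#'
#' Decomposes every focal plane, selects detail coefficients across planes by
#' the configured sharpness criterion (on the Rec.709 luminance in
#' `luminance_guided` mode, with the same selection maps applied to all three
#' channels), majority-filters the selection maps, and reconstructs. The
#' output is clipped to \[0, 1\].
#'
#' @param stack a [zstack].
#' @param cfg a [wavelet_fusion_config].
#' @return an [edof_image] with method `"wavelet"`.
#' @export
fuse_stack_wavelet <- function(stack, cfg = wavelet_fusion_config()) {
  stopifnot(inherits(stack, "zstack"))
  hi <- range_max(stack$range)
  planes <- lapply(stack$planes, function(p) p / hi)
  d <- length(planes)
  if (d == 1L)
    return(edof_image(planes[[1L]], "wavelet", 1L, stack$axial_step))

  fuse_channel <- function(channel_imgs, maps) {
    pyrs <- lapply(channel_imgs, wavelet_decompose, cfg = cfg)
    fused <- pyrs[[1L]]
    for (lev in seq_len(fused$levels))
      for (band in c("lh", "hl", "hh")) {
        coefs <- lapply(pyrs, function(p) p$details[[lev]][[band]])
        fused$details[[lev]][[band]] <- apply_selection(coefs, maps[[lev]][[band]])
      }
    fused$approx <- Reduce(`+`, lapply(pyrs, `[[`, "approx")) / d
    wavelet_reconstruct(fused)
  }

  out <- array(0, dim(planes[[1L]]))
  if (cfg$color_mode == "luminance_guided") {
    lum_pyrs <- lapply(planes, function(p) wavelet_decompose(luminance(p), cfg))
    sel <- select_coefficients(lum_pyrs, cfg)
    maps <- filter_maps(sel$maps, cfg$consistency_radius)
    for (ch in 1:3)
      out[, , ch] <- fuse_channel(lapply(planes, function(p) p[, , ch]), maps)
  } else {
    for (ch in 1:3) {
      pyrs <- lapply(planes, function(p) wavelet_decompose(p[, , ch], cfg))
      sel <- select_coefficients(pyrs, cfg)
      maps <- filter_maps(sel$maps, cfg$consistency_radius)
      out[, , ch] <- fuse_channel(lapply(planes, function(p) p[, , ch]), maps)
    }
  }
  edof_image(out, "wavelet", d, stack$axial_step)
}

filter_maps <- function(maps, radius) {
  if (radius == 0L) return(maps)
  lapply(maps, function(lev) lapply(lev, consistency_filter, radius = radius))
}
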