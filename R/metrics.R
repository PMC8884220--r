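# Image-similarity metrics: SSIM (Gaussian-windowed, the original reference
# defaults), Pearson correlation of luminance values, and the Haar
# wavelet-based perceptual similarity index (HaarPSI). All three accept
# grayscale matrices or RGB arrays; RGB is reduced to Rec.709 luminance for
# SSIM/CORR, while HaarPSI keeps its chroma terms.

# SSIM map over valid 11x11 Gaussian windows (sigma 1.5). Returns the
# per-window structural similarity values.
ssim_map <- function(x, y, L = 1, sigma = 1.5, radius = 5L,
                     K1 = 0.01, K2 = 0.03) {
  k <- gaussian_kernel(sigma, radius)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  mu_x <- sep_conv_valid(x, k); mu_y <- sep_conv_valid(y, k)
  sxx <- sep_conv_valid(x * x, k) - mu_x^2
  syy <- sep_conv_valid(y * y, k) - mu_y^2
  sxy <- sep_conv_valid(x * y, k) - mu_x * mu_y
  ((2 * mu_x * mu_y + C1) * (2 * sxy + C2)) /
    ((mu_x^2 + mu_y^2 + C1) * (sxx + syy + C2))
}

#' Structural similarity index (SSIM)
#'
#' Mean structural similarity over sliding 11x11 Gaussian windows
#' (sigma = 1.5), with stabilizers C1 = (0.01 L)^2 and C2 = (0.03 L)^2 where
#' L is the dynamic range of the inputs. RGB inputs are converted to Rec.709
#' luminance first. Only fully interior windows contribute.
#'
#' @param x,y congruent images (matrices or `H x W x 3` arrays) on \[0, L\].
#' @param L declared dynamic range (1 for unit-range images).
#' @return SSIM in \[-1, 1\]; 1 for identical images.
#' @export
ssim <- function(x, y, L = 1) {
  if (!identical(dim(x), dim(y))) stop("images must have identical dimensions")
  mean(ssim_map(luminance(x), luminance(y), L = L))
}

#' Pearson correlation between two images
#'
#' Pearson r over flattened Rec.709 luminance values. Invariant to positive
#' affine rescaling of either image.
#'
#' @param x,y congruent images.
#' @return r in \[-1, 1\]; `NA` (with a warning) if either image is constant.
#' @export
pearson_corr <- function(x, y) {
  if (!identical(dim(x), dim(y))) stop("images must have identical dimensions")
  xv <- as.vector(luminance(x)); yv <- as.vector(luminance(y))
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    warning("Pearson correlation undefined for a constant image")
    return(NA_real_)
  }
  stats::cor(xv, yv)
}

# 2D Haar high-pass response at the given scale: convolution ('same', zero
# padding) with a 2^s x 2^s kernel of entries +-2^-s, negative on top.
# orientation 1 responds to horizontal edges; orientation 2 is the transpose.
haar_response <- function(x, scale, orientation) {
  n <- 2L^scale
  k_hi <- c(rep(-1, n / 2L), rep(1, n / 2L)) * 2^(-scale / 2)
  k_lo <- rep(1, n) * 2^(-scale / 2)
  if (orientation == 1L) sep_conv_same(x, k_hi, k_lo)
  else sep_conv_same(x, k_lo, k_hi)
}

# 2x2 mean pooling (drops trailing odd row/col).
subsample2 <- function(x) {
  nr <- 2L * (nrow(x) %/% 2L); nc <- 2L * (ncol(x) %/% 2L)
  x <- x[seq_len(nr), seq_len(nc), drop = FALSE]
  0.25 * (x[seq(1L, nr, 2L), seq(1L, nc, 2L), drop = FALSE] +
          x[seq(2L, nr, 2L), seq(1L, nc, 2L), drop = FALSE] +
          x[seq(1L, nr, 2L), seq(2L, nc, 2L), drop = FALSE] +
          x[seq(2L, nr, 2L), seq(2L, nc, 2L), drop = FALSE])
}

local_similarity <- function(a, b, C) (2 * a * b + C) / (a^2 + b^2 + C)

#' Haar wavelet-based perceptual similarity index (HaarPSI)
#'
#' Perceptual similarity built from the magnitudes of 2D Haar wavelet
#' responses: local similarities at the two finest scales, logistic-mapped
#' with constant `C`, are aggregated with weights given by the third-scale
#' response magnitude, then sharpened with exponent `alpha`. For RGB input
#' the images are converted to YIQ; the luminance channel drives the two
#' orientation terms and the chroma channels contribute a third,
#' mean-filtered similarity term. Constants C = 30 and alpha = 4.2 are the
#' defining reference's defaults on the \[0, 255\] scale; unit-range inputs
#' are rescaled internally.
#'
#' @param x,y congruent images (matrices or `H x W x 3` arrays) on \[0, L\].
#' @param L declared dynamic range of the inputs (1 for unit-range).
#' @param C,alpha HaarPSI constants.
#' @return similarity in \[0, 1\]; 1 for identical images.
#' @export
hpsi <- function(x, y, L = 1, C = 30, alpha = 4.2) {
  if (!identical(dim(x), dim(y))) stop("images must have identical dimensions")
  scale <- 255 / L
  rgb <- !is.matrix(x)
  if (rgb) {
    yiq1 <- rgb_to_yiq(x * scale); yiq2 <- rgb_to_yiq(y * scale)
    y1 <- yiq1[[1L]]; y2 <- yiq2[[1L]]
  } else {
    y1 <- x * scale; y2 <- y * scale
  }
  y1 <- subsample2(y1); y2 <- subsample2(y2)

  sim_lum <- vector("list", 2L)   # per orientation
  weights <- vector("list", 2L)
  for (k in 1:2) {
    s <- 0
    for (j in 1:2) {
      a <- abs(haar_response(y1, j, k)); b <- abs(haar_response(y2, j, k))
      s <- s + local_similarity(a, b, C)
    }
    sim_lum[[k]] <- s / 2
    weights[[k]] <- pmax(abs(haar_response(y1, 3L, k)),
                         abs(haar_response(y2, 3L, k)))
  }
  sims <- sim_lum
  wts <- weights
  if (rgb) {
    mean2 <- function(z) sep_conv_same(z, rep(0.5, 2L))
    i1 <- subsample2(yiq1[[2L]]); i2 <- subsample2(yiq2[[2L]])
    q1 <- subsample2(yiq1[[3L]]); q2 <- subsample2(yiq2[[3L]])
    sim_chroma <- (local_similarity(abs(mean2(i1)), abs(mean2(i2)), C) +
                   local_similarity(abs(mean2(q1)), abs(mean2(q2)), C)) / 2
    sims <- c(sims, list(sim_chroma))
    wts <- c(wts, list((weights[[1L]] + weights[[2L]]) / 2))
  }
  sig <- function(v) 1 / (1 + exp(-alpha * v))
  num <- 0; den <- 0
  for (k in seq_along(sims)) {
    num <- num + sum(sig(sims[[k]]) * wts[[k]])
    den <- den + sum(wts[[k]])
  }
  if (den == 0) return(1)  # two blank images: identical by construction
  r <- num / den
  (log(r / (1 - r)) / alpha)^2
}

rgb_to_yiq <- function(img) {
  r <- img[, , 1L]; g <- img[, , 2L]; b <- img[, , 3L]
  list(0.299 * r + 0.587 * g + 0.114 * b,
       0.596 * r - 0.274 * g - 0.322 * b,
       0.211 * r - 0.523 * g + 0.312 * b)
}

#' Compare a test EDoF image against a reference with all three metrics
#'
#' @param reference,test [edof_image]s or plain `H x W x 3` arrays in \[0, 1\].
#' @param reference_id,test_id provenance strings carried into the report.
#' @return a `metric_report`: one-row data frame with columns
#'   `reference_id`, `test_id`, `ssim`, `corr`, `hpsi`.
#' @export
evaluate_pair <- function(reference, test,
                          reference_id = "reference", test_id = "test") {
  ref <- if (inherits(reference, "edof_image")) reference$image else reference
  tst <- if (inherits(test, "edof_image")) test$image else test
  if (!identical(dim(ref), dim(tst))) stop("images must have identical dimensions")
  out <- data.frame(reference_id = reference_id, test_id = test_id,
                    ssim = ssim(ref, tst), corr = pearson_corr(ref, tst),
                    hpsi = hpsi(ref, tst), stringsAsFactors = FALSE)
  class(out) <- c("metric_report", class(out))
  out
}

#' Evaluate matched batches of image pairs
#'
#' @param references,tests equal-length lists of images/[edof_image]s,
#'   compared pairwise in order.
#' @return a `metric_report` data frame with one row per pair.
#' @export
evaluate_batch <- function(references, tests) {
  if (length(references) != length(tests))
    stop("reference and test sets must have equal length")
  rows <- lapply(seq_along(references), function(i)
    evaluate_pair(references[[i]], tests[[i]],
                  reference_id = sprintf("ref_%03d", i),
                  test_id = sprintf("test_%03d", i)))
  out <- do.call(rbind, rows)
  class(out) <- c("metric_report", "data.frame")
  out
}
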