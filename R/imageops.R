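# Low-level image helpers shared by the wavelet fusion, metrics, losses and
# the simulator. All images are numeric matrices (grayscale) or H x W x 3
# arrays (RGB), column-major as usual in R.

#' Rec.709 luminance of an RGB image
#'
#' @param img `H x W x 3` numeric array.
#' @return `H x W` numeric matrix.
#' @export
luminance <- function(img) {
  if (is.matrix(img)) return(img)
  0.2126 * img[, , 1L] + 0.7152 * img[, , 2L] + 0.0722 * img[, , 3L]
}

# 1D convolution of the columns of matrix x with kernel k (odd or even
# length), zero padding, 'same' output size. Centered at ceil((len+1)/2).
conv_cols_same <- function(x, k) {
  n <- nrow(x); len <- length(k); c0 <- ceiling((len + 1) / 2)
  out <- matrix(0, nrow(x), ncol(x))
  for (m in seq_len(len)) {
    off <- m - c0                        # source row = target row + off
    src <- seq_len(n) + off
    keep <- src >= 1L & src <= n
    if (!any(keep)) next
    out[keep, ] <- out[keep, ] + k[m] * x[src[keep], , drop = FALSE]
  }
  out
}

# Separable 2D 'same' convolution with zero padding.
sep_conv_same <- function(x, krow, kcol = krow) {
  t(conv_cols_same(t(conv_cols_same(x, krow)), kcol))
}

# 'valid' 1D convolution along columns: output rows = n - len + 1.
conv_cols_valid <- function(x, k) {
  n <- nrow(x); len <- length(k); nout <- n - len + 1L
  if (nout < 1L) stop("kernel longer than signal in 'valid' convolution")
  out <- matrix(0, nout, ncol(x))
  for (m in seq_len(len))
    out <- out + k[m] * x[seq.int(m, m + nout - 1L), , drop = FALSE]
  out
}

# Separable 2D 'valid' convolution.
sep_conv_valid <- function(x, krow, kcol = krow) {
  t(conv_cols_valid(t(conv_cols_valid(x, krow)), kcol))
}

# Adjoint of sep_conv_valid (full convolution with the flipped kernel):
# maps gradients at the (smaller) valid grid back to the input grid.
sep_conv_valid_adjoint <- function(g, krow, kcol = krow) {
  pad_r <- length(krow) - 1L; pad_c <- length(kcol) - 1L
  gp <- matrix(0, nrow(g) + 2L * pad_r, ncol(g) + 2L * pad_c)
  gp[pad_r + seq_len(nrow(g)), pad_c + seq_len(ncol(g))] <- g
  t(conv_cols_valid(t(conv_cols_valid(gp, rev(krow))), rev(kcol)))
}

# Truncated, normalized Gaussian kernel of given half-width.
gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq.int(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian blur of an image
#'
#' Separable truncated-Gaussian filter with zero padding ('same' size).
#' Used by the defocus simulator; `sigma = 0` is the identity.
#'
#' @param img matrix or `H x W x 3` array.
#' @param sigma standard deviation in pixels.
#' @return blurred image, same shape.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel(sigma)
  if (is.matrix(img)) return(sep_conv_same(img, k))
  out <- img
  for (ch in seq_len(dim(img)[3L])) out[, , ch] <- sep_conv_same(img[, , ch], k)
  out
}

#' Mean luminance-gradient energy of an image
#'
#' Mean squared central-difference gradient magnitude of the Rec.709
#' luminance; a standard focus measure (larger = sharper).
#'
#' @param img matrix or RGB array.
#' @return non-negative scalar.
#' @export
gradient_energy <- function(img) {
  y <- luminance(img)
  gx <- y[, c(2:ncol(y), ncol(y))] - y[, c(1L, 1:(ncol(y) - 1L))]
  gy <- y[c(2:nrow(y), nrow(y)), ] - y[c(1L, 1:(nrow(y) - 1L)), ]
  mean(gx^2 + gy^2) / 4
}

#' Laplacian energy inside a region (local sharpness)
#'
#' Sum of squared 4-neighbour Laplacian responses of the luminance within a
#' rectangular window; used to find the plane in which an object is sharpest.
#'
#' @param img matrix or RGB array.
#' @param rows,cols integer index ranges of the window (default whole image).
#' @return non-negative scalar.
#' @export
laplacian_energy <- function(img, rows = NULL, cols = NULL) {
  y <- luminance(img)
  if (!is.null(rows)) rows <- rows[rows >= 2L & rows <= nrow(y) - 1L]
  if (!is.null(cols)) cols <- cols[cols >= 2L & cols <= ncol(y) - 1L]
  if (is.null(rows)) rows <- 2:(nrow(y) - 1L)
  if (is.null(cols)) cols <- 2:(ncol(y) - 1L)
  lap <- 4 * y[rows, cols] - y[rows - 1L, cols] - y[rows + 1L, cols] -
    y[rows, cols - 1L] - y[rows, cols + 1L]
  sum(lap^2)
}

# Box sum over a (2r+1)^2 window, zero padding, 'same' size.
box_sum <- function(x, r) {
  if (r <= 0) return(x)
  k <- rep(1, 2L * r + 1L)
  sep_conv_same(x, k)
}

# Symmetric (reflect without repeating the edge sample) padding of a matrix
# on the bottom/right to reach target dimensions.
pad_symmetric <- function(x, nr, nc) {
  if (nrow(x) < nr) {
    extra <- nr - nrow(x)
    if (extra > nrow(x) - 1L) stop("padding exceeds image size")
    x <- rbind(x, x[seq.int(nrow(x) - 1L, by = -1L, length.out = extra), , drop = FALSE])
  }
  if (ncol(x) < nc) {
    extra <- nc - ncol(x)
    if (extra > ncol(x) - 1L) stop("padding exceeds image size")
    x <- cbind(x, x[, seq.int(ncol(x) - 1L, by = -1L, length.out = extra), drop = FALSE])
  }
  x
}
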