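# Composite training loss: l = lambda1 * MAE + lambda2 * (1 - SSIM) +
# lambda3 * FFT-MAE. All components are non-negative and vanish iff output
# and target are equal. Gradients are derived analytically so training needs
# no autodiff runtime. Losses operate in the network's [-1, 1] space (the
# SSIM dynamic range is 2 there).

#' Pixel-wise mean absolute error
#'
#' @param output,target congruent images (arrays or matrices).
#' @return mean of `|output - target|` over all pixels and channels.
#' @export
loss_mae <- function(output, target) {
  if (!identical(dim(output), dim(target))) stop("shape mismatch")
  mean(abs(output - target))
}

#' Structural-similarity loss component
#'
#' `1 - mean SSIM(output, target)`, computed per channel over valid 11x11
#' Gaussian windows and averaged, so 0 is the optimum and values lie in
#' \[0, 2\].
#'
#' @param output,target congruent `H x W x 3` arrays (or matrices) on a
#'   common range of width `L`.
#' @param L dynamic range of the inputs (2 for the network's \[-1, 1\] space).
#' @return non-negative scalar.
#' @export
loss_ssim <- function(output, target, L = 2) {
  if (!identical(dim(output), dim(target))) stop("shape mismatch")
  if (is.matrix(output)) return(1 - mean(ssim_map(output, target, L = L)))
  s <- 0
  for (ch in seq_len(dim(output)[3L]))
    s <- s + mean(ssim_map(output[, , ch], target[, , ch], L = L))
  1 - s / dim(output)[3L]
}

#' Fourier-domain mean absolute error
#'
#' Mean modulus of the difference of the 2D discrete Fourier transforms of
#' output and target, per channel, normalized by the pixel count. Penalizes
#' both amplitude and phase errors and vanishes iff the images are equal.
#'
#' @param output,target congruent images.
#' @return non-negative scalar.
#' @export
loss_fft <- function(output, target) {
  if (!identical(dim(output), dim(target))) stop("shape mismatch")
  if (is.matrix(output)) return(mean(Mod(stats::fft(output - target))))
  s <- 0
  for (ch in seq_len(dim(output)[3L]))
    s <- s + mean(Mod(stats::fft(output[, , ch] - target[, , ch])))
  s / dim(output)[3L]
}

#' Combined training loss
#'
#' `lambda1 * MAE + lambda2 * (1 - SSIM) + lambda3 * FFT-MAE`; the default
#' weights are 1.0, 0.1 and 0.5.
#'
#' @param output,target congruent images.
#' @param lambda1,lambda2,lambda3 non-negative component weights.
#' @param L dynamic range passed to the SSIM component.
#' @return scalar loss; 0 iff the images are equal (for positive weights).
#' @export
combined_loss <- function(output, target, lambda1 = 1.0, lambda2 = 0.1,
                          lambda3 = 0.5, L = 2) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, lambda3 >= 0)
  lambda1 * loss_mae(output, target) +
    lambda2 * loss_ssim(output, target, L = L) +
    lambda3 * loss_fft(output, target)
}

# ---------------------------------------------------------------------------
# gradients

grad_mae <- function(output, target) {
  sign(output - target) / length(output)
}

# gradient of (1 - mean valid-window SSIM) of one channel w.r.t. x.
grad_ssim_channel <- function(x, y, L = 2, sigma = 1.5, radius = 5L,
                              K1 = 0.01, K2 = 0.03) {
  k <- gaussian_kernel(sigma, radius)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  mu_x <- sep_conv_valid(x, k); mu_y <- sep_conv_valid(y, k)
  sxx <- sep_conv_valid(x * x, k) - mu_x^2
  syy <- sep_conv_valid(y * y, k) - mu_y^2
  sxy <- sep_conv_valid(x * y, k) - mu_x * mu_y
  A1 <- 2 * mu_x * mu_y + C1; A2 <- 2 * sxy + C2
  B1 <- mu_x^2 + mu_y^2 + C1; B2 <- sxx + syy + C2
  dS_dmux <- 2 * mu_y * A2 / (B1 * B2) - 2 * mu_x * A1 * A2 / (B1^2 * B2)
  dS_dsxx <- -A1 * A2 / (B1 * B2^2)
  dS_dsxy <- 2 * A1 / (B1 * B2)
  adj <- function(g) sep_conv_valid_adjoint(g, k)
  dx <- adj(dS_dmux) +
    2 * x * adj(dS_dsxx) - 2 * adj(mu_x * dS_dsxx) +
    y * adj(dS_dsxy) - adj(mu_y * dS_dsxy)
  -dx / length(mu_x)                       # d(1 - mean S)/dx
}

grad_fft_channel <- function(x, y) {
  d <- x - y
  f <- stats::fft(d)
  m <- Mod(f)
  p <- f / ifelse(m < 1e-12, 1, m)
  p[m < 1e-12] <- 0
  Re(stats::fft(p, inverse = TRUE)) / length(d)
}

# value + gradient of the combined loss for an H x W x 3 array pair in the
# [-1, 1] training space. Per-channel losses are averaged over 3 channels.
combined_loss_grad <- function(output, target, lam) {
  d3 <- dim(output)[3L]
  grad <- array(0, dim(output))
  l_mae <- loss_mae(output, target)
  l_ssim <- 0; l_fft <- 0
  g_mae <- grad_mae(output, target)
  for (ch in seq_len(d3)) {
    x <- output[, , ch]; y <- target[, , ch]
    l_ssim <- l_ssim + (1 - mean(ssim_map(x, y, L = 2))) / d3
    l_fft <- l_fft + mean(Mod(stats::fft(x - y))) / d3
    grad[, , ch] <- lam[1L] * g_mae[, , ch] +
      lam[2L] * grad_ssim_channel(x, y) / d3 +
      lam[3L] * grad_fft_channel(x, y) / d3
  }
  loss <- lam[1L] * l_mae + lam[2L] * l_ssim + lam[3L] * l_fft
  list(loss = loss, components = c(l_mae, l_ssim, l_fft), grad = grad)
}
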