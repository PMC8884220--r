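# Small programmatic fixtures shared across the test files.

rand_image <- function(h, w = h, channels = 3L, seed = NULL, lo = 0, hi = 1) {
  if (!is.null(seed)) set.seed(seed)
  if (channels == 1L) matrix(stats::runif(h * w, lo, hi), h, w)
  else array(stats::runif(h * w * channels, lo, hi), c(h, w, channels))
}

rand_stack <- function(d, h = 32L, w = h, seed = 1L, axial_step = 0.5) {
  set.seed(seed)
  planes <- lapply(seq_len(d), function(i) rand_image(h, w))
  zstack(planes, axial_step = axial_step)
}

# stack of d copies of one plane (fusion degeneracy fixture)
const_stack <- function(plane, d, axial_step = 0.5) {
  zstack(rep(list(plane), d), axial_step = axial_step)
}

# two-plane stack: left half sharp in plane 1, right half sharp in plane 2
half_sharp_pair <- function(h = 64L, seed = 3L) {
  set.seed(seed)
  sharp <- array(0.5, c(h, h, 3L))
  tex <- matrix(stats::runif(h * h), h)
  for (ch in 1:3) sharp[, , ch] <- tex
  blurred <- gaussian_blur(sharp, 3)
  left <- sharp; left[, (h / 2 + 1):h, ] <- blurred[, (h / 2 + 1):h, ]
  right <- sharp; right[, 1:(h / 2), ] <- blurred[, 1:(h / 2), ]
  zstack(list(left, right), axial_step = 0.5)
}

# clamp to [0, 1] preserving the dim attribute
clip_img <- function(x) { d <- dim(x); x <- pmin(1, pmax(0, x)); dim(x) <- d; x }

# direct windowed SSIM oracle: explicit loop over valid Gaussian windows
ssim_oracle <- function(x, y, L = 1, sigma = 1.5, radius = 5L,
                        K1 = 0.01, K2 = 0.03) {
  k1d <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  w <- outer(k1d, k1d); w <- w / sum(w)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  n <- 2L * radius + 1L
  vals <- c()
  for (i in seq_len(nrow(x) - n + 1L))
    for (j in seq_len(ncol(x) - n + 1L)) {
      xs <- x[i:(i + n - 1L), j:(j + n - 1L)]
      ys <- y[i:(i + n - 1L), j:(j + n - 1L)]
      mx <- sum(w * xs); my <- sum(w * ys)
      vx <- sum(w * xs^2) - mx^2; vy <- sum(w * ys^2) - my^2
      cxy <- sum(w * xs * ys) - mx * my
      vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                        ((mx^2 + my^2 + C1) * (vx + vy + C2)))
    }
  mean(vals)
}
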