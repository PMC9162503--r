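# Internal helpers shared across modules.

# Classed conditions so the CLI can map argument/config errors to exit 2.
stop_arg <- function(msg) {
  stop(structure(class = c("mf_arg_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
stop_config <- function(msg) {
  stop(structure(class = c("mf_config_error", "mf_arg_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Evaluate expr with a temporarily-seeded RNG, restoring global state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# DFT sample frequencies in cycles/sample, standard layout:
# 0, 1/n, ..., then the negative half.
fft_freq <- function(n) {
  c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L)) / n
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(X) stats::fft(X, inverse = TRUE) / length(X)

# Minimal-norm least-squares pseudoinverse with relative singular-value
# cutoff: singular values below rcond * max(sv) are treated as zero.
pinv_trunc <- function(A, rcond = 1e-3) {
  s <- svd(A)
  keep <- s$d > rcond * s$d[1] & s$d > 0
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# Antialiased disc of radius r (px) centred at fractional pixel coordinates
# (cy, cx) on an H x W canvas, 1 inside, 0 outside, subpixel area coverage
# at the rim (ss x ss supersampling of rim pixels only).
disc_coverage <- function(H, W, cy, cx, r, ss = 8L) {
  if (r < 0) stop_arg("disc radius must be nonnegative")
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  d <- sqrt((rows - cy)^2 + (cols - cx)^2)
  cov <- matrix(0, H, W)
  cov[d <= r - 0.75] <- 1
  rim <- which(d > r - 0.75 & d < r + 0.75)
  if (length(rim)) {
    off <- (seq_len(ss) - 0.5) / ss - 0.5
    sy <- rows[rim]; sx <- cols[rim]
    acc <- numeric(length(rim))
    for (oy in off) for (ox in off) {
      acc <- acc + ((sy + oy - cy)^2 + (sx + ox - cx)^2 <= r^2)
    }
    cov[rim] <- acc / (ss * ss)
  }
  cov
}

# Catmull-Rom cubic interpolation weights for fractional offset t in [0,1).
cubic_w <- function(t) {
  t2 <- t * t; t3 <- t2 * t
  cbind(-0.5 * t3 + t2 - 0.5 * t,
        1.5 * t3 - 2.5 * t2 + 1,
        -1.5 * t3 + 2 * t2 + 0.5 * t,
        0.5 * t3 - 0.5 * t2)
}

# n_out x n_in matrix applying 1-D bicubic sampling at coordinates `at`
# (1-based, fractional); samples outside [1, n_in] evaluate to 0.
cubic_sampling_matrix <- function(n_in, at) {
  Wm <- matrix(0, length(at), n_in)
  i0 <- floor(at)
  tfrac <- at - i0
  w <- cubic_w(tfrac)
  for (k in -1:2) {
    idx <- i0 + k
    ok <- idx >= 1 & idx <= n_in & at >= 0.5 & at <= n_in + 0.5
    if (any(ok))
      Wm[cbind(which(ok), idx[ok])] <- Wm[cbind(which(ok), idx[ok])] + w[ok, k + 2]
  }
  Wm
}

# Zoom a 2-D image about its centre by factor z (>1 magnifies), bicubic,
# zeros outside the source support; canvas size preserved.
zoom_about_center <- function(img, z) {
  if (z == 1) return(img)
  H <- nrow(img); W <- ncol(img)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  ry <- cy + (seq_len(H) - cy) / z
  rx <- cx + (seq_len(W) - cx) / z
  Wr <- cubic_sampling_matrix(H, ry)
  Wc <- cubic_sampling_matrix(W, rx)
  Wr %*% img %*% t(Wc)
}

is_rgb <- function(x) length(dim(x)) == 3L
n_channels <- function(x) if (is_rgb(x)) dim(x)[3] else 1L

# Apply fn(matrix) -> matrix to each channel of a 2-D or H x W x 3 image.
per_channel <- function(img, fn) {
  if (!is_rgb(img)) return(fn(img))
  out <- img
  for (ch in seq_len(dim(img)[3])) out[, , ch] <- fn(img[, , ch])
  out
}
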