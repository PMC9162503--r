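#' Defocus blur model
#'
#' Geometric defocus in the EFTL microscope is a uniform disc (pillbox) PSF
#' whose radius grows linearly with the difference of the drive currents of
#' the observed and in-focus slices: r_kk' = R0 |j_k - j_k'| pixels. The
#' single effective coefficient R0 (pixels per mA) folds together the pupil
#' aperture R, the magnification-per-current coefficient alpha and the pixel
#' pitch p as R0 = R alpha / p.
#'
#' @param R0 Effective blur coefficient, pixels per mA.
#' @param R Optional pupil aperture (m).
#' @param alpha Optional magnification-per-current coefficient (1/mA).
#' @param pixel_pitch_um Optional pixel pitch (um); when `R`, `alpha` and
#'   the pitch are all given, `R0` must equal `R * alpha / p`.
#' @return An object of class `blur_model`.
#' @examples
#' blur_radius(265, 125, blur_model(0.67))  # 93.8 px
#' @export
blur_model <- function(R0, R = NULL, alpha = NULL, pixel_pitch_um = NULL) {
  if (!is.numeric(R0) || length(R0) != 1L || R0 <= 0)
    stop_arg("R0 must be a single positive number (px/mA)")
  if (!is.null(R) && !is.null(alpha) && !is.null(pixel_pitch_um)) {
    implied <- R * alpha / (pixel_pitch_um * 1e-6)
    if (abs(implied - R0) > 1e-9 * abs(R0))
      stop_arg(sprintf("inconsistent blur model: R*alpha/p = %g but R0 = %g",
                       implied, R0))
  }
  structure(list(R0 = R0, R = R, alpha = alpha,
                 pixel_pitch_um = pixel_pitch_um), class = "blur_model")
}

#' @export
print.blur_model <- function(x, ...) {
  cat(sprintf("<blur_model> R0 = %g px/mA\n", x$R0)); invisible(x)
}

#' Defocus blur radius between two focal slices
#'
#' r = R0 |j_a - j_b|, in pixels. Symmetric in its current arguments.
#'
#' @param j_a,j_b Drive currents, mA. Vectorized.
#' @param blur A [blur_model()].
#' @return Blur radius in pixels.
#' @export
blur_radius <- function(j_a, j_b, blur) {
  stopifnot(inherits(blur, "blur_model"))
  blur$R0 * abs(j_a - j_b)
}

#' Discrete pillbox (uniform disc) PSF kernel
#'
#' Unit-sum disc of radius `r` pixels with area-weighted antialiasing at the
#' rim. Radii below half a pixel degenerate to the identity (1 x 1) kernel.
#'
#' @param r Disc radius, pixels (>= 0).
#' @return Square numeric matrix of odd size summing to 1.
#' @examples
#' sum(pillbox_kernel(7.3))  # 1
#' @export
pillbox_kernel <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0)
    stop_arg("pillbox radius must be a single nonnegative number")
  if (r < 0.5) return(matrix(1, 1, 1))
  n <- 2L * as.integer(ceiling(r + 1)) + 1L
  c0 <- (n + 1) / 2
  k <- disc_coverage(n, n, c0, c0, r)
  k / sum(k)
}

#' Radial defocus optical transfer function
#'
#' Closed-form Fourier transform of the unit-mass pillbox of radius `r`:
#' H(rho) = 2 J1(2 pi r rho) / (2 pi r rho), with H = 1 at rho = 0 or
#' r = 0 (jinc profile; first zero at rho ~ 0.6098 / r). Real-valued,
#' bounded by 1 in magnitude.
#'
#' @param r Blur radius, pixels (>= 0). Scalar.
#' @param rho Radial spatial frequency, cycles/pixel (>= 0). Vectorized.
#' @return Transfer value(s) in `[-1, 1]`.
#' @export
defocus_transfer <- function(r, rho) {
  if (any(r < 0) || any(rho < 0))
    stop_arg("defocus_transfer needs r >= 0 and rho >= 0")
  x <- 2 * pi * r * rho
  out <- rep(1, length(x))
  nz <- x > 1e-12
  out[nz] <- 2 * besselJ(x[nz], 1) / x[nz]
  out
}

#' Synthetic layered bead phantom
#'
#' Generates the ground-truth scene used throughout testing: rings of
#' disc-shaped fluorescent beads, each ring lying on its own focal plane
#' (its own EFTL current). The scene is piecewise planar: layer k is sharp
#' and beads of different layers do not overlap by construction of the
#' default ring radii.
#'
#' With `jitter_sd = 0` and the default angular offset the scene is
#' mirror-symmetric about the vertical axis through the canvas centre,
#' which some symmetry diagnostics rely on.
#'
#' @param n_layers Number of focal planes.
#' @param currents_mA EFTL current per layer (pairwise distinct); default
#'   `c(50, 100/3, 0)` mA.
#' @param canvas `c(H, W)` canvas size in pixels.
#' @param ring_radii_px Ring radius per layer, pixels.
#' @param beads_per_ring Beads on each ring.
#' @param bead_radius_px Bead disc radius, pixels.
#' @param intensity Peak bead intensity (8-bit-like scale by default).
#' @param seed RNG seed controlling the angular jitter.
#' @param jitter_sd Standard deviation of the angular jitter, radians.
#' @param angle_offset First-bead angle, radians.
#' @return An object of class `bead_scene`: `layers` (list of sharp images
#'   f_k), `currents_mA`, `beads` (per-layer centre/radius/intensity
#'   descriptors), `canvas`, `seed`.
#' @examples
#' sc <- bead_scene(seed = 1)
#' length(sc$layers)
#' @export
bead_scene <- function(n_layers = 3, currents_mA = c(50, 100 / 3, 0),
                       canvas = c(256, 256),
                       ring_radii_px = c(40, 65, 90),
                       beads_per_ring = 12, bead_radius_px = 3,
                       intensity = 200, seed = 1L, jitter_sd = 0.05,
                       angle_offset = pi / 2) {
  if (length(currents_mA) != n_layers)
    stop_arg("currents_mA must have one entry per layer")
  if (anyDuplicated(currents_mA))
    stop_arg("layer currents must be pairwise distinct")
  if (length(ring_radii_px) != n_layers)
    stop_arg("ring_radii_px must have one entry per layer")
  H <- canvas[1]; W <- canvas[2]
  if (any(ring_radii_px + bead_radius_px + 1 > min(H, W) / 2))
    stop_arg("ring exceeds canvas: largest ring + bead radius must fit")
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  layers <- vector("list", n_layers)
  beads <- vector("list", n_layers)
  with_seed(seed, {
    for (k in seq_len(n_layers)) {
      m <- beads_per_ring
      ang <- angle_offset + (seq_len(m) - 1) * 2 * pi / m +
        if (jitter_sd > 0) stats::rnorm(m, 0, jitter_sd) else 0
      by <- cy - ring_radii_px[k] * sin(ang)
      bx <- cx + ring_radii_px[k] * cos(ang)
      img <- matrix(0, H, W)
      for (i in seq_len(m))
        img <- img + intensity * disc_coverage(H, W, by[i], bx[i], bead_radius_px)
      layers[[k]] <- img
      beads[[k]] <- data.frame(y = by, x = bx, radius = bead_radius_px,
                               intensity = intensity)
    }
  })
  structure(list(layers = layers, currents_mA = as.numeric(currents_mA),
                 beads = beads, canvas = c(H, W), seed = seed),
            class = "bead_scene")
}

#' @export
print.bead_scene <- function(x, ...) {
  cat(sprintf("<bead_scene> %d layers on %d x %d px, currents %s mA\n",
              length(x$layers), x$canvas[1], x$canvas[2],
              paste(signif(x$currents_mA, 4), collapse = ", ")))
  invisible(x)
}

# FFT convolution of `img` with kernel `ker` (odd size, centred), periodic
# on a canvas padded by `pad` then cropped back.
conv_padded <- function(img, ker, pad) {
  H <- nrow(img); W <- ncol(img)
  P <- H + 2L * pad; Q <- W + 2L * pad
  big <- matrix(0, P, Q)
  big[pad + seq_len(H), pad + seq_len(W)] <- img
  kimg <- matrix(0, P, Q)
  n <- nrow(ker); h <- (n - 1L) / 2L
  ri <- ((seq_len(n) - 1L - h) %% P) + 1L
  ci <- ((seq_len(n) - 1L - h) %% Q) + 1L
  kimg[ri, ci] <- ker
  out <- Re(ifft2(fft2(big) * fft2(kimg)))
  out[pad + seq_len(H), pad + seq_len(W)]
}

#' Forward-simulate a multifocus stack from a layered scene
#'
#' Image formation model: the slice focused at current j_k sees its own
#' layer sharp plus every other layer convolved with the pillbox PSF of
#' radius R0 |j_k - j_k'|:
#' `i_k = f_k + sum_{k' != k} h_kk' * f_k'`.
#' Convolution is FFT-based with periodic boundary on a canvas padded by
#' the maximum blur radius, then cropped; unit-mass kernels make the
#' simulation energy-conserving for content away from the canvas edge.
#'
#' @param scene A [bead_scene()] (or any object with `layers` and
#'   `currents_mA`).
#' @param blur A [blur_model()].
#' @param noise_sd Optional additive Gaussian noise standard deviation
#'   (same intensity units as the scene); 0 disables (default). Negative
#'   excursions are clipped at 0.
#' @param seed RNG seed for the noise draw.
#' @return A [multifocus_stack()] with one slice per scene layer.
#' @examples
#' st <- simulate_stack(bead_scene(seed = 1), blur_model(0.2))
#' n_slices(st)
#' @export
simulate_stack <- function(scene, blur, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(blur, "blur_model"))
  if (length(scene$layers) < 1L) stop_arg("scene has no layers")
  N <- length(scene$layers)
  j <- scene$currents_mA
  rmax <- max(blur_radius(rep(j, each = N), rep(j, N), blur))
  pad <- as.integer(ceiling(rmax)) + 1L
  slices <- vector("list", N)
  for (k in seq_len(N)) {
    acc <- scene$layers[[k]]
    for (kp in seq_len(N)[-k]) {
      r <- blur_radius(j[k], j[kp], blur)
      acc <- acc + conv_padded(scene$layers[[kp]], pillbox_kernel(r), pad)
    }
    slices[[k]] <- acc
  }
  if (noise_sd > 0) {
    slices <- with_seed(seed, lapply(slices, function(s) {
      s <- s + matrix(stats::rnorm(length(s), 0, noise_sd), nrow(s))
      s[s < 0] <- 0
      s
    }))
  } else {
    slices <- lapply(slices, function(s) { s[s < 0] <- 0; s })
  }
  multifocus_stack(slices, j, bit_depth = 8, registered = TRUE)
}

#' Total energy of a layered scene
#' @param scene A [bead_scene()].
#' @return Sum of all layer energies.
#' @export
scene_energy <- function(scene) sum(vapply(scene$layers, sum, numeric(1)))
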