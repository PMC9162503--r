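#' Rec. 601 luminance of an image
#'
#' Grayscale images pass through; RGB images are collapsed with weights
#' (0.299, 0.587, 0.114).
#'
#' @param img Matrix or H x W x 3 array.
#' @return Matrix.
#' @export
luminance <- function(img) {
  if (!is_rgb(img)) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Mean square error between two images, compared as luminances
#'
#' RGB inputs are converted to Rec. 601 luminance first. `scale = "raw"`
#' compares native intensities; `scale = "unit"` divides both by
#' `max_value` (the dtype maximum, e.g. 255 for 8-bit data) beforehand.
#'
#' @param image_a,image_b Images of identical dimensions.
#' @param scale `"raw"` or `"unit"`.
#' @param max_value Dtype maximum used by the unit scale.
#' @return Scalar MSE (>= 0; 0 iff the compared luminances are identical).
#' @export
mse_luminance <- function(image_a, image_b, scale = c("raw", "unit"),
                          max_value = 255) {
  scale <- match.arg(scale)
  if (!identical(dim(image_a), dim(image_b)))
    stop_arg("mse_luminance: image dimensions differ")
  a <- luminance(image_a); b <- luminance(image_b)
  if (scale == "unit") { a <- a / max_value; b <- b / max_value }
  mean((a - b)^2)
}

#' Ground-truth viewpoint of a layered scene
#'
#' Shifts each true sharp layer by its disparity beta * R0 * j_k and sums,
#' using the same Fourier phase-ramp machinery as the reconstruction (so
#' comparisons are free of interpolation-scheme confounds).
#'
#' @param scene A [bead_scene()].
#' @param blur A [blur_model()].
#' @param beta_x,beta_y Pupil-displacement fractions.
#' @return Real image.
#' @export
scene_viewpoint <- function(scene, blur, beta_x, beta_y = 0) {
  sx <- disparity_px(beta_x, scene$currents_mA, blur)
  sy <- disparity_px(beta_y, scene$currents_mA, blur)
  ramp_sum_gray(lapply(scene$layers, fft2), sx, sy, 0L)
}

#' Evaluate reconstructed viewpoints against ground truth
#'
#' For each requested pupil displacement beta: the ground truth is the
#' analytically shifted superposition of the scene's true layers; the
#' reconstruction runs the full pipeline (forward-simulate the multifocus
#' stack, recover layer spectra by pseudoinversion, synthesize the
#' viewpoint). Reports the luminance MSE on both the raw intensity scale
#' and the unit (dtype-normalized) scale.
#'
#' @param scene A [bead_scene()] with known layers.
#' @param blur A [blur_model()] used for both simulation and inversion.
#' @param beta_x Vector of horizontal displacement fractions.
#' @param beta_y Vector of vertical displacement fractions (recycled).
#' @param rcond Pseudoinverse cutoff.
#' @param noise_sd Additive Gaussian noise in the simulation (default 0).
#' @param seed Seed for the noise draw.
#' @param max_value Dtype maximum for the unit scale (default 255,
#'   matching the 8-bit-like phantom intensities).
#' @return `evaluation_report`: a data.frame with columns `beta_x`,
#'   `beta_y`, `mse_raw`, `mse_unit`.
#' @examples
#' sc <- bead_scene(canvas = c(64, 64), ring_radii_px = c(10, 18, 26),
#'                  seed = 1)
#' evaluate_viewpoints(sc, blur_model(0.2), beta_x = c(-0.5, 0, 0.5))
#' @export
evaluate_viewpoints <- function(scene, blur, beta_x = c(-0.5, 0, 0.5),
                                beta_y = 0, rcond = 1e-3, noise_sd = 0,
                                seed = 1L, max_value = 255) {
  stopifnot(inherits(blur, "blur_model"))
  n <- max(length(beta_x), length(beta_y))
  beta_x <- rep_len(beta_x, n); beta_y <- rep_len(beta_y, n)
  stack <- simulate_stack(scene, blur, noise_sd = noise_sd, seed = seed)
  sp <- solve_layer_spectra(stack, blur, rcond)
  rows <- lapply(seq_len(n), function(i) {
    gt <- scene_viewpoint(scene, blur, beta_x[i], beta_y[i])
    rec <- synthesize_viewpoint(sp, beta_x[i], beta_y[i])
    data.frame(beta_x = beta_x[i], beta_y = beta_y[i],
               mse_raw = mse_luminance(gt, rec, "raw"),
               mse_unit = mse_luminance(gt, rec, "unit",
                                        max_value = max_value))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("evaluation_report", "data.frame")
  out
}

#' Measure sub-pixel horizontal disparity between two views
#'
#' Real circular cross-correlation via FFT, integer peak, then sub-pixel
#' refinement by maximizing the band-limited (Dirichlet) interpolant of
#' the correlation along each axis. An optional mask restricts the
#' measurement to one layer's support.
#'
#' @param image_a,image_b Images of identical size (b displaced relative
#'   to a).
#' @param mask Optional non-negative weight matrix applied to both.
#' @return Named vector `c(dx, dy)` in pixels: the displacement of
#'   `image_a`'s content relative to `image_b`'s.
#' @export
measure_disparity <- function(image_a, image_b, mask = NULL) {
  a <- luminance(image_a); b <- luminance(image_b)
  if (!is.null(mask)) { a <- a * mask; b <- b * mask }
  a <- a - mean(a); b <- b - mean(b)
  H <- nrow(a); W <- ncol(a)
  cc <- Re(ifft2(fft2(a) * Conj(fft2(b))))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  ix <- unname(pk[2]); iy <- unname(pk[1])
  # band-limited 1-D interpolant of the sampled correlation along one axis
  refine <- function(vals, i0) {
    n <- length(vals)
    Vf <- stats::fft(vals)
    f <- fft_freq(n)
    interp <- function(s) Re(sum(Vf * exp(2i * pi * f * s))) / n
    stats::optimize(interp, lower = i0 - 2, upper = i0, maximum = TRUE,
                    tol = 1e-7)$maximum
  }
  dx <- refine(cc[iy, ], ix)
  dy <- refine(cc[, ix], iy)
  if (dx > W / 2) dx <- dx - W
  if (dy > H / 2) dy <- dy - H
  c(dx = dx, dy = dy)
}

#' Write an evaluation report to CSV
#' @param report An `evaluation_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
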