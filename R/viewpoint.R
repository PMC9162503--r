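#' Horizontal disparity of a focal layer under pupil displacement
#'
#' A virtual pinhole displaced by a fraction beta of the pupil radius sees
#' the layer at current j_k displaced by d_k = beta * R0 * j_k pixels
#' (signed; linear in both beta and j_k).
#'
#' @param beta Pupil-displacement fraction (signed).
#' @param j_mA Layer current(s), mA. Vectorized.
#' @param blur A [blur_model()].
#' @return Disparity in pixels.
#' @examples
#' disparity_px(0.25, 10, blur_model(12.7))  # 31.75 px
#' @export
disparity_px <- function(beta, j_mA, blur) {
  stopifnot(inherits(blur, "blur_model"))
  beta * blur$R0 * j_mA
}

# Sum per-layer spectra with linear phase ramps implementing per-layer
# shifts (sx right, sy up, px), optionally on a zero-padded canvas to avoid
# circular wrap; returns the real image cropped to the original canvas.
ramp_sum_gray <- function(layers_spec, sx, sy, pad) {
  H <- nrow(layers_spec[[1]]); W <- ncol(layers_spec[[1]])
  if (pad > 0) {
    P <- H + 2L * pad; Q <- W + 2L * pad
    fu <- fft_freq(Q); fv <- fft_freq(P)
    acc <- matrix(0i, P, Q)
    for (k in seq_along(layers_spec)) {
      big <- matrix(0, P, Q)
      big[pad + seq_len(H), pad + seq_len(W)] <- Re(ifft2(layers_spec[[k]]))
      ramp <- exp(-2i * pi * outer(-sy[k] * fv, sx[k] * fu, "+"))
      acc <- acc + fft2(big) * ramp
    }
    out <- Re(ifft2(acc))
    out[pad + seq_len(H), pad + seq_len(W)]
  } else {
    fu <- fft_freq(W); fv <- fft_freq(H)
    acc <- matrix(0i, H, W)
    for (k in seq_along(layers_spec)) {
      ramp <- exp(-2i * pi * outer(-sy[k] * fv, sx[k] * fu, "+"))
      acc <- acc + layers_spec[[k]] * ramp
    }
    Re(ifft2(acc))
  }
}

#' Synthesize a virtual-pinhole viewpoint from recovered layer spectra
#'
#' Applies, per layer k, the linear phase ramp
#' exp(-i 2 pi j_k R0 (beta_x u + beta_y v)) to the recovered spectrum F_k
#' (u, v in cycles/px), sums over layers, and inverse-transforms. This is
#' the Fourier-domain equivalent of shifting each sharp layer by its
#' disparity beta * R0 * j_k and superposing: the scene as seen by a
#' pinhole displaced a fraction (beta_x, beta_y) of the pupil radius.
#' beta = (0, 0) yields the extended depth-of-field image.
#'
#' Axes: x = columns, positive beta_x shifts a layer with positive current
#' to the right; y = rows with positive beta_y shifting it upward.
#'
#' @param spectra A [solve_layer_spectra()] result.
#' @param beta_x,beta_y Pupil-displacement fractions, `|beta| <= 1`
#'   (displacements outside the aperture have no physical meaning).
#' @param pad Zero-pad margin (px) guarding against circular wrap of
#'   shifted content. The default 0 is the pure periodic phase-ramp
#'   formulation, which conserves total intensity exactly; `"auto"` pads by
#'   the maximum expected shift (use when shifted content approaches the
#'   canvas edge), or give a margin in pixels.
#' @return Real image (matrix, or H x W x 3 array for RGB input).
#' @examples
#' st <- simulate_stack(bead_scene(canvas = c(64, 64),
#'                                 ring_radii_px = c(10, 18, 26), seed = 1),
#'                      blur_model(0.2))
#' edof <- synthesize_viewpoint(solve_layer_spectra(st, blur_model(0.2)), 0, 0)
#' @export
synthesize_viewpoint <- function(spectra, beta_x, beta_y = 0, pad = 0L) {
  stopifnot(inherits(spectra, "layer_spectra"))
  if (abs(beta_x) > 1 || abs(beta_y) > 1)
    stop_arg("|beta| <= 1 required: pupil displacements outside the aperture have no physical meaning")
  sx <- disparity_px(beta_x, spectra$currents_mA, blur_model(spectra$R0))
  sy <- disparity_px(beta_y, spectra$currents_mA, blur_model(spectra$R0))
  if (identical(pad, "auto")) pad <- as.integer(ceiling(max(abs(c(sx, sy, 0)))))
  if (spectra$rgb) {
    out <- array(0, spectra$dim)
    for (ch in 1:3)
      out[, , ch] <- ramp_sum_gray(lapply(spectra$F, `[[`, ch), sx, sy, pad)
    out
  } else {
    ramp_sum_gray(spectra$F, sx, sy, pad)
  }
}

#' Extended depth-of-field (all-in-focus) image
#'
#' Convenience composition: recover the layer spectra from a registered
#' stack, then synthesize the centred-pinhole viewpoint (beta = 0), in
#' which every focal plane appears simultaneously sharp.
#'
#' @param stack A registered [multifocus_stack()].
#' @param blur A [blur_model()].
#' @param rcond Pseudoinverse cutoff, see [solve_layer_spectra()].
#' @return Real image, same size as the input slices.
#' @export
extended_dof <- function(stack, blur, rcond = 1e-3) {
  synthesize_viewpoint(solve_layer_spectra(stack, blur, rcond), 0, 0)
}

#' Stereoscopic pair from a multifocus stack
#'
#' A virtual stereo camera with baseline B (pinholes at +/- B/2 from the
#' pupil centre): left view at beta_x = +B/(2R), right view at
#' beta_x = -B/(2R). Physically B <= 2R, i.e. `baseline_fraction` = B/R
#' must not exceed 2 in magnitude; a negative baseline swaps the eyes.
#'
#' @param stack A registered [multifocus_stack()].
#' @param blur A [blur_model()].
#' @param baseline_fraction Baseline as a fraction B/R of the pupil radius.
#' @param rcond Pseudoinverse cutoff.
#' @return An object of class `stereo_pair` with `left`, `right` and
#'   `baseline_fraction`.
#' @export
stereo_pair <- function(stack, blur, baseline_fraction = 0.5, rcond = 1e-3) {
  if (abs(baseline_fraction) > 2)
    stop_arg("baseline exceeds the pupil: B <= 2R requires |baseline_fraction| <= 2")
  sp <- solve_layer_spectra(stack, blur, rcond)
  structure(list(left = synthesize_viewpoint(sp, +baseline_fraction / 2),
                 right = synthesize_viewpoint(sp, -baseline_fraction / 2),
                 baseline_fraction = baseline_fraction),
            class = "stereo_pair")
}

#' @export
print.stereo_pair <- function(x, ...) {
  d <- dim(x$left)
  cat(sprintf("<stereo_pair> %d x %d px, baseline B/R = %g\n",
              d[1], d[2], x$baseline_fraction))
  invisible(x)
}

#' Render a stereo pair for display
#'
#' `cross_eye` places the left-eye view on the right panel and vice versa
#' (fused by deliberately crossing the eyes); `parallel` uses the natural
#' order; `anaglyph` encodes the left view in the red channel and the right
#' view in green + blue (grayscale inputs are promoted to RGB).
#'
#' @param pair A [stereo_pair()].
#' @param mode `"cross_eye"`, `"parallel"` or `"anaglyph"`.
#' @param gutter Blank columns between the two panels (side-by-side modes).
#' @return Image matrix (side-by-side) or H x W x 3 array (anaglyph).
#' @export
render_stereo <- function(pair, mode = c("cross_eye", "parallel", "anaglyph"),
                          gutter = 0L) {
  stopifnot(inherits(pair, "stereo_pair"))
  mode <- match.arg(mode)
  to_gray <- function(img) if (is_rgb(img)) luminance(img) else img
  L <- to_gray(pair$left); R <- to_gray(pair$right)
  gap <- matrix(0, nrow(L), gutter)
  switch(mode,
    cross_eye = cbind(R, gap, L),
    parallel = cbind(L, gap, R),
    anaglyph = {
      out <- array(0, c(nrow(L), ncol(L), 3))
      out[, , 1] <- L; out[, , 2] <- R; out[, , 3] <- R
      out
    })
}

#' Sweep a grid of virtual viewpoints
#'
#' Synthesizes one frame per (beta_x, beta_y) pair on a rectangular grid,
#' re-using a single layer-spectra solve. Frames are ordered row-major with
#' serpentine (boustrophedon) traversal so consecutive frames are adjacent
#' viewpoints.
#'
#' @param stack A registered [multifocus_stack()].
#' @param blur A [blur_model()].
#' @param beta_x_grid,beta_y_grid Viewpoint fractions (each within the unit
#'   pupil).
#' @param rcond Pseudoinverse cutoff.
#' @return List of frames; each has attributes `beta_x`, `beta_y`.
#' @export
sweep_viewpoints <- function(stack, blur,
                             beta_x_grid = seq(-0.25, 0.25, length.out = 5),
                             beta_y_grid = seq(-0.25, 0.25, length.out = 5),
                             rcond = 1e-3) {
  sp <- solve_layer_spectra(stack, blur, rcond)
  frames <- list()
  for (iy in seq_along(beta_y_grid)) {
    xs <- if (iy %% 2L == 1L) seq_along(beta_x_grid) else rev(seq_along(beta_x_grid))
    for (ix in xs) {
      fr <- synthesize_viewpoint(sp, beta_x_grid[ix], beta_y_grid[iy])
      attr(fr, "beta_x") <- beta_x_grid[ix]
      attr(fr, "beta_y") <- beta_y_grid[iy]
      frames[[length(frames) + 1L]] <- fr
    }
  }
  frames
}
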