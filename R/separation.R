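#' Build the per-frequency defocus system matrix
#'
#' At radial spatial frequency rho the N slices of a registered multifocus
#' stack are coupled by the N x N symmetric matrix H with unit diagonal and
#' off-diagonal entries H_kk' = defocus_transfer(R0 |j_k - j_k'|, rho).
#' At rho = 0 this is the (singular) all-ones matrix.
#'
#' @param rho Radial spatial frequency, cycles/pixel. Scalar.
#' @param currents_mA Slice currents, mA.
#' @param blur A [blur_model()].
#' @return N x N real symmetric matrix with unit diagonal.
#' @examples
#' build_system_matrix(0.1, c(50, 0), blur_model(0.2))
#' @export
build_system_matrix <- function(rho, currents_mA, blur) {
  N <- length(currents_mA)
  r <- blur$R0 * abs(outer(currents_mA, currents_mA, "-"))
  H <- matrix(defocus_transfer_mat(r, rho), N, N)
  diag(H) <- 1
  H
}

# Vectorized transfer evaluation over a matrix of radii at one rho.
defocus_transfer_mat <- function(r, rho) {
  x <- 2 * pi * r * rho
  out <- matrix(1, nrow(r), ncol(r))
  nz <- x > 1e-12
  out[nz] <- 2 * besselJ(x[nz], 1) / x[nz]
  out
}

#' Recover per-plane in-focus layer spectra by pseudoinversion
#'
#' Solves, independently at every spatial-frequency bin (u, v), the linear
#' system H(u,v) F(u,v) = I(u,v) relating the Fourier transforms I_k of the
#' observed slices to the spectra F_k of the unknown sharp layers, using
#' the minimal-norm least-squares (Moore-Penrose) solution
#' F = pinv(H) I. H depends on (u, v) only through rho = sqrt(u^2 + v^2),
#' so bins are grouped by their exact rho value (integer key
#' (ku H)^2 + (kv W)^2) and each distinct H is pseudo-inverted once; the
#' grouped solution is identical to the per-bin one.
#'
#' Singular values below `rcond` times the largest are truncated; this
#' regularizes the rank-deficient DC bin (all-ones H) and near-singular
#' low-frequency bins.
#'
#' @param stack A registered [multifocus_stack()].
#' @param blur A [blur_model()].
#' @param rcond Relative singular-value cutoff of the pseudoinverse.
#' @param taper Optional cosine (Tukey) edge taper fraction in `[0, 1)`
#'   applied to each slice before the transform to limit wrap-around
#'   ringing; 0 (default) disables. A deviation knob, not part of the model.
#' @return An object of class `layer_spectra`: `F` (list of N complex
#'   H x W matrices, or H x W x 3 per-channel lists for RGB),
#'   `currents_mA`, `R0`, `dim`, `rcond`, `bit_depth`.
#' @examples
#' st <- simulate_stack(bead_scene(canvas = c(64, 64),
#'                                 ring_radii_px = c(10, 18, 26), seed = 1),
#'                      blur_model(0.2))
#' sp <- solve_layer_spectra(st, blur_model(0.2))
#' @export
solve_layer_spectra <- function(stack, blur, rcond = 1e-3, taper = 0) {
  stopifnot(inherits(stack, "multifocus_stack"), inherits(blur, "blur_model"))
  N <- n_slices(stack)
  if (!stack$registered && N > 1L)
    stop_arg("stack must be registered before layer separation")
  if (any(vapply(stack$slices, function(s) any(!is.finite(s)), logical(1))))
    stop_arg("non-finite values in stack slices")
  d <- dim(stack$slices[[1]])
  H <- d[1]; W <- d[2]
  rgb <- length(d) == 3L

  win <- if (taper > 0) outer(tukey_win(H, taper), tukey_win(W, taper)) else NULL
  solve_ch <- function(ch) {
    mats <- lapply(stack$slices, function(s) {
      m <- if (rgb) s[, , ch] else s
      if (!is.null(win)) m <- m * win
      m
    })
    solve_spectra_gray(mats, stack$currents_mA, blur, rcond)
  }
  Fs <- if (rgb) {
    chans <- lapply(1:3, solve_ch)
    lapply(seq_len(N), function(k) lapply(chans, `[[`, k))
  } else solve_ch(1L)

  structure(list(F = Fs, currents_mA = stack$currents_mA, R0 = blur$R0,
                 dim = d, rcond = rcond, rgb = rgb,
                 bit_depth = stack$bit_depth),
            class = "layer_spectra")
}

tukey_win <- function(n, frac) {
  t <- (seq_len(n) - 1) / (n - 1)
  w <- rep(1, n)
  a <- frac / 2
  lo <- t < a; hi <- t > 1 - a
  w[lo] <- 0.5 * (1 + cos(pi * (t[lo] / a - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * ((t[hi] - 1 + a) / a)))
  w
}

# Core grayscale solver: list of H x W matrices -> list of complex spectra.
solve_spectra_gray <- function(mats, currents, blur, rcond) {
  N <- length(mats)
  H <- nrow(mats[[1]]); W <- ncol(mats[[1]])
  Imat <- matrix(0i, N, H * W)
  for (k in seq_len(N)) Imat[k, ] <- as.vector(fft2(mats[[k]]))
  if (N == 1L) {
    Fm <- Imat
  } else {
    ku <- round(fft_freq(W) * W)  # integer col indices
    kv <- round(fft_freq(H) * H)  # integer row indices
    key_mat <- outer((kv * W)^2, (ku * H)^2, "+")  # exact rho^2 * (HW)^2
    rho_mat <- sqrt(outer((kv / H)^2, (ku / W)^2, "+"))
    groups <- split(seq_len(H * W), as.vector(key_mat))
    Fm <- matrix(0i, N, H * W)
    for (g in groups) {
      Hm <- build_system_matrix(rho_mat[g[1]], currents, blur)
      Fm[, g] <- pinv_trunc(Hm, rcond) %*% Imat[, g, drop = FALSE]
    }
  }
  lapply(seq_len(N), function(k) matrix(Fm[k, ], H, W))
}

#' @export
print.layer_spectra <- function(x, ...) {
  cat(sprintf("<layer_spectra> N = %d layers, %s px grid, R0 = %g px/mA, rcond = %g\n",
              length(x$F), paste(x$dim[1:2], collapse = " x "), x$R0, x$rcond))
  invisible(x)
}

#' Inverse-transform recovered layer spectra to images
#'
#' Returns the spatial-domain sharp layers. For real input stacks the
#' spectra are Hermitian and the inverse transforms are real up to
#' numerical noise; a relative imaginary residue above 1e-3 signals
#' inconsistent input and raises an error. Negative excursions are kept
#' (statistics available via `attr(, "negative_fraction")`).
#'
#' @param spectra A [solve_layer_spectra()] result.
#' @return List of N real images (matrices, or H x W x 3 arrays for RGB).
#' @export
layers_to_images <- function(spectra) {
  stopifnot(inherits(spectra, "layer_spectra"))
  inv1 <- function(Fk) {
    z <- ifft2(Fk)
    scale <- max(abs(z), 1e-300)
    if (max(abs(Im(z))) > 1e-3 * scale)
      stop_arg("imaginary residue exceeds tolerance: spectra are not consistent with a real stack")
    Re(z)
  }
  out <- lapply(spectra$F, function(Fk) {
    if (spectra$rgb) {
      a <- array(0, spectra$dim)
      for (ch in 1:3) a[, , ch] <- inv1(Fk[[ch]])
      a
    } else inv1(Fk)
  })
  attr(out, "negative_fraction") <-
    vapply(out, function(m) mean(m < 0), numeric(1))
  out
}
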