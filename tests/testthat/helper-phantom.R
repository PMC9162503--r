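# Shared fixtures: a small fast phantom for unit tests and the full-size
# default phantom for end-to-end checks. Blur coefficient 0.2 px/mA puts
# the adjacent-plane blur radii of the default currents (50, 100/3, 0 mA)
# at 3.33 and 6.67 px.

test_blur <- function(R0 = 0.2) blur_model(R0)

small_scene <- function(seed = 1, jitter_sd = 0.05, ...) {
  # ring + bead + max blur (10 px at R0 = 0.2) stays clear of the border
  bead_scene(canvas = c(64, 64), ring_radii_px = c(8, 13, 18),
             beads_per_ring = 6, bead_radius_px = 2, seed = seed,
             jitter_sd = jitter_sd, ...)
}

single_layer_scene <- function(j = 10, seed = 2, canvas = c(64, 64)) {
  bead_scene(n_layers = 1, currents_mA = j, canvas = canvas,
             ring_radii_px = 20, beads_per_ring = 6, seed = seed)
}

# Independent per-frequency-bin reference solver: loops over every (u, v)
# bin and applies the pseudoinverse there, with no grouping.
naive_solver <- function(stack, blur, rcond = 1e-3) {
  N <- n_slices(stack)
  H <- nrow(stack$slices[[1]]); W <- ncol(stack$slices[[1]])
  Im <- lapply(stack$slices, function(s) stats::fft(s))
  fu <- multifocusr:::fft_freq(W); fv <- multifocusr:::fft_freq(H)
  Fs <- lapply(seq_len(N), function(k) matrix(0i, H, W))
  for (a in seq_len(H)) for (b in seq_len(W)) {
    rho <- sqrt(fv[a]^2 + fu[b]^2)
    Hm <- build_system_matrix(rho, stack$currents_mA, blur)
    Ivec <- vapply(Im, function(M) M[a, b], complex(1))
    Fvec <- multifocusr:::pinv_trunc(Hm, rcond) %*% Ivec
    for (k in seq_len(N)) Fs[[k]][a, b] <- Fvec[k]
  }
  Fs
}

# Binary support mask of a scene layer dilated by `by` pixels.
dilated_support <- function(layer, by = 4) {
  mask <- (layer > 0) * 1
  multifocusr:::conv_padded(mask, pillbox_kernel(by), as.integer(by) + 2L) > 1e-9
}
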