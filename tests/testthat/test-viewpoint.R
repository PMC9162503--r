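# Virtual-pinhole viewpoint synthesis, extended DoF, stereo rendering.

test_that("disparity is linear in beta and current", {
  b <- blur_model(12.7)
  expect_equal(disparity_px(0, c(10, 50), b), c(0, 0))
  expect_equal(disparity_px(0.25, 10, b), 31.75)
  expect_equal(disparity_px(0.3, 20, b), 2 * disparity_px(0.3, 10, b))
  expect_equal(disparity_px(-0.3, 10, b), -disparity_px(0.3, 10, b))
})

test_that("single-layer viewpoints are exact circular shifts at integer disparities", {
  sc <- single_layer_scene(j = 10)
  st <- simulate_stack(sc, blur_model(0.5))
  sp <- solve_layer_spectra(st, blur_model(0.5))
  img <- sc$layers[[1]]
  # beta 0.4 * R0 0.5 * j 10 = 2 px rightward
  v <- synthesize_viewpoint(sp, 0.4, 0, pad = 0)
  expect_lt(max(abs(v - img[, c(63, 64, 1:62)])), 1e-9)
  # vertical: 2 px upward
  vy <- synthesize_viewpoint(sp, 0, 0.4, pad = 0)
  expect_lt(max(abs(vy - img[c(3:64, 1, 2), ])), 1e-9)
})

test_that("fractional shifts match band-limited interpolation", {
  # smooth band-limited layer: analytic shift available in closed form
  n <- 64
  g <- function(sh) {
    x <- multifocusr:::fft_freq(n) * n
    Re(stats::fft(stats::fft(exp(-(x %% n - 20)^2 / 18)) *
                  exp(-2i * pi * sh * multifocusr:::fft_freq(n)),
                  inverse = TRUE)) / n
  }
  layer <- matrix(g(0), n, n, byrow = TRUE) * 10 + 1
  st <- multifocus_stack(list(layer), 10, registered = TRUE)
  sp <- solve_layer_spectra(st, blur_model(0.5))
  v <- synthesize_viewpoint(sp, 0.13, 0, pad = 0)  # 0.65 px shift
  expected <- matrix(g(0.65), n, n, byrow = TRUE) * 10 + 1
  expect_equal(v, expected, tolerance = 1e-9)
})

test_that("the centred viewpoint is the extended-DoF image and conserves energy", {
  sc <- small_scene()
  st <- simulate_stack(sc, test_blur())
  sp <- solve_layer_spectra(st, test_blur())
  edof <- synthesize_viewpoint(sp, 0, 0)
  expect_equal(edof, extended_dof(st, test_blur()), tolerance = 1e-12)
  # DC conservation: output energy equals the mean slice energy
  Emean <- mean(vapply(st$slices, total_energy, numeric(1)))
  expect_lt(abs(total_energy(edof) - Emean) / Emean, 1e-6)
  # single-slice stack: extended DoF is the slice itself
  st1 <- simulate_stack(single_layer_scene(), test_blur())
  expect_equal(extended_dof(st1, test_blur()), st1$slices[[1]],
               tolerance = 1e-9)
})

test_that("every synthesized viewpoint preserves the centred reconstruction's energy", {
  sc <- small_scene()
  sp <- solve_layer_spectra(simulate_stack(sc, test_blur()), test_blur())
  E0 <- total_energy(synthesize_viewpoint(sp, 0, 0))
  for (b in list(c(0.5, 0), c(-0.5, 0), c(0.25, -0.25), c(0, 1))) {
    Eb <- total_energy(synthesize_viewpoint(sp, b[1], b[2]))
    expect_lt(abs(Eb - E0) / E0, 1e-6)
  }
})

test_that("extended DoF is simultaneously sharp where single slices are not", {
  sc <- bead_scene(seed = 5)
  st <- simulate_stack(sc, test_blur())
  edof <- extended_dof(st, test_blur())
  # sharpness: high-pass residual energy within each ring's support
  hp <- function(img, mask) {
    low <- multifocusr:::conv_padded(img, pillbox_kernel(2), 4)
    sum(((img - low)[mask])^2)
  }
  for (k in 1:3) {
    mask <- dilated_support(sc$layers[[k]], by = 3)
    s_true <- hp(sc$layers[[k]], mask)
    expect_lt(abs(hp(edof, mask) - s_true) / s_true, 0.10)
  }
  # in any single input slice at least one ring is badly blurred
  worst <- vapply(1:3, function(slice) {
    min(vapply(1:3, function(k) {
      mask <- dilated_support(sc$layers[[k]], by = 3)
      hp(st$slices[[slice]], mask) / hp(sc$layers[[k]], mask)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(worst < 0.5))
})

test_that("out-of-pupil viewpoints are rejected", {
  sp <- solve_layer_spectra(simulate_stack(single_layer_scene(), test_blur()),
                            test_blur())
  expect_error(synthesize_viewpoint(sp, 1.5, 0), "physical meaning")
  expect_error(synthesize_viewpoint(sp, 0.3, -1.2), "physical meaning")
  z <- sp; z$F[[1]][] <- 0i
  expect_equal(synthesize_viewpoint(z, 0.5), matrix(0, 64, 64))
})

test_that("stereo pairs follow the baseline convention", {
  sc <- small_scene()
  st <- simulate_stack(sc, test_blur())
  pair <- stereo_pair(st, test_blur(), baseline_fraction = 0.5)
  sp <- solve_layer_spectra(st, test_blur())
  # B = R/2 means views at beta_x = +/- 0.25
  expect_equal(pair$left, synthesize_viewpoint(sp, 0.25), tolerance = 1e-12)
  expect_equal(pair$right, synthesize_viewpoint(sp, -0.25), tolerance = 1e-12)
  # zero baseline: both eyes see the extended-DoF image
  p0 <- stereo_pair(st, test_blur(), 0)
  expect_equal(p0$left, p0$right)
  expect_equal(p0$left, extended_dof(st, test_blur()), tolerance = 1e-12)
  # negated baseline swaps the eyes exactly
  pn <- stereo_pair(st, test_blur(), -0.5)
  expect_identical(pn$left, pair$right)
  expect_identical(pn$right, pair$left)
  expect_error(stereo_pair(st, test_blur(), 2.5), "2R")
})

test_that("stereo disparity sits in the moving layer and vanishes in the static one", {
  sc <- bead_scene(seed = 2)   # layers at 50, 100/3, 0 mA
  st <- simulate_stack(sc, test_blur())
  pair <- stereo_pair(st, test_blur(), baseline_fraction = 0.5)
  m50 <- dilated_support(sc$layers[[1]], by = 5)
  m0 <- dilated_support(sc$layers[[3]], by = 5)
  d50 <- measure_disparity(pair$left, pair$right, mask = m50)
  d0 <- measure_disparity(pair$left, pair$right, mask = m0)
  expect_equal(d50[["dx"]], 2 * 0.25 * 0.2 * 50, tolerance = 0.02)
  expect_lt(abs(d0[["dx"]]), 0.1)
})

test_that("stereo renderings follow their display conventions", {
  sc <- small_scene()
  pair <- stereo_pair(simulate_stack(sc, test_blur()), test_blur(), 0.5)
  ce <- render_stereo(pair, "cross_eye")
  pl <- render_stereo(pair, "parallel")
  expect_equal(ncol(ce), 128)
  expect_equal(ncol(render_stereo(pair, "cross_eye", gutter = 8L)), 136)
  # cross-eye swaps the panels of parallel
  expect_equal(ce[, 1:64], pl[, 65:128])
  expect_equal(ce[, 65:128], pl[, 1:64])
  # anaglyph of identical eyes is neutral (all channels equal)
  p0 <- stereo_pair(simulate_stack(sc, test_blur()), test_blur(), 0)
  an <- render_stereo(p0, "anaglyph")
  expect_equal(an[, , 1], an[, , 2])
  expect_equal(an[, , 2], an[, , 3])
  expect_error(render_stereo(pair, "wiggle"), "arg")
})

test_that("viewpoint sweeps reuse one solve and traverse serpentine", {
  sc <- small_scene()
  st <- simulate_stack(sc, test_blur())
  one <- sweep_viewpoints(st, test_blur(), 0, 0)
  expect_length(one, 1)
  expect_equal(one[[1]], extended_dof(st, test_blur()),
               ignore_attr = TRUE, tolerance = 1e-12)
  frames <- sweep_viewpoints(st, test_blur(),
                             seq(-0.2, 0.2, length.out = 3),
                             seq(-0.2, 0.2, length.out = 3))
  expect_length(frames, 9)
  bx <- vapply(frames, attr, numeric(1), "beta_x")
  expect_equal(bx[1:3], c(-0.2, 0, 0.2))
  expect_equal(bx[4:6], c(0.2, 0, -0.2))  # serpentine reversal
  # mirrored viewpoints carry opposite per-layer shifts
  sp <- solve_layer_spectra(simulate_stack(single_layer_scene(j = 10),
                                           blur_model(0.5)), blur_model(0.5))
  vp <- synthesize_viewpoint(sp, 0.3)
  vm <- synthesize_viewpoint(sp, -0.3)
  d <- measure_disparity(vp, vm)
  expect_equal(d[["dx"]], 2 * 0.3 * 0.5 * 10, tolerance = 0.02)
})
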