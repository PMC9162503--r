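---
title: "Multifocus reconstruction: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifocus reconstruction: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multifocusr)
```

## The problem

Wide-field fluorescence microscopy of thick samples — multicellular tumor
spheroids stained with a nuclear dye are the motivating case — suffers from
a shallow depth of field: no single image shows the whole 3-D structure in
focus. An electrically focus-tunable lens (EFTL) placed between the
objective and the sensor sweeps the focal plane non-mechanically: its
optical power $P$ varies approximately linearly with drive current $j$, so
a current sweep acquires a multifocus stack $i_1, \dots, i_N$ with neither
the sample nor the optics moving.

`multifocusr` turns such a stack into (i) per-plane in-focus layers,
(ii) an extended depth-of-field (all-in-focus) image, (iii) arbitrary
virtual-pinhole viewpoints, and (iv) stereoscopic pairs — with no
depth-map estimation and no segmentation of in-focus regions.

## Optics of the tunable-lens microscope

With objective focal length $f_{MO}$, EFTL-to-sensor distance $D$ and
objective-to-EFTL distance $d$, the combined system has equivalent power

$$f_{eq}^{-1} = f_{MO}^{-1} + P - f_{MO}^{-1} P d,$$

and the conjugate object plane sits a distance

$$z = \frac{-f_{MO}\,P\,(D - P^{-1})}{P^{-1} f_{MO}^{-1} + (D - P^{-1})\,f_{eq}^{-1}}$$

from the working-distance plane, imaged with lateral magnification

$$M = P^{-1} f_{MO}^{-1} + (D - P^{-1})\,f_{eq}^{-1}.$$

A note on this grouping of terms: the quotient form above is adopted
because, with the default constants ($f_{MO} = 9$ mm, $D = 10$ cm,
$d = 5$ cm, $P \in [-2, 3]$ diopters), it reproduces both instrument-scale
aggregates simultaneously — a focusing range of about 210 µm and a maximum
relative magnification change of about 16%:

```{r optics}
focusing_range(optics_config())
relative_magnification_change(optics_config())
```

Algebraically the $P^{-1}$ terms in $M$ cancel, leaving $M$ affine in $P$
— so the extrema over a power interval always sit at its endpoints.
$P = 0$ is nonetheless excluded from the valid domain (the formulas as
written are singular there) and rejected with a clear error. All internal
computation is in SI units; the public API takes mA, mm, cm and µm with
units named in every parameter.

The sign convention of $z$ follows the formula as written; only the range
$|z(P_{max}) - z(P_{min})|$ is physically anchored, and `focusing_range()`
reports min, max and range so either convention can be read off.

## Registration by conservation of energy

Because the illumination path is unaffected by the EFTL, total radiant
energy (the intensity integral) is the same in every slice; only the
magnification — hence the field of view — changes with current.
`register_stack()` exploits this with two modes:

* **model** (default): geometric zoom by the ratio $M(j_{ref})/M(j_k)$
  predicted by the optics model — deterministic, no estimation — followed
  by an exact multiplicative intensity equalization against the reference
  slice.
* **energy**: the geometric factor is estimated as $\sqrt{E_{ref}/E_k}$
  (a zoom by $s$ scales the enclosed energy by $s^2$), again followed by
  exact multiplicative equalization. Uses no optics metadata.

The trailing multiplicative step is what makes the post-registration
energy match exact rather than interpolation-limited; the recorded
`scale_factors` and `intensity_factors` attributes keep the transform
auditable. Zooming is bicubic (Catmull–Rom) about the image centre on the
fixed canvas, with zeros outside the source support and a shared transform
across RGB channels. A geometric factor outside $[0.5, 2]$ triggers a
warning — it almost always indicates wrong metadata rather than a real
field-of-view change.

## Image formation and the bead phantom

The scene is modelled as piecewise planar: layer $f_k$ is sharp in slice
$k$ and contributes to slice $k'$ through a pillbox (uniform disc) PSF
whose radius grows linearly with current difference,

$$i_k = f_k + \sum_{k' \neq k} h_{kk'} * f_{k'}, \qquad
  r_{kk'} = R_0\,|j_k - j_{k'}| \ \text{px},$$

with a single effective coefficient $R_0$ (px/mA) folding together pupil
aperture, magnification-per-current slope and pixel pitch. Noise and
chromatic aberration are neglected; an optional additive Gaussian term
(default off) supports robustness experiments only.

`simulate_stack()` implements this forward model with FFT convolution on
a canvas padded by the maximum blur radius, and `bead_scene()` generates
the test phantom: three rings of disc-shaped fluorescent beads, each ring
on its own focal plane. Phantom defaults — 256×256 canvas, ring radii
40/65/90 px, 12 beads of radius 3 px per ring, intensity 200 on an
8-bit-like scale, currents 50, 100/3 and 0 mA — are chosen so that beads
of different layers never overlap and all blurred content stays clear of
the canvas border (which is what makes the forward simulation
energy-conserving to numerical precision). With the angular jitter
disabled the phantom is mirror-symmetric about the vertical axis, which
the symmetry diagnostics use.

For round-trip experiments the blur coefficient is $R_0 = 0.2$ px/mA,
putting the adjacent-plane blur radii at 3.3 and 6.7 px — large enough
that slices are clearly distinguishable, small enough that discrete discs
are well resolved.

What the phantom does **not** emulate: photon (Poisson) noise, PSF
anisotropy or aberrations, depth-continuous structure between planes,
occlusion (layers combine additively), and the autofluorescent background
of real tissue. Passing tests therefore demonstrate correctness of the
algorithmic chain under the stated model, not robustness to everything a
real microscope produces.

## Layer separation by truncated pseudoinversion

In the Fourier domain the model couples the slice spectra $I_k(u,v)$ to
the unknown sharp-layer spectra $F_k(u,v)$ through an $N \times N$
symmetric matrix with unit diagonal whose entries are the pillbox
transfer values at radial frequency $\rho = \sqrt{u^2 + v^2}$:

$$\vec I(u,v) = H(u,v)\,\vec F(u,v), \qquad
  H_{kk'} = \frac{2 J_1(2\pi r_{kk'} \rho)}{2\pi r_{kk'} \rho}.$$

$H$ is singular at DC (all-ones matrix) and near-singular at low $\rho$,
so the solver uses the minimal-norm least-squares (Moore–Penrose)
solution $\vec F = H^\dagger \vec I$ per frequency bin. Numerical
choices:

* **Cutoff.** Singular values below `rcond` times the largest are
  truncated; the default `rcond = 1e-3` regularizes the band of low
  frequencies where defocus discs of different slices are practically
  indistinguishable. At DC the truncated pseudoinverse of the all-ones
  matrix is $J/N^2$, which fixes each $F_k(0,0)$ to the slice-mean DC —
  the origin of the pipeline's exact energy bookkeeping.
* **Grouping.** $H$ depends on $(u,v)$ only through $\rho$, so bins are
  grouped by the exact integer key $(k_u H)^2 + (k_v W)^2$ and each
  distinct matrix is pseudo-inverted once. Only exact collisions are
  merged, so the grouped solution equals the per-bin solution to machine
  precision (the test suite checks this against an independent per-bin
  solver).
* **Transfer-function split.** The inversion uses the continuous
  closed-form (jinc) transfer function while the simulator uses the
  rasterized, area-antialiased pillbox. Their high-frequency mismatch
  (max ≈ 0.06 at $r = 2$ px, shrinking roughly like $1/r$; dominated by
  the pixel-footprint sinc rolloff) is deliberate: round-trip tests are
  then honest inversions rather than inverse crimes.
* **Edge taper.** An optional Tukey window (`taper`, default off) damps
  wrap-around ringing from the periodic-convolution assumption for real
  stacks whose content touches the border. It is a deviation knob, not
  part of the model.

A consequence worth knowing: per-layer attribution is fundamentally
ambiguous below the defocus-discrimination frequency
($\rho \lesssim \sqrt{3\,\mathrm{rcond}}/(\pi r_{adj})$, about 0.005
cycles/px at the defaults). Scene content at those frequencies — e.g. the
default phantom's ring envelope at ~1/90 cycles/px — is split across
layers by the minimal-norm solution, so individual recovered layers carry
a smooth low-amplitude residue (squared-energy support concentration
stays above 95%, but per-layer relative L2 error is 7–20%). Viewpoint
syntheses, which *sum* the layers, cancel this residue almost entirely
(unit-scale MSE ~7×10⁻⁷ on the default phantom). Relatedly,
reconstruction error *grows* as $R_0 \to 0$: less defocus diversity means
worse conditioning, not an easier problem.

## Viewpoint synthesis and stereo

A virtual pinhole displaced a fraction $\beta$ of the pupil radius sees
layer $k$ displaced by the disparity $d_k = \beta R_0 j_k$ pixels, so a
new perspective is one inverse FFT of

$$S_{\beta}(u,v) = \sum_k e^{-i 2\pi j_k R_0 (\beta_x u + \beta_y v)}
  \left(H^\dagger \vec I\right)_k.$$

$\beta = 0$ is the extended-DoF image; $|\beta| \le 1$ is enforced
because displacements outside the aperture have no physical meaning.
Axes: $x$ = columns with positive $\beta_x$ shifting positive-current
layers rightward; positive $\beta_y$ shifts them upward. A stereo pair
with baseline $B$ uses $\beta_x = \pm B/(2R)$ ($B \le 2R$ enforced), and
`render_stereo()` offers cross-eye (left view on the right panel),
parallel, and red/cyan anaglyph conventions.

The phase-ramp shifts imply circular boundary conditions. The default is
the pure periodic formulation (`pad = 0`), under which every synthesized
viewpoint has exactly the energy of the centred reconstruction (the DC
bin is untouched by the ramps). An opt-in pad-and-crop guard
(`pad = "auto"` or a pixel margin) prevents content wrap for large
$\beta R_0 j$ products at the cost of clipping a sliver of the recovered
layers' global ringing (energy deviations up to ~10⁻⁴ were measured with
the guard on, which is why it is not the default). The global
magnification-at-zero-current factor in the disparity law is a constant
independent of $k$ and is ignored: views live on the registered pixel
grid.

## Evaluation

`evaluate_viewpoints()` runs the full pipeline
(simulate → separate → synthesize) against ground truth formed by
shifting the *true* layers with the same phase-ramp machinery — same
interpolation, so the comparison isolates inversion error. It reports
luminance MSE (Rec. 601 weights for RGB) on both the raw intensity scale
and a unit scale normalized by the dtype maximum, because published MSE
figures for comparable synthetic experiments do not state their intensity
normalization; absolute comparisons across implementations are therefore
qualitative. `measure_disparity()` provides the sub-pixel
cross-correlation estimator (band-limited interpolant refinement) used to
verify the parallax law $d = \beta R_0 j$ empirically.

## Problem sizes

The shipped tests run the full pipeline on the 256×256 three-ring phantom
(the configuration every quantitative claim refers to) and use 64×64 and
32×32 variants where a property is geometry-independent — e.g. the
grouped-versus-per-bin solver equality, which is checked bin by bin. The
whole suite completes in well under a minute on a single core.

## Known limitations

* Registration corrects isotropic scale only — by design, since the EFTL
  causes no lateral displacement; rotation/translation are out of scope.
* The additive layered model ignores occlusion; opaque samples violate it.
* $R_0$ is a config input; calibrating it for a given instrument is not
  part of the package.
* Per-layer recovery (as opposed to viewpoint synthesis) degrades for
  scenes whose structure lies below the defocus-discrimination frequency,
  as quantified above.
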