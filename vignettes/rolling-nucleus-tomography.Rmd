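---
title: "Rolling-nucleus phase-contrast tomography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rolling-nucleus phase-contrast tomography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holotomo)
```

# The measurement model

A transparent specimen imaged in off-axis digital holography imprints an
optical phase delay
$$\varphi(x, y) = \frac{2\pi}{\lambda}\int \Delta n(x, y, z)\, dz$$
on the object beam. The recorded intensity is the interference
$H = |R + O|^2 = |R|^2 + |O|^2 + R^*O + RO^*$ with a tilted plane-wave
reference $R$; the tilt shifts the $R^*O$ term away from the spectral
origin, so a circular window around the carrier peak isolates the complex
object field, and $\psi_O = \arg\{C\}$ after refocusing is the quantitative
phase map (QPM). Refocusing uses the angular-spectrum operator
$\hat U(z) = \hat U(0)\, e^{i 2\pi z \sqrt{1/\lambda^2 - f_x^2 - f_y^2}}$
(evanescent components zeroed), and the best-focus plane maximizes the
Tamura coefficient $\sqrt{\sigma/\mu}$ of the chosen image representation.

During dehydration the cell's nucleus — modelled as a rigid triaxial
ellipsoid with semi-axes $a \ge b \ge c$ — rolls about its major axis,
which lies in the image plane. The projection of the rotated ellipsoid is an
ellipse with a constant major axis $2a$ and a minor axis
$$l(\beta) = 2\sqrt{b^2\cos^2\beta + c^2\sin^2\beta},$$
so the per-frame minor-axis lengths $l_k$ fold the rolling angle into
$[0^\circ, 90^\circ]$:
$$\beta = \arccos\sqrt{\frac{(l/2)^2 - c^2}{b^2 - c^2}}.$$
Every extreme of the $l_k$ curve marks the passage of a $90^\circ$ cell
boundary; reflecting $\beta_k$ segment by segment and adding $90^\circ$ per
passed extreme yields monotone rolling angles $\theta_k$. The lookup
semi-axes $b$ and $c$ are half the largest and smallest observed minor-axis
length, which pins $\theta$ at the global extrema to exact multiples of
$90^\circ$. Extrema that do not come within tolerance of the global
minimum/maximum arise when the true extreme falls between frames; the angle
at such a frame is indeterminate and the frame is dropped.

The aligned, centred projections and the angles $\theta_k$ feed a filtered
back-projection: each slice perpendicular to the rotation axis is
reconstructed from its 1D phase profiles with a ramp filter, and the
line-integral density $g$ (rad/µm) converts to refractive index as
$n = n_{bg} + g\lambda/2\pi$ under the straight-ray assumption. Dry mass
follows the refraction-increment relation $m_d = (\bar n - n_w)V/\alpha$.

## Key assumptions

* **Rigid, single-axis, in-plane rotation.** Checked at run time: the
  coefficient of variation of the major-axis lengths must stay below 3 %
  (`check_major_axis_constancy()`), otherwise the sequence is flagged.
* **Straight-ray projection.** Diffraction within the specimen is ignored;
  no Born/Rytov correction. Adequate for nuclei a few tens of µm across at
  RI contrasts of a few 0.01.
* **Monotone accumulated rotation.** The sign of rotation is unobservable
  from projections; $\theta_k$ is the accumulated magnitude and
  reconstructions are defined up to a mirror reflection along the optical
  axis (all reported statistics are invariant to it).
* **Observable fold.** If $b = c$ (circular cross-section) the rotation is
  invisible and `invert_angle()` refuses; a sequence without at least one
  extreme (rotation < 90°) cannot be anchored and errors.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `wavelength` | 0.532 | µm | green laser line of the reference instrument |
| `pixel_size` | 0.17 | µm | image-plane sampling of the reference instrument |
| `background_ri` | 1.368 | — | measured cytoplasm RI; the tomographic background |
| `n_w` | 1.334 | — | RI of water in the dry-mass relation |
| `alpha` | 0.2 | µm³/pg | refraction increment of protein/DNA (0.2 ml/g) |
| `threshold_frac` | 0.1 | — | phase threshold above background as a fraction of the peak excursion; scales out of the angle inversion because $b, c$ come from the same biased lengths |
| `smooth_window` | 3 | frames | moving average used for extrema *detection* only; the unsmoothed $l_k$ feed the inversion |
| `global_tol` | 0.02 | fraction of range | how close to the series min/max an extreme must be to count as global |
| `min_prominence` | 0.1 | fraction of range | adjacent extrema pairs with smaller amplitude are cancelled as noise wiggles |
| `filter` | Ram-Lak | — | quantitative interior RI; Hann available when noise dominates |
| `delta` | 0.005 | RI | nucleus segmentation excess over background |

# What the phantom emulates — and what it does not

`phantom_spec()` renders the analytic phase projection of a rigid
two-ellipsoid model (uniform nucleoplasm contrast 0.022 over 1.368, a
denser nucleolus at +0.02) rotated through a user-given angle schedule,
with i.i.d. Gaussian phase noise. Defaults mirror the reference nucleus:
major axis $2a = 23.44$ µm, projected minor axis between 14 and 7 µm, and
a 26-frame schedule spanning 300°. Closed-form chords make the renderer an
exact oracle; an independent voxel-summation renderer cross-checks it. A
`schedule_sinusoidal()` velocity profile reproduces the unevenly spaced
extrema seen when rotation accelerates and slows.

The phantom establishes *algorithmic* correctness: segmentation bias,
angle-recovery error, reconstruction fidelity, morphometric accuracy. It
does **not** emulate spatially correlated coherent noise, cytoplasmic
clutter around the nucleus, wall/membrane structures, slow nucleus
deformation, or out-of-plane rotation-axis drift. Passing the phantom
suites therefore bounds method error, not instrument error; on real data
the segmentation threshold and the major-axis constancy check are the
first things to inspect.

The true angular-velocity profile of a rolling nucleus is unknown, so the
schedule is user-specified; uniform increments are the default study
condition and a sinusoidal modulation is available for stress-testing the
local-extreme bookkeeping.

# Numerical choices

* **Demodulation window**: circular, radius half the carrier magnitude,
  raised-cosine edge (30 % of the radius). Sub-bin carrier residuals are
  removed with the median wrapped phase gradient, and the background phase
  is zeroed by the median over an 8-pixel border ring.
* **Phase unwrapping**: unweighted least-squares (DCT/Poisson) unwrapping,
  applied when the wrapped-gradient check fails (any $|\nabla\varphi| >
  \pi/2$ per pixel and a range beyond $2\pi$), then made congruent to the
  wrapped input modulo $2\pi$.
* **Autofocus**: Tamura of the wrapped-aware phase-gradient magnitude
  (default) or of the amplitude-gradient magnitude; both representations
  are non-negative and insensitive to the arbitrary global phase. The
  metric is evaluated away from the frame borders because periodic (FFT)
  propagation wraps energy in from the edges at large defocus; search
  ranges should stay comparable to the frame extent. Coarse grid, then
  golden-section refinement; ties break toward the smallest $|z|$; a
  non-unimodal coarse curve returns the grid maximum with a warning.
* **Logistic fit**: Levenberg–Marquardt with free asymptotes, initialized
  from data quantiles (midpoint-crossing time, slope-based rate).
  Normalization happens before fitting by default; fitting the raw values
  first is available (`normalize = "after"`).
* **Extrema bookkeeping**: detection on the lightly smoothed curve;
  persistence pruning cancels adjacent low-amplitude extrema pairs
  (noise); plateaus from frames straddling an extreme symmetrically record
  the extreme at the earlier frame. Frames at local extrema are invalid.
  Small noise-induced decreases of $\theta_k$ are repaired by a running
  maximum.
* **Inversion clipping**: lengths outside $[2c, 2b]$ by up to 2 % of
  $(b - c)$ are clipped with a warning; larger excursions error.
* **FBP at non-uniform angles**: angles folded to $[0^\circ, 180^\circ)$
  via $p(t;\theta + 180^\circ) = p(-t;\theta)$; trapezoidal local-spacing
  weights normalized to total $\pi$, which keeps interior RI on scale for
  limited-angle spans (the 130° scenario) at the cost of wedge blur;
  4× zero-padding in the ramp filtering suppresses circular-convolution
  leakage of the filter tails (integrated optical mass is then conserved
  to ~1 %); values below $n_{bg} - 0.02$ are clipped to the background
  with the raw volume retained.
* **Nucleolus threshold**: the antimode between the nucleoplasm mode and a
  high-RI mode at least 0.004 above it, accepted only if the valley dips
  at least 10 % below the smaller mode; otherwise an upper-quantile
  fallback (0.9). Largest connected component kept (3D labelling via
  per-slice components merged by union-find).
* **Principal axes**: $2\sqrt{5\,\mathrm{eig}}$ of the voxel-coordinate
  covariance — exact for a uniform solid ellipsoid; degenerate (coplanar)
  masks error. This convention is one of several plausible ones for
  published principal-axis tables, so small systematic offsets against
  other conventions are expected.
* **Statistics conventions**: population standard deviation for per-object
  RI statistics; sample (n−1) standard deviation in the multi-nucleus
  summary column of `report_table()`.
* **Rounding**: RI is carried at full precision; displaying it at 2
  decimals breaks the self-consistency of derived dry masses (1.39 vs
  1.3896 changes $m_d$ by several %), which is why dry-mass checks use
  unrounded means.

# Problem sizes used by the test-suite

The suites run phantoms at 96–160 px frames and reconstructions at 64³ to
128³ voxels with up to 180 views — sizes chosen so the full chain stays
comfortably within a desk-scale run while leaving discretization error well
below the asserted tolerances (interior RI to 0.002 at 128³/180 views;
median angle RMS ≤ 3° over 20 noisy phantoms at 110 px).

# Known limitations

* Limited-angle (< 180°) reconstructions are anisotropically blurred along
  the missing-wedge direction; the weight normalization restores the mean
  RI but not the shape fidelity, so limited-angle volumes carry larger
  segmentation uncertainty (the relaxed 0.005 RI tolerance).
* The angle at a local extreme is genuinely indeterminate (up to ~one frame
  step), so dense sampling near extrema is the main lever on angle
  accuracy.
* Nucleolar volume depends on the histogram-valley threshold; at RI
  contrasts below ~0.01 the valley becomes shallow and the quantile
  fallback dominates.
* No aberration compensation, no multi-wavelength phase unwrapping, no
  diffraction-aware (Born/Rytov) tomography, and no iterative
  limited-angle regularization.
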