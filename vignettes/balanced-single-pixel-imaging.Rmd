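---
title: "Balanced-detection single-pixel imaging: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balanced-detection single-pixel imaging: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(balancedSPI)
```

## The measurement model

A single-pixel camera images an $s \times s$ scene $X$ (here always with
$s$ a power of two) by displaying a sequence of spatial masks on a digital
micromirror device (DMD) and recording, for each mask, the total light it
passes on a single photodetector. We use the Walsh–Hadamard basis: $s^2$
orthogonal, separable, $\pm 1$-valued square-wave functions
$H_i = w_v w_u^{\top}$, indexed by their sequency pair $(u, v)$ — the
number of sign changes along rows and down columns, the square-wave
analogue of spatial frequency. The signed projections
$c_i = \langle X, H_i \rangle$ determine $X$ exactly through the
orthonormal synthesis $X = s^{-2} \sum_i c_i H_i$.

A binary mirror cannot display $-1$, so each function is split into the
complementary pair
$$H^{\pm} = \tfrac{1}{2}(E \pm H),$$
with $E$ the all-ones matrix; $H^+$ appears on one DMD reflection arm and
$H^-$ simultaneously on the other, and $H = H^+ - H^-$. Feeding both arms
into a balanced photodetector measures the analog difference
$I^+ - I^-$ directly, so one displayed pattern yields one signed
coefficient — half the pattern budget of showing $H^+$ then $H^-$
sequentially — and no photon is discarded: $I^+ + I^-$ is the full
collected flux at every instant.

With object illumination $P_0$ and a spatially homogeneous ambient
("parasite") term $N(t)$, the light at the DMD plane is
$F = P_0 X + N(t) E$ and the arm intensities are
$I^{\pm} = P_0 \langle X, H^{\pm}\rangle + N(t) \langle E, H^{\pm}\rangle$.
For every non-DC function, $H^+$ and $H^-$ each open exactly $s^2/2$
mirrors, so the parasite contribution is identical on both arms and the
balanced output
$$I^+ - I^- = P_0 \langle X, H_i \rangle$$
is exactly independent of $N(t)$. The one exception is the DC (all-ones)
function, whose pair is $H^+ = E$, $H^- = 0$: its balanced coefficient
absorbs the whole parasite flux. We expose this rather than hide it — the
DC coefficient only sets the recovered image's mean, which display
normalization discards anyway.

## Forward-model parameters

* `illumination_model()`: object power scale `p0` (radiometric units per
  scene unit, default 1); parasite baseline and ripple amplitude in the
  same units, ripple frequency 100&nbsp;Hz by default and sinusoidal — the
  behaviour of a mains-driven halogen lamp, whose intensity ripples at
  twice the 50&nbsp;Hz line frequency. Only the frequency is physically
  anchored; baseline and amplitude are scenario parameters. The invariant
  `baseline >= amplitude` keeps irradiance non-negative.
* `detection_config()`: mode (`balanced`, `single`,
  `sequential_complementary`), detector gain (V per irradiance unit,
  default 1), additive Gaussian read noise per sample (V), optional
  Poisson shot noise on each arm before subtraction. Real detectors have
  correlated and frequency-shaped noise; we model only these two terms.
* `acquisition_config()`: pattern rate 20&nbsp;kHz by default (the class
  of fast DMDs this emulates) and 4 ADC samples per pattern dwell,
  averaged into one coefficient. Pattern $i$ occupies the time slot
  $[i-1, i)/\mathrm{rate}$; the ripple is evaluated at sample midpoints,
  and video scenes advance by nearest-frame lookup at the slot midpoint.
* `adc_config()`: a uniform mid-cell quantizer with $2^{\text{bits}}$
  cells spanning `[v_min, v_max]`; inputs map to their cell centre
  (maximum in-range error of half a cell) and out-of-range inputs
  saturate to the extreme cells. Sixteen bits by default, the class of
  laboratory digitizers this emulates.

### Dynamic range and the dual-range converter

A single always-positive detector signal is a large DC pedestal (about
half the scene flux) with small informative oscillations on top; one
unipolar ADC range must span both, so the oscillations receive only a
fraction of the quantization levels. The balanced signal is centred on
zero, and a bipolar range matched to the oscillations uses every level
for information. The all-ones pattern is again the exception: it routes
the entire flux to one arm and would force the bipolar span open by
orders of magnitude. `adc_autorange()` therefore models a per-pattern
dual-range converter (`adc_pair`): a fine bipolar span fitted to the
non-DC measurements (10% headroom) and a coarse span for the single
total-flux slot. This is the modelling choice behind the claim that the
full dynamic range measures only the useful fluctuations; laboratory
acquisition systems switch ranges per channel or measure the total flux
separately.

One caveat found while studying the quantization comparison: on binary
high-contrast phantoms (bar targets), a single Walsh coefficient can
carry as much energy as the total flux, and many coefficients are exactly
zero — the deterministic quantizer then produces *correlated* errors that
happen to cancel in the subtractive schemes. The balanced-vs-single
dynamic-range comparison is therefore made on generic grayscale scenes,
where the usual variance arithmetic applies and the balanced scheme wins
by orders of magnitude in MSE.

## Reconstruction

* **Inverse transform** (`inverse_transform()`): exact synthesis from a
  full record; gain and `p0` are divided out first so images are in scene
  units. Single-detector records measured $\langle X, H^+\rangle$, so the
  signed coefficient is recovered as $2y_i - y_{\mathrm{DC}}$ before
  synthesis.
* **Zero-fill** (`zero_fill_reconstruct()`): unmeasured coefficients set
  to zero, then synthesis. No solver, hence the real-time display mode.
* **Min-TV** (`min_tv_reconstruct()`): solves
  $\min_x \mathrm{TV}(x)$ s.t. $\lVert \Phi x - y \rVert_2 \le \varepsilon$
  with anisotropic TV — the sum of absolute horizontal and vertical
  forward differences, replicate padding at the borders (last difference
  zero), declared so TV values are bit-comparable across implementations.
  The solver is a Chambolle–Pock primal-dual iteration with steps
  $\tau = \sigma = 1/\sqrt{8}$ (the gradient operator norm bound).
  Because the sensing rows are orthogonal with squared norm $s^2$,
  projection onto the constraint set is the closed form
  $x + \Phi^{\top}(y' - \Phi x)/s^2$, applied every iteration, so all
  iterates are feasible; the returned image is the lowest-TV feasible
  iterate seen, making the reported objective non-increasing. Defaults:
  $\varepsilon = 0$, relative-change tolerance $10^{-6}$, 2000 iterations
  maximum; non-convergence is flagged in the result, never silent. On
  tiny instances the optimum was cross-checked against an independent
  linear-programming formulation of the same problem.

## Undersampling

`select_low_sequency_subset()` keeps the $\lceil \rho s^2 \rceil$
functions with the lowest 2D sequencies (so a 20% ratio on a 64×64 basis
keeps 820 patterns). The 2D ordering is a design choice — 1D sequency does
not induce a canonical 2D order — and we rank by concentric shells:
$\max(u, v)$ first, ties by $u + v$, then $(u, v)$ lexicographically.
This mimics an ideal low-pass window, keeps the selection deterministic,
and always places the DC function first so zero-filled reconstructions
preserve the scene mean.

## Phantoms and what the simulations do not show

`render_bars()` produces axis-aligned binary bar targets (a resolution
test chart element); `render_pacman_video()` a moving disc with a wedge
mouth eating a shrinking pellet, rendered with hard edges to match
binary-looking laboratory scenes (an optional supersampling flag is
deliberately absent — edges are exact by construction). Both are
bit-reproducible functions of their parameters.

The phantoms are noise-free, perfectly registered, and spatially sparse
in gradient — favourable for TV recovery. Real scenes add optical blur,
speckle, non-uniform illumination and detector bandwidth effects that are
out of scope here, so passing these simulations demonstrates the
*relative* claims (immunity, dynamic range, pattern budgets, motion
robustness), not absolute fidelity on natural scenes.

## Study conditions used by the checks

The quantitative checks run at sizes a desk machine handles in seconds:
pattern-budget and exact-recovery checks at 64×64; the property-based
immunity, quantization, compressive-sweep and motion checks at 32×32. The
ambient-immunity scenario uses a parasite whose total collected flux
exceeds the object flux (baseline 1.0, ripple amplitude 0.8 in scene
units against a bar target of total flux 288); the compressive sweep uses
the anchored ratio of object light at five times the ambient power, with
80% ripple modulation and $10^{-2}$ V read noise; the motion check runs
the default cartoon at a 25 Hz scene frame rate against a 20 kHz pattern
rate. These were fixed once as the scenario definitions.

## Known limitations

* The parasite is spatially homogeneous by assumption; structured ambient
  light does not cancel and is not modelled.
* The DC coefficient absorbs parasite light in every mode; quantitative
  mean levels are only meaningful in parasite-free scenarios.
* The min-TV solver's equality projection relies on orthogonal pattern
  rows; it would need a least-squares inner solve for non-orthogonal
  (e.g. random) mask sets, which are provided for display purposes only.
* Timing arithmetic covers acquisition only; solver post-processing time
  is deliberately not budgeted.
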