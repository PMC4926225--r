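# balancedSPI

A desk-scale digital twin of a **balanced-detection single-pixel camera**.

Single-pixel imaging (SPI) recovers an image from scalar measurements: a
digital micromirror device (DMD) displays a sequence of binary masks and a
single photodetector integrates the light each mask passes. Every DMD
pattern automatically produces its binary complement on the second
reflection arm; routing both arms into a balanced photodetector measures
the *signed* Walsh–Hadamard projection of the scene in one shot. Compared
with classical one-arm schemes this

* cancels spatially homogeneous ambient ("parasite") light for every
  non-DC pattern — the complementary pair `H± = (E ± H)/2` satisfies
  `H⁺ − H⁻ = H` while both arms collect the same parasite flux;
* halves the pattern budget relative to showing each pattern and its
  complement sequentially (4096 instead of 8192 patterns for a lossless
  64 × 64 frame);
* centres the informative signal on zero, so a bipolar ADC range
  quantizes only the useful fluctuations instead of a large DC pedestal;
* uses the full photon flux: `I⁺ + I⁻` is the total collected light.

The package simulates this chain end to end — sequency-ordered
Walsh–Hadamard bases and their complementary binary pairs, an optical
forward model with a 100 Hz rippling parasite source, detector noise and
ADC quantization, and image recovery by exact inverse transform,
zero-filled synthesis, or total-variation (TV) minimization with
equality constraints

```
min TV(x)   subject to   ‖Φx − y‖₂ ≤ ε ,
```

solved by a primal-dual splitting with closed-form feasibility
projections. Synthetic phantoms (bar targets, a moving cartoon video),
fidelity metrics (`corr2`, MSE) and acquisition-timing arithmetic round
out the toolkit. See the vignette in `vignettes/` for the model and every
numerical choice.

## Worked example

Acquire a 64 × 64 bar target under an ambient source *stronger than the
object light* (baseline 1.0 and 80% ripple at 100 Hz per unit scene
flux), with balanced and single detection, then compress to 20%:

```r
library(balancedSPI)

basis   <- build_basis_2d(64)
target  <- render_bars(64, n_bars = 3, bar_width = 6)
ambient <- illumination_model(p0 = 1, parasite_baseline = 1,
                              ripple_amplitude = 0.8)

rec_bal <- simulate_acquisition(target, basis, illum = ambient)
rec_one <- simulate_acquisition(target, basis, illum = ambient,
                                det = detection_config("single"))
truth <- target$frames[[1]]
corr2(inverse_transform(rec_bal, basis)$image, truth)  # 1.000000
corr2(inverse_transform(rec_one, basis)$image, truth)  # 0.011260

subset <- select_low_sequency_subset(basis, 0.2)       # 820 patterns
rec_cs <- simulate_acquisition(target, basis, subset, illum = ambient)
cs <- min_tv_reconstruct(rec_cs, sensing_operator(basis, subset))
corr2(cs$image, truth)                                 # 0.9359
```

The balanced reconstruction is exact (the parasite cancels arm-to-arm at
every sample instant), while the single-detector image is destroyed by
the ripple. The 20% compressive acquisition takes 820 of 4096 patterns
and still recovers the bars at corr2 ≈ 0.94.

Acquisition timing at the 20 kHz DMD rate:

```r
acquisition_budget(sides = c(32, 64), ratios = c(0.2, 1))
#  side                     mode ratio pattern_count frame_time_s reported_hz reported_ms
#    64                 balanced   1.0          4096      0.20480           5         200
#    64 sequential_complementary   1.0          8192      0.40960           2         400
#    32                 balanced   1.0          1024      0.05120          20          50
#    32                 balanced   0.2           205      0.01025         100          10
#    64                 balanced   0.2           820      0.04100          20          40
```

A lossless 64 × 64 frame needs 4096 patterns (about 200 ms, 5 Hz);
sequential complementary acquisition doubles that; the 820-pattern 20%
mode runs a frame in 40 ms.

Command-line use (thin wrapper over the same functions):

```sh
Rscript inst/scripts/balancedspi.R timing
Rscript inst/scripts/balancedspi.R simulate --config cfg.yaml --out out/
Rscript inst/scripts/balancedspi.R reconstruct --record out/ --method min_tv
```

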