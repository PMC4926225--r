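Package: balancedSPI
Title: Digital Twin of a Balanced-Detection Single-Pixel Camera
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a single-pixel camera that projects complementary
    Walsh-Hadamard illumination patterns from the two reflection arms of a
    digital micromirror device and records their difference on a balanced
    photodetector.  The forward model covers object illumination, homogeneous
    time-varying ambient (parasite) light, detector noise, and ADC
    quantization with explicit dynamic-range accounting.  Images are
    recovered by the exact inverse Walsh-Hadamard transform, by zero-filled
    synthesis of undersampled coefficients, or by total-variation
    minimization with (relaxed) equality constraints.  Includes synthetic
    bar-target and moving-cartoon phantoms, acquisition-timing arithmetic,
    image-fidelity metrics, and command-style drivers for reproducible
    simulated experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, grDevices, png, tiff, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
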