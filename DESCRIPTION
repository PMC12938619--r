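Package: mpsharmonics
Title: Harmonic-Ratio Tissue Characterization for Magnetic Particle Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for magnetic particle spectroscopy
    (MPS) tissue characterization by the third-to-fifth harmonic ratio (H3/H5).
    Implements equilibrium Langevin magnetization of mono- and polydisperse
    superparamagnetic nanoparticle ensembles under a sinusoidal drive field, a
    physics-based synthetic generator of receive-coil voltage traces including a
    Debye (Brownian-relaxation) low-pass constraint, instrument gain, residual
    fundamental feedthrough and seeded Gaussian noise, the exact-bin windowed-FFT
    harmonic extraction chain, repeat-averaged ratio statistics, and benign versus
    malignant stratification with an explicit indeterminate band.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
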