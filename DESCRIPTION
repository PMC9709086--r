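Package: holostiff
Title: Acousto-Holographic Whole-Cell Stiffness Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and reconstruction pipeline for acousto-holographic
    stiffness mapping of transparent microscopic objects.  Synthetic phase
    objects (reference microbeads, cell-like blobs) are acoustically deformed
    and imaged through a simulated phase-shifting Mach-Zehnder interferometer;
    the recorded interferogram stacks are reconstructed into thickness maps,
    per-pixel displacement waveforms and whole-object stiffness maps via
    wavelet-based frame matching, stroboscopic binning, least-squares phase
    retrieval, DCT-Poisson phase unwrapping and linear-elastic inversion, with
    coefficient-of-determination comparison of stiffness distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
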