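Package: octfocus
Title: Axial Motion and Defocus Stabilization for OCT Retinal B-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop stabilization of axial motion and defocus for optical
    coherence tomography (OCT) retinal B-scan acquisition. Provides a physics
    simulator of the defocused retinal A-scan intensity profile (confocal point
    spread function, tissue attenuation, spectrometer sensitivity roll-off),
    synthetic two-band retina phantoms, Ornstein-Uhlenbeck motion and
    accommodation trajectories, a focus-robust edge-detection-map (EDM)
    pixel-shift axial registration stage, and a single-step deep deterministic
    policy gradient (DDPG) agent that predicts the defocus correction in
    diopters from averaged A-scan observations. Includes A-scan focus
    interpolation for fast fine-tuning on new retinal structures, simulated
    correction sessions with kymograph export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
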