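Package: efptycho
Title: Electron Fourier Ptychography: Simulation, Preprocessing and Exit-Wave Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end electron Fourier ptychography (eFP) for tilted-illumination
    transmission electron microscopy. Simulates tilt series of complex specimen
    phantoms through a partially coherent wave-transfer-function imaging model with
    a fluence-budgeted Poisson detector, preprocesses micrograph stacks (CTF-based
    defocus estimation, phase-correlation registration, compensation of the
    tilt-induced image shift), reconstructs the complex exit wave with a modified
    Ptychographic Iterative Engine whose image-amplitude update acts in real space
    and whose exit-wave update acts on an upsampled Fourier canvas, and evaluates
    reconstructions (synthetic-aperture redundancy maps, PSNR, circularly averaged
    power spectra, reflection I/sigma scores).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
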