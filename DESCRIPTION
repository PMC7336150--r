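Package: spectralgm
Title: Spectral Graph Model of Brain Oscillations on Structural Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Closed-form hierarchical linear model of regional brain activity
    spectra. Local excitatory/inhibitory neural assemblies are lumped into
    gamma-shaped transfer functions; long-range dynamics are obtained from the
    eigenmodes of a frequency-dependent complex Laplacian of the structural
    connectome, in which axonal conduction delays enter as phase factors. The
    package provides connectome I/O and synthetic connectome generators, the
    steady-state regional frequency response in closed form, simulated-annealing
    estimation of the seven global model parameters against empirical regional
    spectra, band-power and spatial-correlation analyses, sorted-cumulative
    eigenmode selection, and a command-line interface for reproducible runs.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
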