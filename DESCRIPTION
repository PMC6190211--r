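Package: iceobind
Title: Induced-Charge Electroosmotic Enhancement of Microfluidic Immunoassay Binding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.com")
Description: A 2D finite-element simulator for heterogeneous immunoassays
    stirred by induced-charge electroosmosis (ICEO) over a floating gate
    electrode. Solves the quasi-static complex-phasor Laplace problem with an
    RC double-layer charging condition on the gate, derives the time-averaged
    Helmholtz-Smoluchowski slip, drives steady incompressible Stokes flow with
    that slip, and integrates transient antigen advection-diffusion coupled to
    Langmuir surface-binding kinetics on a functionalized segment. Computes the
    binding enhancement factor Be and its dependence on drive voltage, field
    frequency, Damkohler number, gate height, and inlet Peclet number.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
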