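Package: romt
Title: Regularized Optimal Mass Transport for Dynamic 3D Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates time-varying velocity fields from a sequence of
    non-negative 3D volumes (e.g. dynamic contrast-enhanced MRI of
    glymphatic tracer transport) by solving a regularized optimal mass
    transport problem: the Benamou-Brenier kinetic-energy objective
    constrained by an advection-diffusion equation, discretized with a
    particle-in-cell advection step and an implicit-Euler diffusion step,
    and optimized with a matrix-free Gauss-Newton method. Includes a
    Lagrangian post-processing layer (pathlines, speed-lines,
    Peclet-lines, speed and Peclet maps, velocity flux vectors), a
    Gaussian-sphere phantom generator with approximate ground-truth
    intermediates for accuracy benchmarking, minimal NIfTI-1 volume I/O,
    and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    parallel,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
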