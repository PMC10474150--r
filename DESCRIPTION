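Package: quboCT
Title: QUBO and Ising Formulations of Computed-Tomography Image
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs parallel-beam computed-tomography (CT) images by
    recasting the sinogram least-squares problem as a quadratic
    unconstrained binary optimization (QUBO) or Ising model whose global
    minimum encodes the attenuation image consistent with the measured
    projections. Provides Shepp-Logan phantom generation, an exact
    overlap-area (strip-integral) forward projector with sparse system
    matrices, assembly of the QUBO from the squared sinogram residual over
    per-pixel bit expansions, the exact QUBO-to-Ising transform with offset
    bookkeeping, classical solvers (exhaustive enumeration, simulated
    annealing, tabu search) plus a file-based contract for external
    samplers, an end-to-end reconstruction pipeline with energy
    certificates and error maps, and plain-text interchange formats for
    images, sinograms, models and results.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
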