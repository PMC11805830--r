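Package: cartnode
Title: Dynamics of CAR T-Cells and B-Cell Lymphoma in a Lymph Node
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a two-population ordinary differential equation model
    of chimeric antigen receptor (CAR) T-cells interacting with diffuse large
    B-cell lymphoma cells in a lymph node compartment.  Provides the
    dimensional and dimensionless vector fields and exact maps between them,
    closed-form equilibria with existence, positivity and stability
    classification, analytic bifurcation curves (transcritical, fold,
    pitchfork, Hopf and the Bogdanov-Takens point) together with a
    numerically located homoclinic curve and a region classifier for the
    (m2, m5) parameter plane, trajectory integration with orbit-fate
    classification, limit-cycle detection, saddle-manifold and
    basin-of-attraction analyses defining the curable tumor burden, and a
    variance-based first-order Sobol sensitivity study of the first year
    after infusion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
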