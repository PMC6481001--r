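Package: chondrosim
Title: Reaction-Diffusion Simulation of TGF-beta Mediated Chondrogenesis in
    Layered Hydrogel Constructs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the chondrogenic differentiation of mesenchymal stem
    cells (MSCs) co-cultured with chondrocytes in a one-dimensional hydrogel
    scaffold bathed in culture medium. A reaction-diffusion model tracks MSC
    and chondrocyte densities together with the life cycle of transforming
    growth factor beta (TGF-beta): unbound latent, matrix-bound latent and
    active pools, plus receptor-bound fractions on both cell types.
    Differentiation is switched on when MSC receptor occupancy exceeds a
    threshold. The package provides the three canonical culture strategies
    (chondrocyte layer only, exogenous TGF-beta only, and their combination),
    stiff method-of-lines integration with event detection of the 90%
    differentiation time, chondrocyte-yield summaries, bisection searches for
    critical seeding densities and doses, two-parameter phase sweeps, and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
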