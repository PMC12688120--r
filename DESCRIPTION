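Package: dimerscale
Title: Ligand-Receptor Dimerization Equilibria and Response Heterogeneity Scaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Equilibrium models of ligand-receptor binding for monomeric,
    homodimeric and heterodimeric receptor architectures, together with a
    local scaling metric (the logarithmic derivative of the downstream
    response with respect to total receptor abundance) that quantifies how
    receptor-level cell-to-cell variability propagates into response
    heterogeneity. Includes a general mass-action equilibrium solver for
    arbitrary association networks (used for competitive inhibition and
    non-sequential heterodimer assembly), population simulations with
    gamma-distributed receptor levels, mean-matched ligand panel
    comparisons of the response coefficient of variation, and model
    extensions covering ligand-dependent receptor turnover, finite ligand
    pools and nonlinear downstream responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
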