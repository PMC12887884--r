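Package: fibrilBD
Title: Brownian Dynamics Prediction of Glycosaminoglycan Binding Sites
    on Amyloid Fibrils
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale multiscale modelling of glycosaminoglycan (heparin)
    binding to amyloid fibrils. Generates idealized parallel in-register
    fibrils with charged residue ladders and linear sulfated glycan chains,
    steers the glycan by Debye-Hueckel screened-Coulomb electrostatics in a
    rigid-body Brownian dynamics engine with a Northrup-Allison-McCammon
    style reaction criterion, then filters and clusters bound poses,
    computes salt-bridge contact statistics and unit/group-resolved contact
    frequency maps, tabulates per-site binding probabilities with binomial
    confidence intervals, regresses interaction energy on contact count,
    and accumulates sulfur density maps with OpenDX export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
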