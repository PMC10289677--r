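Package: crowdcell
Title: Crowding-Adjusted Reaction Kinetics and Optimal Cytosolic Occupancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the effect of macromolecular crowding on biochemical
    reaction kinetics and on the optimal dry-mass volume occupancy of a
    bacterial cytosol. Implements hard-sphere activity coefficients from
    scaled particle theory, size-dependent diffusion slowdown, and the
    resulting crowding-adjusted Michaelis parameter; an N-step pathway model
    (metabolic and ribosomal presets) with grid scans for the occupancy that
    maximizes flux per unit dry mass; a five-variable whole-cell balanced
    growth model (transporter, metabolic pathway, ribosome) whose growth rate
    is maximized at fixed occupancy by multi-start constrained optimization;
    and conversions between experimental dry-mass density, RNA/protein
    composition, and volume occupancy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
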