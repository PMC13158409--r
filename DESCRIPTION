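Package: slbtools
Title: Structural Analysis of Drug-Membrane Interactions on Supported Lipid Bilayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-contrast neutron reflectometry co-refinement of supported
    lipid bilayer slab models with drug intercalation and adsorbed layers,
    together with the companion analyses of a drug-membrane interaction study:
    partition-coefficient fitting from fluorescence titrations, Laurdan
    generalized-polarization dose series, nitroxide spin-label EPR parameter
    extraction, and AFM force-curve breakthrough detection. Includes a
    fully seeded synthetic-data generator for every input kind, a Parratt
    forward model with Nevot-Croce roughness and constant-relative resolution
    smearing, differential-evolution global optimization, ensemble MCMC
    posterior sampling, and reduced chi-squared model selection.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    signal,
    pracma,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
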