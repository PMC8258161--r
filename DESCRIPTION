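Package: fluxred
Title: Robustified Experimental Design of Isotope Tracer Experiments for 13C
    Metabolic Flux Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans informative and economic isotope labeling experiments for
    13C metabolic flux analysis when no reliable prior flux estimate exists.
    Given a metabolic network with carbon atom transitions, a GC-MS
    measurement configuration, and a priced catalogue of commercially
    available tracer species, the package enumerates candidate tracer
    mixtures on a simplex lattice and scores each one over a uniform sample
    of the entire feasible flux polytope: a median reference-normalized
    D-criterion, a coverage criterion (the fraction of sampled flux maps for
    which the mixture renders a given number of free fluxes statistically
    identifiable), and the tracer cost.  Labeling states are simulated by
    elementary metabolite unit (EMU) decomposition with an independent
    cumomer-cascade cross-check, sensitivities by implicit differentiation
    of the EMU cascade, and flux maps by hit-and-run sampling of the
    stoichiometric polytope.  Results are aggregated into tidy data pools
    for exploratory trade-off decisions between information and cost.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
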