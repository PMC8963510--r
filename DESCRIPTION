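Package: phytoclock
Title: Plant Circadian Clock Simulation of Light-Quality-Dependent Hypocotyl Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a compact model of the Arabidopsis circadian clock coupled
    to red/blue-light photoreceptor signalling (phyA, phyB, cry1), competitive
    binding of activated photoreceptors to the COP1/SPA E3-ligase complex, and
    PIF-driven hypocotyl elongation. Provides stiff integration over
    piecewise-constant light programs (constant conditions, photoperiod cycles
    and pulse protocols), free-running period estimation and rhythmicity
    classification, in-silico knockdown/overexpression genotypes, phase-response
    curves with advance/delay area ratios, photoperiodic hypocotyl growth
    experiments with min-max normalisation against measured seedling lengths,
    and weighted mean-squared-error parameter estimation by derivative-free
    optimisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    minpack.lm,
    pracma,
    jsonlite,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
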