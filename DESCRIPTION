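Package: oxex
Title: Stochastic Kinetics of Intermediate Pi-HOH Oxygen Exchange in
    F1-ATPase Catalysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Closed-form and stochastic modelling of the intermediate
    Pi-HOH oxygen exchange that accompanies ATP hydrolysis by F1-ATPase.
    Implements the fractional-extent kinetics of 18O uptake into released
    inorganic phosphate, Poisson-chain washout of 18O label from the
    gamma-phosphoryl group of ATP with closed-form isotopomer
    distributions, zero-intercept estimation of the apparent exchange
    rate constant from (velocity, 18O/P) data, least-squares selection of
    the number of simultaneously exchanging catalytic sites with
    detection of the short-time/long-time regime transition,
    Michaelis-Menten activity normalisation, an equilibrium
    catalytic-site occupancy model (trisite versus bisite filling from
    site-specific dissociation constants), and a seeded stochastic
    simulator of GC-MS style isotopomer observations for parameter- and
    structure-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
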