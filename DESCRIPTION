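Package: nabtiter
Title: Neutralizing-Antibody Titer Estimation for AAV Transduction-Inhibition Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cell-based AAV neutralizing-antibody
    assays run as two-fold serum dilution series on 96-well plates, in
    either the constant serum concentration (CSC) or the conventional
    variable serum concentration (VSC) format. Normalizes raw luminescence
    to format- and serotype-matched antibody-free controls, estimates ND50
    titers with 95% credible intervals by Bayesian four-parameter Hill or
    Bayesian linear-model fitting (with the sub-range censoring rule),
    stratifies serostatus under pool-eligibility and neutralization rules,
    tests CSC/VSC classification discordance with the exact McNemar test,
    and quantifies format differences with Cliff's delta and a Bayesian
    practical equivalence test on log2 ND50. Includes a synthetic plate
    generator that emulates serum matrix effects (transduction enhancement
    by serum pre-incubated with vector, inhibition by serum on cells) with
    recorded ground truth, so the full pipeline is testable without
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
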