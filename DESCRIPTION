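Package: pbpkddi
Title: Two-Compartment PBPK Simulation of CYP3A4-Mediated Drug-Drug
    Interactions and Spontaneous-Report Disproportionality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates drug disposition under a two-compartment model with
    first-order oral absorption and a well-stirred liver, and predicts
    victim-drug exposure changes under competitive CYP3A4 inhibition with
    gut-wall and hepatic inhibition separately toggleable, including the
    effect of staggered dosing.  Ships a triazole/cyclosporine example set
    (isavuconazole, voriconazole, cyclosporine).  Also provides
    nonlinear-least-squares fitting of compartmental parameters with AIC
    scoring, a spontaneous adverse-event report pipeline (deduplication,
    role-code and date filters, 2x2 contingency tables, reporting odds
    ratios with Woolf confidence intervals), therapeutic drug monitoring
    metrics (concentration/dose ratio, Japanese eGFR), and seeded synthetic
    data generators for every input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
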