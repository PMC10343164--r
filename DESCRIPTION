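Package: betalos
Title: Beta-Geometric Models and Heavy-Tail Diagnostics for Hospital Length of Stay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling hospital length of stay (LOS) as a shifted
    Beta-Geometric compound distribution: closed-form distribution functions,
    maximum-likelihood fitting, mixture fitting for policy-censored wards
    (truncated-Poisson body, point-mass spike, Beta-Geometric tail),
    Monte-Carlo goodness of fit with a discrete two-sample
    Kolmogorov-Smirnov test, extreme-value diagnostics (mean excess curves,
    maximum-to-sum ratios, exponential QQ plots of log data, empirical
    subexponentiality ratios), Lorenz/Gini concentration analysis with
    bootstrap uncertainty, charge-per-day analysis, admission-registry
    ingestion, and a seeded synthetic registry generator for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
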