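Package: bandgrowth
Title: Age and Growth of Batoids from Vertebral Band Counts
Version: 1.0.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for age-and-growth studies of elasmobranchs based on growth
    bands in vertebral centra: ageing precision statistics (percent agreement,
    average percent error, coefficient of variation, age-bias tables, Bowker's
    test of symmetry), band-periodicity analyses (marginal increment ratio,
    centrum edge analysis, Kruskal-Wallis with Dunn's post hoc, two-sample
    Kolmogorov-Smirnov), age adjustment to the reproductive cycle and date of
    capture, Francis proportion-based back-calculation, maximum-likelihood
    fitting of von Bertalanffy, Gompertz and logistic growth models under a
    multiplicative lognormal error with analytically concentrated sigma,
    likelihood-profile and likelihood-contour confidence intervals, and AIC
    multimodel selection with Akaike weights. Includes a synthetic-data
    generator emulating a seasonally pulsed batoid population and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
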