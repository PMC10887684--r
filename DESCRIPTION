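Package: wextropy
Title: Nonparametric Estimation of Weighted Extropy for Lifetime Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of weighted extropy, a shift-dependent uncertainty
    measure for positive lifetime data, by three nonparametric routes: a
    log-transformed kernel density estimator suited to skewed and
    heavy-tailed lifetimes, a standard kernel density estimator, and an
    empirical estimator built on spacings of squared order statistics.
    Includes Sheather-Jones plug-in and AMISE-optimal bandwidth selection,
    the asymptotic bias/variance theory of the log-kernel estimator, a
    reproducible Monte Carlo engine for bias/RMSE studies, parametric
    (maximum-likelihood plug-in) estimates, file readers and a small
    command-line interface, including a reliability-ranking workflow for
    competing repairable systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
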