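Package: ssgphc
Title: Multicomponent Stress-Strength Reliability under Generalized
    Progressive Hybrid Censoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inference for the reliability of s-out-of-j multicomponent
    stress-strength systems whose component strengths follow a Gompertz
    distribution and whose common stress follows a Chen distribution, with
    both samples observed under generalized progressive hybrid censoring
    (GPHC). Provides numerically stable distribution primitives, GPHC
    scheme representation and simulation, the system reliability integral
    R[s,j], maximum-likelihood estimation with asymptotic (delta-method)
    confidence intervals, exact pivotal confidence intervals built on
    F and chi-squared pivots of generalized spacings, Bayesian estimation
    by a Metropolis-Hastings-within-Gibbs sampler with highest posterior
    density intervals, and Monte Carlo study drivers. Includes a bundled
    reservoir-storage dataset analysed as a 1-out-of-6 system.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
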