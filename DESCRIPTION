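Package: bmitrend
Title: Hierarchical Bayesian Meta-Regression of BMI Category Prevalence Trends
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates national trends in the prevalence of body-mass-index
    categories from heterogeneous population surveys using a Bayesian
    hierarchical meta-regression with a probit-binomial likelihood, hierarchical
    linear time trends, second-order random-walk nonlinear change, cubic-spline
    age models and study-level offsets and random effects, fitted by a bespoke
    Metropolis-within-Gibbs sampler. Includes survey-record cleaning and
    design-aware aggregation, a synthetic survey-database generator for
    end-to-end testing, posterior post-processing (rescaling, age
    standardization, trend velocity, posterior probabilities), trajectory
    clustering with Jaccard stability analysis, and a held-out validation
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
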