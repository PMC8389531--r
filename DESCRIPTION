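Package: uqmd
Title: Forward Uncertainty Quantification for Ensemble Molecular Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dimension-adaptive stochastic collocation for propagating
    parametric uncertainty through expensive simulators such as ensemble
    molecular dynamics binding-affinity workflows. Provides nested
    Clenshaw-Curtis sparse grids with the combination technique, a
    variance-driven adaptive campaign runner with evaluation caching,
    Sobol sensitivity indices obtained by converting the collocation
    surrogate to an orthonormal Legendre expansion, aleatoric analysis of
    replica ensembles (probability boxes, envelope confidence intervals,
    skewness and kurtosis with bootstrap intervals), coefficient-of-variation
    robustness ratios with and without ensemble averaging, and a seeded
    synthetic binding-energy simulator plus standard analytic benchmarks
    (Sobol g-function, Ishigami) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    lhs,
    yaml,
    pracma,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
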