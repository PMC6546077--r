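Package: longqtl
Title: Functional Mapping of Quantitative Trait Loci for Longitudinal Traits
Version: 0.1.0
Authors@R: person("longqtl", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Interval mapping of quantitative trait loci (QTL) for
    function-valued (longitudinal) phenotypes in experimental inbred crosses
    (backcross, F2, recombinant inbred lines, doubled haploids). Genotype
    means follow parametric trajectories (logistic, double-logistic,
    Legendre, pharmacology; user-extensible) and residuals follow structured
    longitudinal covariance models (AR(1), ante-dependence, ARMA(1,1),
    compound symmetry, banded Toeplitz, independence). A finite mixture of
    multivariate normals is maximised by an EM algorithm at every 1 cM scan
    position, genome-wide significance is assessed by permutation with an
    optional correlation-based pre-filter, and a simulation module generates
    genotypes by Haldane recombination and phenotypes from genotype-specific
    curves plus structured noise.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    parallel,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
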