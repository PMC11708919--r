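Package: metfa
Title: Factor-Analytic Mixed Models with Environmental-Covariate Priors
    for Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bayesian sparse factor-analytic multivariate linear mixed
    models for genomic prediction in multi-environment trials (METs).
    The trait-by-experiment matrix is decomposed into latent factors
    whose per-experiment loadings are modelled as regressions on
    environmental covariates (state, tester, weather, kinship
    eigenvectors), so that genetic values of old or new genotypes can be
    predicted in old or new environments. Includes a Gibbs sampler with
    multiplicative-gamma shrinkage priors and full missing-data
    augmentation, kinship-based GBLUP baselines, the CV1/CV2/NewTrial/
    NewState/NewTester/NewGenoNewYear cross-validation scenarios,
    Hunter-Schmidt meta-analysis of per-experiment predictive
    abilities, a calibrated simulation generator for method evaluation,
    and MET preprocessing utilities (experiment splitting, outlier
    filtering, best linear unbiased estimates, parent genotype
    inference, VanRaden genomic relationship matrices, and
    growing-degree-day weather covariates).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    metafor,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
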