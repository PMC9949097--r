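Package: FcBindMix
Title: Multivalent Immune-Complex Binding, Affinity Inference, and
    Effector-Function Regression
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models the equilibrium binding of mixed-composition IgG immune
    complexes to cells bearing multiple Fc-gamma receptor species, using a
    generalized multi-ligand multivalent binding model with a phenomenological
    crosslinking constant. Provides Bayesian refinement of monovalent IgG-FcgR
    affinities from replicated immune-complex binding panels (lognormal priors
    built from documented affinities and their standard errors, MAP
    initialization, MCMC sampling), a regression linking model-predicted
    receptor multimerization on effector cell types to in vivo target-cell
    depletion through an exponential-CDF link, normalization and descriptive
    diagnostics for binding panels, and a synthetic-data generator emulating a
    432-condition factorial mixture design for end-to-end parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    coda,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Software, SystemsBiology, Bayesian, ImmunoOncology, Regression
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'FcBindMix-package.R'
    'binding-model.R'
    'diagnostics.R'
    'mcmc.R'
    'effector.R'
    'priors.R'
    'inference.R'
    'io.R'
    'synthetic.R'
    'pipeline.R'
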