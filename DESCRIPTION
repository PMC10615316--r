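Package: sindysio
Title: Identifiable and Interpretable Discovery of Rational ODE Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
                  email = "author@example.org")
Description: Distills structurally identifiable, observable and
    mechanistically interpretable ordinary differential equation models from
    time-series data. Implements implicit sparse regression (sequentially
    thresholded least squares over a candidate library containing derivative
    terms, with Pareto/AIC model selection), structural identifiability and
    observability analysis via the generic rank of the Lie-derivative
    observability-identifiability matrix (exact modular arithmetic at random
    specializations), detection and breaking of one-parameter Lie symmetries
    (translation, scaling, Moebius) by reparameterization, and symbolic
    reformulation of rational right-hand sides against a dictionary of
    canonical kinetic terms (mass action, Michaelis-Menten/Monod, Hill,
    saturating feedback). Ships six benchmark case studies from systems
    biology.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
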