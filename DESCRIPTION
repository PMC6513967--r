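Package: fasciclefit
Title: Bayesian Inference of Tendon Fiber-Scale Viscoelastic Properties
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers fiber-scale elastic modulus, matrix modulus and embedded
    fiber viscosity of tendon fascicles from fascicle-scale elastic,
    volumetric and stress-relaxation observations.  A standard-linear-solid
    relaxation model with a rule-of-mixtures elastic surrogate maps material
    parameters and a fascicle geometry class (fiber content, helix angle) to
    the observable quantities; a proportional-error Gaussian likelihood with
    uniform priors is sampled by Transitional Markov Chain Monte Carlo
    (TMCMC), yielding posterior samples, a model-evidence estimate and
    maximum a-posteriori (MAP) values.  Includes a synthetic-data generator
    for relaxation datasets, grid orchestration over model classes and
    datasets, and replay diagnostics of fitted relaxation curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
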