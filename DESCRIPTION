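Package: wmattractor
Title: Attractor Drift-Diffusion Analysis of Delayed-Estimation Working Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for continuous-report (delayed-estimation)
    working-memory experiments on a circular color wheel: task geometry and
    graded reward scoring, trial-table input/output, model-free behavioral
    statistics (performance matrices, chance-corrected circular precision and
    bias, Hodges-Ajne, Cochran's Q, binomial and Friedman tests, partial
    omega-squared effect sizes, serial-dependence curves), a three-component
    von Mises mixture model fitted by expectation-maximization, per-color
    Gaussian tuning fits, and a drift-diffusion attractor model of memory
    dynamics on the circle solved through its Fokker-Planck equation, with
    maximum-likelihood fitting, cross-validated model comparison and
    attractor extraction. Includes a synthetic-data generator that simulates
    sessions and responses from a known generative attractor model, serving
    both as a test bed and as a Monte-Carlo oracle for the Fokker-Planck
    engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    stats,
    utils,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
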