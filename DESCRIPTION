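Package: preflexr
Title: Muscle Preflex Analysis with a Hill-Type Hopping Model and Synthetic Fiber Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates perturbed single-leg hopping driven by a four-element
    Hill-type muscle-tendon unit to obtain physiological contractile-element
    boundary conditions, replays those kinematics through an isolated
    contractile element and through a synthetic skinned-fiber generator, and
    analyses the preflex phase of the resulting work loops: preflex mechanical
    work, short-range stiffness, post-short-range-stiffness work, and the
    dynamic-versus-quasistatic work difference, with a nonparametric
    statistics chain (Shapiro-Wilk, Friedman, pairwise sign tests with
    Bonferroni correction, Cohen's d).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
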