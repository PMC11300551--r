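Package: coopcost
Title: Expected Cost of Thresholded Institutional Incentives in Finite Populations
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the expected institutional cost of individual-based
    reward, punishment, and mixed incentives for promoting cooperation in
    well-mixed finite populations evolving under the pairwise-comparison
    (Fermi) update rule. Incentives are paid only while the number of
    cooperators is at or below a threshold t. Provides exact closed-form
    cost functions for t = 1 and t = 2 built on tridiagonal-inverse
    recurrences, the absorbing-chain fundamental-matrix route for any
    threshold, neutral-drift and strong-selection limits, fixation
    probabilities and the minimal incentive guaranteeing a target
    cooperation frequency, the constrained cost-minimisation problem, a
    seeded Monte-Carlo simulator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
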