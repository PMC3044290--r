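Package: hbstab
Title: Probabilistic Models of Hydrogen-Bond Stability from Molecular
    Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("hbstab", "maintainers", email = "hbstab@example.org",
           role = c("aut", "cre"))
Description: Learns protein-independent probabilistic models of hydrogen-bond
    stability from molecular-dynamics-style trajectories supplied as
    multi-model PDB files. Detects hydrogen bonds with configurable geometric
    criteria, computes per-occurrence predictors (geometry, a Mayo-form
    hydrogen-bond energy, sequence context and local environment counts) with
    trailing-window averaging against thermal noise, labels occurrences with a
    measured stability (the fraction of a future time window at which the bond
    persists), and fits binary regression trees by variance-reduction splits
    with adaptive validation-set pruning. Includes an evaluation suite (RMSE,
    relative base error decrease, identification curves for the least stable
    bonds, predictor importance, leave-one-protein-out protocols), a synthetic
    trajectory and table generator with exact ground truth, and a command-line
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
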