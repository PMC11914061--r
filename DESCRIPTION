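Package: slgcfate
Title: Stochastic Fate Modelling of Stomatal Lineage Ground Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how stomatal lineage ground cells (SLGCs) in
    the Arabidopsis leaf epidermis decide between asymmetric division and
    differentiation. Provides a synthetic cohort generator with known ground
    truth, per-cell measurement routines (nuclear-size allometry, SPCH decay
    constants, percent decline, intensity dip detection, photobleaching rate,
    neighbour contact fractions), a CART classifier with Gini splitting and
    minimal cost-complexity pruning plus bagged-forest feature importances, a
    stochastic one-generation lineage simulator with four SPCH degradation
    modes and logistic fate rules, and a three-step statistical model-selection
    procedure (TOST equivalence, Welch t-tests, SSE with AICc ranking).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    zoo,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    rpart,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
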