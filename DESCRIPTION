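Package: lowrankCDM
Title: Low-Rank Recurrent Network Models of Context-Dependent Decision-Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and mechanistic analysis of rate recurrent neural
    networks performing a pulse-based context-dependent decision-making task.
    Provides the task generator (Poisson pulse trains with per-trial location
    and frequency probabilities), full and latent low-rank network simulation,
    gradient-based training of rank-constrained and full-rank networks,
    linearized dynamical-systems analysis (slow points, line attractor,
    selection vector, classical contextual-modulation decomposition), a
    pathway-based information-flow analysis (effective couplings between task
    variables, pathway selection vector, pathway modulation decomposition,
    closed-form pulse responses), mean-field constructors for networks with a
    prescribed ratio of input to selection-vector modulation, activity-level
    signatures (response-kernel regression, SVD dynamical modes, effective
    dimension), and an orthogonal-subspace lesion analysis of task-irrelevant
    activity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
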