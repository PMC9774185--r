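Package: pipgate
Title: Single-Channel Kinetics and Colocalization Analysis of PIP2-Gated Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative tools for studying ligand-dependent gating of the
    epithelial sodium channel (ENaC) by the membrane lipid PIP2. Implements
    ligand-dependent Markov gating schemes with exact stationary open
    probabilities and aggregated dwell-time means, exact stochastic simulation
    of single-channel and multi-channel patch-clamp traces with Gaussian
    low-pass filtering, half-amplitude idealization with NPo and dwell-time
    statistics, exponential-mixture dwell fitting, Hill dose-response and
    Goldman-Hodgkin-Katz current-voltage fitting, Manders/Costes colocalization
    statistics for registered two-channel micrographs, and the electrostatic
    sequestration arithmetic (dissociation constant to energy well, local
    concentration enhancement, and membrane diffusion encounter times).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
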