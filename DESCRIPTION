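Package: causalprosody
Title: Prosodic Signalling of Subjective and Objective Causality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether the prosody of the English causal
    connective "so" cues subjective versus objective causality. Implements
    functional principal component analysis (FPCA) of f0 contours on a
    duration-normalized grid, restyling of component scores to impose a
    prosodic category, stimulus assembly with segment-ratio-preserving
    duration scaling and Praat PitchTier/TextGrid export, synthetic
    generation of contours and forced-choice listener responses from a
    hierarchical logistic generative model, filler-based participant
    filtering, a Bayesian hierarchical logistic model ladder fitted by
    MCMC (JAGS), prior predictive checks, bridge-sampling Bayes factors
    under multiple priors, and posterior summaries on the odds scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rjags,
    coda,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
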