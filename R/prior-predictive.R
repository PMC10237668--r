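#' Prior predictive distribution of the subjective-choice proportion
#'
#' Simulates whole datasets from a ladder model's priors: for each draw, the
#' population coefficients come from the normal(0, prior sd) prior, every
#' random-effect SD from its half-normal(0, 1) prior, the random effects
#' from the implied normals, and the choices from the Bernoulli likelihood
#' over the full design. Returns the per-draw proportion of subjective
#' choices — the quantity whose distribution shows whether a prior encodes
#' reasonable beliefs before data (a very wide prior such as normal(0, 10)
#' piles the proportions against 0 and 1).
#'
#' @param spec A [model_spec()]; the intercept model `m0` is the usual
#'   screening model.
#' @param prior A [prior_spec()].
#' @param n_participants,n_pairs Design dimensions; defaults 40 and 15.
#' @param n_draws Number of prior draws (>= 1000 for a stable picture).
#' @param seed Integer seed.
#' @return Numeric vector of length `n_draws` of simulated proportions.
#' @examples
#' pp <- prior_predictive(model_spec("m0"), prior_spec(0.5), n_draws = 1000)
#' mean(pp > 0.05 & pp < 0.95)
#' @export
prior_predictive <- function(spec, prior, n_participants = 40, n_pairs = 15,
                             n_draws = 2000, seed = 1) {
  stopifnot(inherits(spec, "model_spec"), inherits(prior, "prior_spec"))
  if (n_draws < 1) stop_cp("n_draws must be >= 1", "argument_error")
  with_seed(derive_seed(seed, 4), {
    design <- expand.grid(p = seq_len(n_participants), q = seq_len(n_pairs),
                          x = c(0L, 1L))
    n <- nrow(design)
    vapply(seq_len(n_draws), function(d) {
      b0 <- stats::rnorm(1, 0, prior$sd)
      sa <- abs(stats::rnorm(1))
      sb <- abs(stats::rnorm(1))
      a <- stats::rnorm(n_participants, 0, sa)
      b <- stats::rnorm(n_pairs, 0, sb)
      eta <- b0 + a[design$p] + b[design$q]
      if (spec$prosody) {
        bp <- stats::rnorm(1, 0, prior$sd)
        slope <- bp
        if (spec$slope_participant) {
          slope <- slope + stats::rnorm(n_participants, 0,
                                        abs(stats::rnorm(1)))[design$p]
        }
        if (spec$slope_pair) {
          slope <- slope + stats::rnorm(n_pairs, 0,
                                        abs(stats::rnorm(1)))[design$q]
        }
        eta <- eta + slope * design$x
      }
      mean(stats::rbinom(n, 1, stats::plogis(eta)))
    }, numeric(1))
  })
}
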