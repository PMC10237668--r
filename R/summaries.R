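#' Odds-scale and per-participant summaries of a fitted model
#'
#' Extends a fit's posterior summary to the scales reported in practice:
#' the baseline odds of a subjective choice (exponentiated intercept), the
#' prosody odds ratio, and — for models with by-participant prosody slopes —
#' a per-participant slope table. Exponentiated summaries are reported under
#' both conventions: the mean of the exponentiated draws (the headline
#' convention here) and the exponential of the posterior mean; the two
#' differ by Jensen's inequality and both are returned. The reciprocal odds
#' (odds of the objective choice) are included for the intercept.
#'
#' @param fit A `cp_fit` from [fit_choice_model()].
#' @param participant_table Request the per-participant slope table; only
#'   models with by-participant prosody slopes (m2, m3) support it. Default
#'   TRUE for those models.
#' @return A list of class `cp_effects`:
#'   \describe{
#'     \item{population}{data.frame of population-level parameters with 95%
#'       and 50% CrIs and both exponentiated summaries; the intercept row
#'       also carries `reciprocal_odds = 1 / odds`.}
#'     \item{variances}{data.frame of random-effect SD posterior means and
#'       their squares (variances).}
#'     \item{participants}{per-participant prosody slope table (mean, 50%
#'       and 95% CrIs, and whether the 95% CrI excludes zero), or NULL.}
#'   }
#' @export
summarize_effects <- function(fit,
                              participant_table = fit$spec$slope_participant) {
  stopifnot(inherits(fit, "cp_fit"))
  if (participant_table && !fit$spec$slope_participant) {
    stop_cp("per-participant slopes require a model with by-participant prosody slopes (m2 or m3)",
            "capability_error")
  }
  draws <- fit$draws
  pop_pars <- intersect(c("b0", "bp"), colnames(draws))
  population <- summarize_draws(draws, pop_pars)
  population$odds <- population$exp_mean_of_draws
  population$reciprocal_odds <- ifelse(population$parameter == "b0",
                                       1 / population$odds, NA_real_)
  sd_pars <- intersect(c("sa", "sb", "su", "sw"), colnames(draws))
  sd_mean <- colMeans(draws[, sd_pars, drop = FALSE])
  variances <- data.frame(
    parameter = sd_pars,
    group = c(sa = "participant", sb = "pair", su = "participant",
              sw = "pair")[sd_pars],
    term = c(sa = "intercept", sb = "intercept", su = "prosody",
             sw = "prosody")[sd_pars],
    sd_mean = unname(sd_mean),
    variance = unname(sd_mean^2))
  participants <- NULL
  if (participant_table) {
    np <- fit$index$NP
    slopes <- draws[, "bp"] +
      draws[, "su"] * draws[, paste0("zu[", seq_len(np), "]")]
    qs <- apply(slopes, 2, stats::quantile,
                probs = c(0.025, 0.25, 0.75, 0.975))
    participants <- data.frame(
      participant_id = fit$index$participant_ids,
      mean = colMeans(slopes),
      q2.5 = qs[1, ], q25 = qs[2, ], q75 = qs[3, ], q97.5 = qs[4, ])
    participants$excludes_zero <- participants$q2.5 > 0 |
      participants$q97.5 < 0
    rownames(participants) <- NULL
  }
  structure(list(population = population, variances = variances,
                 participants = participants, model = fit$spec$name),
            class = "cp_effects")
}

#' @export
print.cp_effects <- function(x, ...) {
  cat(sprintf("Effect summaries for %s\n", x$model))
  print(x$population, row.names = FALSE, digits = 3)
  cat("\nRandom-effect SDs:\n")
  print(x$variances, row.names = FALSE, digits = 3)
  if (!is.null(x$participants)) {
    n_clear <- sum(x$participants$excludes_zero)
    cat(sprintf("\nPer-participant prosody slopes: %d of %d with 95%% CrI excluding zero\n",
                n_clear, nrow(x$participants)))
  }
  invisible(x)
}
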