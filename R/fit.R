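#' MCMC sampler settings
#'
#' Defaults mirror the study configuration: four chains, 10,000 iterations
#' per chain of which 2,000 are warm-up. [reduced_settings()] is a cheaper
#' configuration (2,000 iterations, 500 warm-up) intended for
#' replicate simulation runs and continuous testing; see the methods
#' vignette for the rationale.
#'
#' @param chains Number of chains.
#' @param iterations Iterations per chain, including warm-up.
#' @param warmup Warm-up (burn-in) iterations per chain.
#' @param thin Thinning interval applied to the kept draws.
#' @param adapt JAGS adaptation steps before warm-up.
#' @param seed Integer seed; per-chain RNG seeds are derived from it.
#' @return A `sampler_settings` list.
#' @export
sampler_settings <- function(chains = 4, iterations = 10000, warmup = 2000,
                             thin = 1, adapt = 500, seed = 1) {
  if (iterations <= warmup) {
    stop_cp("iterations must exceed warmup", "argument_error")
  }
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup = as.integer(warmup),
                 thin = as.integer(thin),
                 adapt = as.integer(adapt),
                 seed = as.integer(seed)),
            class = "sampler_settings")
}

#' @rdname sampler_settings
#' @param ... Overrides passed to [sampler_settings()].
#' @export
reduced_settings <- function(...) {
  # no thinning: bridge-sampling proposals want the full draw count
  args <- utils::modifyList(list(chains = 4, iterations = 2000, warmup = 500,
                                 thin = 1, adapt = 500, seed = 1),
                            list(...))
  do.call(sampler_settings, args)
}

# JAGS model code for a ladder member. Non-centered parameterization
# throughout: random effects are sigma * z with z ~ N(0,1), which removes the
# funnel that defeats Gibbs/slice sampling in the centered form. Population
# coefficients get the normal(0, prior sd) prior; every random-effect SD gets
# half-normal(0, 1).
jags_code <- function(spec, prior_sd) {
  eta <- "b0 + sa*za[p[i]] + sb*zb[q[i]]"
  if (spec$prosody) {
    slope <- "bp"
    if (spec$slope_participant) slope <- paste0(slope, " + su*zu[p[i]]")
    if (spec$slope_pair) slope <- paste0(slope, " + sw*zw[q[i]]")
    eta <- paste0(eta, " + (", slope, ")*x[i]")
  }
  lines <- c(
    "model {",
    "  for (i in 1:N) {",
    sprintf("    y[i] ~ dbern(ilogit(%s))", eta),
    "  }",
    "  for (j in 1:NP) { za[j] ~ dnorm(0, 1) }",
    "  for (k in 1:NQ) { zb[k] ~ dnorm(0, 1) }",
    if (spec$slope_participant) "  for (j in 1:NP) { zu[j] ~ dnorm(0, 1) }",
    if (spec$slope_pair) "  for (k in 1:NQ) { zw[k] ~ dnorm(0, 1) }",
    sprintf("  b0 ~ dnorm(0, %.10g)", 1 / prior_sd^2),
    if (spec$prosody) sprintf("  bp ~ dnorm(0, %.10g)", 1 / prior_sd^2),
    "  sa ~ dnorm(0, 1) T(0,)",
    "  sb ~ dnorm(0, 1) T(0,)",
    if (spec$slope_participant) "  su ~ dnorm(0, 1) T(0,)",
    if (spec$slope_pair) "  sw ~ dnorm(0, 1) T(0,)",
    "}")
  paste(lines[!vapply(lines, is.null, TRUE)], collapse = "\n")
}

monitored_params <- function(spec) {
  c("b0", if (spec$prosody) "bp", "sa", "sb",
    if (spec$slope_participant) "su", if (spec$slope_pair) "sw",
    "za", "zb", if (spec$slope_participant) "zu",
    if (spec$slope_pair) "zw")
}

reported_params <- function(spec) {
  c("b0", if (spec$prosody) "bp", "sa", "sb",
    if (spec$slope_participant) "su", if (spec$slope_pair) "sw")
}

#' Fit a model of the ladder by MCMC
#'
#' Samples the posterior of a [model_spec()] ladder member for a trial table
#' with JAGS (Bernoulli likelihood, logit link, non-centered random
#' effects). After sampling, a convergence report is computed: split-chain
#' Rhat and bulk/tail effective sample size for every reported coefficient.
#' The convergence contract (Rhat within 0.01 of 1; bulk ESS above 90% of
#' the kept post-warm-up draws; no divergent transitions) is evaluated and
#' the result attached; a violation raises a warning (or an error when
#' `strict = TRUE`) carrying the report — never silent. Note the slice
#' sampler has no divergence diagnostic, so the divergence count is reported
#' as 0 by construction.
#'
#' @param spec A [model_spec()].
#' @param data A trial table (see [gen_responses()]).
#' @param prior A [prior_spec()] for the population-level coefficients.
#' @param settings A [sampler_settings()].
#' @param strict If TRUE, a convergence-contract violation is an error.
#' @param quiet Suppress JAGS progress output; default TRUE.
#' @return A `cp_fit` object: posterior draw matrix (`draws`, merged
#'   chains), coda `mcmc.list` (`chains`), per-parameter `summary`
#'   data.frame, `convergence` report, and the model metadata needed for
#'   marginal-likelihood estimation.
#' @export
fit_choice_model <- function(spec, data, prior = prior_spec(1.5),
                             settings = sampler_settings(), strict = FALSE,
                             quiet = TRUE) {
  stopifnot(inherits(spec, "model_spec"), inherits(prior, "prior_spec"),
            inherits(settings, "sampler_settings"))
  check_trial_table(data)
  if (!nrow(data)) stop_cp("empty trial table", "precondition_error")
  if (spec$prosody && length(unique(data$prosody)) < 2) {
    stop_cp("both prosody levels must be present to estimate the prosody effect",
            "precondition_error")
  }
  p <- match(data$participant_id, sort(unique(data$participant_id)))
  q <- match(data$pair_id, sort(unique(data$pair_id)))
  jd <- list(y = data$choice, p = p, q = q, N = nrow(data),
             NP = max(p), NQ = max(q))
  if (spec$prosody) jd$x <- data$prosody
  inits <- lapply(seq_len(settings$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = derive_seed(settings$seed, 100 + ch))
  })
  code <- jags_code(spec, prior$sd)
  run <- function() {
    jm <- rjags::jags.model(textConnection(code), data = jd, inits = inits,
                            n.chains = settings$chains,
                            n.adapt = settings$adapt, quiet = TRUE)
    stats::update(jm, settings$warmup, progress.bar = "none")
    rjags::coda.samples(jm, monitored_params(spec),
                        n.iter = settings$iterations - settings$warmup,
                        thin = settings$thin, progress.bar = "none")
  }
  chains <- if (quiet) suppressMessages(run()) else run()
  draws <- as.matrix(chains)
  conv <- convergence_report(chains, spec)
  fit <- structure(
    list(spec = spec, prior = prior, settings = settings,
         draws = draws, chains = chains,
         index = list(p = p, q = q, x = if (spec$prosody) data$prosody,
                      y = data$choice, NP = jd$NP, NQ = jd$NQ,
                      participant_ids = sort(unique(data$participant_id))),
         summary = summarize_draws(draws, reported_params(spec)),
         convergence = conv),
    class = "cp_fit")
  if (!conv$passed) {
    msg <- paste0("convergence contract violated for ", spec$name, ": ",
                  paste(conv$notes, collapse = "; "))
    if (strict) {
      stop(errorCondition(msg, class = c("diagnostic_failure",
                                         "causalprosody_error"),
                          report = conv))
    }
    warning(warningCondition(msg, class = "diagnostic_warning"))
  }
  fit
}

# Rhat / ESS report for the reported coefficients.
convergence_report <- function(chains, spec) {
  pars <- reported_params(spec)
  sub <- lapply(chains, function(m) m[, pars, drop = FALSE])
  sub <- coda::as.mcmc.list(lapply(sub, coda::as.mcmc))
  n_kept <- coda::niter(sub) * coda::nchain(sub)
  rhat <- tryCatch(
    coda::gelman.diag(sub, autoburnin = FALSE,
                      multivariate = FALSE)$psrf[, 1],
    error = function(e) stats::setNames(rep(NA_real_, length(pars)), pars))
  ess_bulk <- coda::effectiveSize(sub)[pars]
  ess_tail <- vapply(pars, function(pp) {
    x <- unlist(lapply(sub, function(m) m[, pp]))
    qs <- stats::quantile(x, c(0.05, 0.95))
    min(coda::effectiveSize(coda::mcmc(as.numeric(x <= qs[1]))),
        coda::effectiveSize(coda::mcmc(as.numeric(x >= qs[2]))))
  }, numeric(1))
  notes <- character(0)
  if (any(!is.finite(rhat)) || any(abs(rhat - 1) > 0.01, na.rm = TRUE)) {
    notes <- c(notes, sprintf("max Rhat %.3f exceeds 1.01", max(rhat)))
  }
  if (any(ess_bulk < 0.9 * n_kept)) {
    notes <- c(notes, sprintf("min bulk ESS %.0f below 90%% of %d kept draws",
                              min(ess_bulk), n_kept))
  }
  list(rhat = rhat, ess_bulk = ess_bulk, ess_tail = ess_tail,
       n_kept = n_kept, divergences = 0L,
       passed = length(notes) == 0, notes = notes)
}

# Posterior summary table: mean, 95% and 50% CrI, exponentiated summaries.
summarize_draws <- function(draws, pars) {
  do.call(rbind, lapply(pars, function(pp) {
    x <- draws[, pp]
    data.frame(parameter = pp,
               mean = mean(x),
               sd = stats::sd(x),
               q2.5 = unname(stats::quantile(x, 0.025)),
               q25 = unname(stats::quantile(x, 0.25)),
               q75 = unname(stats::quantile(x, 0.75)),
               q97.5 = unname(stats::quantile(x, 0.975)),
               exp_mean_of_draws = mean(exp(x)),
               exp_of_mean = exp(mean(x)))
  }))
}

#' @export
print.cp_fit <- function(x, ...) {
  cat(sprintf("<cp_fit %s, prior normal(0, %g), %d kept draws%s>\n",
              x$spec$name, x$prior$sd, nrow(x$draws),
              if (x$convergence$passed) "" else " [convergence flagged]"))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
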