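# Marginal likelihood by bridge sampling.
#
# The estimator is the iterative optimal-bridge scheme of Meng & Wong,
# run entirely in log space for numerical robustness, with a moment-matched
# multivariate normal proposal fitted on half of the posterior draws (the
# other half enters the bridge identity). Random-effect SDs are mapped to the
# log scale first so the posterior support is unconstrained; the Jacobian is
# added to the target density. A repeated-estimation coefficient-of-variation
# diagnostic guards against an unstable estimate.

logaddexp <- function(a, b) {
  m <- pmax(a, b)
  r <- m + log1p(exp(pmin(a, b) - m))
  # handle -Inf pairs cleanly
  r[is.infinite(m) & m < 0] <- -Inf
  r
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

# Build the log unnormalized posterior for a fitted ladder model, as a
# function of a draw matrix in the *unconstrained* parameterization (SD
# columns carry log(sd)). Includes the half-normal(0,1) SD priors, standard
# normal priors on the non-centered effects, the normal(0, prior sd) priors
# on the population coefficients, and the log-scale Jacobian.
make_log_post <- function(fit) {
  spec <- fit$spec
  idx <- fit$index
  cn <- colnames(fit$draws)
  sd_pars <- intersect(c("sa", "sb", "su", "sw"), cn)
  z_cols <- grep("^z", cn, value = TRUE)
  # design matrix mapping transformed draw columns to the linear predictor
  N <- length(idx$y)
  ind <- function(i, n) {
    m <- matrix(0, N, n)
    m[cbind(seq_len(N), i)] <- 1
    m
  }
  D <- cbind(1, ind(idx$p, idx$NP), ind(idx$q, idx$NQ))
  t_cols <- list(c("b0"), paste0("za[", seq_len(idx$NP), "]"),
                 paste0("zb[", seq_len(idx$NQ), "]"))
  t_scale <- list(NA, "sa", "sb")
  if (spec$prosody) {
    D <- cbind(D, idx$x)
    t_cols <- c(t_cols, list("bp"))
    t_scale <- c(t_scale, NA)
    if (spec$slope_participant) {
      D <- cbind(D, idx$x * ind(idx$p, idx$NP))
      t_cols <- c(t_cols, list(paste0("zu[", seq_len(idx$NP), "]")))
      t_scale <- c(t_scale, "su")
    }
    if (spec$slope_pair) {
      D <- cbind(D, idx$x * ind(idx$q, idx$NQ))
      t_cols <- c(t_cols, list(paste0("zw[", seq_len(idx$NQ), "]")))
      t_scale <- c(t_scale, "sw")
    }
  }
  y <- idx$y
  prior_sd <- fit$prior$sd
  fixed_pars <- intersect(c("b0", "bp"), cn)
  function(theta) {
    # theta: S x K matrix, colnames as fit$draws but SD columns on log scale
    S <- nrow(theta)
    sds <- exp(theta[, sd_pars, drop = FALSE])
    Tm <- matrix(0, S, ncol(D))
    at <- 1
    for (b in seq_along(t_cols)) {
      cols <- theta[, t_cols[[b]], drop = FALSE]
      if (!is.na(t_scale[[b]])) cols <- cols * sds[, t_scale[[b]]]
      Tm[, at:(at + ncol(cols) - 1)] <- cols
      at <- at + ncol(cols)
    }
    eta <- D %*% t(Tm)                       # N x S
    loglik <- colSums(y * eta) - colSums(log1pexp(eta))
    lp <- loglik +
      rowSums(stats::dnorm(theta[, fixed_pars, drop = FALSE],
                           0, prior_sd, log = TRUE)) +
      rowSums(stats::dnorm(theta[, z_cols, drop = FALSE], 0, 1, log = TRUE))
    # half-normal(0,1) prior on each SD plus the log-transform Jacobian
    lp + rowSums(log(2) + stats::dnorm(sds, 0, 1, log = TRUE)) +
      rowSums(theta[, sd_pars, drop = FALSE])
  }
}

# Map a fit's draw matrix into the unconstrained space used by the bridge.
unconstrained_draws <- function(fit) {
  theta <- fit$draws
  sd_pars <- intersect(c("sa", "sb", "su", "sw"), colnames(theta))
  theta[, sd_pars] <- log(theta[, sd_pars])
  theta
}

# One bridge-sampling pass: fits the proposal on the odd rows, runs the
# iteration with the even rows against fresh proposal draws.
bridge_once <- function(theta, log_post, seed = NULL, max_iter = 1000,
                        tol = 1e-10) {
  n <- nrow(theta)
  fit_half <- theta[seq(1, n, by = 2), , drop = FALSE]
  post_half <- theta[seq(2, n, by = 2), , drop = FALSE]
  mu <- colMeans(fit_half)
  cv <- stats::cov(fit_half)
  ridge <- 1e-8 * mean(diag(cv))
  ch <- chol(cv + diag(ridge, ncol(cv)))
  n1 <- nrow(post_half)
  n2 <- n1
  prop <- with_seed(seed, rmvnorm_chol(n2, mu, ch))
  l1 <- log_post(post_half) - dmvnorm_chol_log(post_half, mu, ch)
  l2 <- log_post(prop) - dmvnorm_chol_log(prop, mu, ch)
  ls1 <- log(n1 / (n1 + n2))
  ls2 <- log(n2 / (n1 + n2))
  lr <- logsumexp(l1) - log(n1)   # harmonic-free starting value
  for (it in seq_len(max_iter)) {
    lnum <- logsumexp(l2 - logaddexp(ls1 + l2, ls2 + lr)) - log(n2)
    lden <- logsumexp(-logaddexp(ls1 + l1, ls2 + lr)) - log(n1)
    lr_new <- lnum - lden
    if (is.finite(lr_new) && abs(lr_new - lr) < tol * max(1, abs(lr))) {
      lr <- lr_new
      break
    }
    lr <- lr_new
  }
  lr
}

#' Log marginal likelihood of a fitted ladder model
#'
#' Estimates the log marginal likelihood by iterative bridge sampling with a
#' moment-matched normal proposal in the unconstrained parameter space. The
#' estimate is repeated `reps` times with fresh proposal draws; the spread of
#' the repeats yields a coefficient-of-variation diagnostic on the
#' likelihood scale.
#'
#' @param fit A `cp_fit` from [fit_choice_model()].
#' @param reps Number of independent estimator repeats (>= 2).
#' @param seed Integer seed for the proposal draws.
#' @return A list: `lml` (mean log marginal likelihood), `reps` (the
#'   individual estimates), `cv` (approximate coefficient of variation).
#' @export
marginal_likelihood <- function(fit, reps = 3, seed = 1) {
  stopifnot(inherits(fit, "cp_fit"), reps >= 2)
  theta <- unconstrained_draws(fit)
  log_post <- make_log_post(fit)
  ests <- vapply(seq_len(reps), function(r) {
    bridge_once(theta, log_post, seed = derive_seed(seed, 200 + r))
  }, numeric(1))
  list(lml = mean(ests), reps = ests,
       cv = stats::sd(ests))  # sd of log ~ CV of the marginal likelihood
}

#' Bayes factor between two nested ladder models
#'
#' BF10 is the ratio of marginal likelihoods of the model with the term of
#' interest over the model without it, both estimated by bridge sampling on
#' their own posterior draws. The two fits must be nested neighbours (or any
#' nested pair) on the same data and share the same population-coefficient
#' prior. If the repeated-estimation coefficient of variation reaches 10%
#' the estimate is rejected as unstable.
#'
#' @param fit_with,fit_without `cp_fit` objects for the richer and the
#'   reduced model.
#' @param reps Estimator repeats per model (>= 2).
#' @param seed Integer seed.
#' @param cv_limit Maximum tolerated coefficient of variation; default 0.10.
#' @return A `bf_result`: `bf10`, `log_bf10`, model names, `prior_sd`,
#'   interpretive `band` (see [bf_band()]), `cv`, and the per-model marginal
#'   likelihood estimates.
#' @export
bayes_factor <- function(fit_with, fit_without, reps = 3, seed = 1,
                         cv_limit = 0.10) {
  stopifnot(inherits(fit_with, "cp_fit"), inherits(fit_without, "cp_fit"))
  order_ok <- match(fit_with$spec$name, c("m0", "m1", "m2", "m3")) >=
    match(fit_without$spec$name, c("m0", "m1", "m2", "m3"))
  if (!order_ok) {
    stop_cp("fit_with must be the richer (or equal) model", "argument_error")
  }
  if (!identical(fit_with$index$y, fit_without$index$y)) {
    stop_cp("both models must be fitted to the same data", "argument_error")
  }
  if (fit_with$prior$sd != fit_without$prior$sd) {
    stop_cp("both models must share the same prior", "argument_error")
  }
  ml1 <- marginal_likelihood(fit_with, reps = reps,
                             seed = derive_seed(seed, 11))
  ml0 <- marginal_likelihood(fit_without, reps = reps,
                             seed = derive_seed(seed, 13))
  bf_reps <- exp(ml1$reps - ml0$reps)
  cv <- stats::sd(bf_reps) / mean(bf_reps)
  if (!is.finite(cv) || cv >= cv_limit) {
    stop(errorCondition(
      sprintf("bridge-sampling estimate unstable (CV %.3f >= %.2f)",
              cv, cv_limit),
      class = c("instability_error", "causalprosody_error"),
      diagnostics = list(cv = cv, reps_with = ml1$reps,
                         reps_without = ml0$reps)))
  }
  log_bf <- ml1$lml - ml0$lml
  structure(list(bf10 = exp(log_bf), log_bf10 = log_bf,
                 model_with = fit_with$spec$name,
                 model_without = fit_without$spec$name,
                 prior_sd = fit_with$prior$sd,
                 band = bf_band(exp(log_bf)), cv = cv,
                 lml_with = ml1, lml_without = ml0),
            class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("<bf_result %s vs %s, prior normal(0, %g): BF10 = %.3g (%s), CV %.3f>\n",
              x$model_with, x$model_without, x$prior_sd, x$bf10, x$band,
              x$cv))
  invisible(x)
}
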