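# Synthetic-data generators. These emulate the two kinds of input the study
# pipeline consumes: condition-structured f0 contours for the connective
# "so", and forced-choice trial tables from the hierarchical logistic
# generative model at the study's reported posterior means.

#' Parameters of the contour generator
#'
#' Defines a low-rank generative model for connective f0 contours: a mean
#' curve plus three orthonormal component curves on \[0, 1\], with scores
#' drawn per contour. The second component is a concave mid-span bulge and
#' the third an end-point tilt; their score means differ by prosodic
#' condition (defaults are the production-study condition means: s2 = +0.335
#' subjective / -0.515 objective, s3 = -0.065 / +0.025), so subjective
#' contours come out more concave with a lower intercept. Durations are drawn
#' near 285 ms (subjective) and 235 ms (objective).
#'
#' @param grid_size Grid resolution for the underlying shapes; default 101.
#' @param score_sds Within-condition SDs of (s1, s2, s3); default
#'   `c(1, 0.25, 0.2)`.
#' @param condition_means Named list with `subjective` and `objective`
#'   two-vectors `(s2, s3)`; defaults per the production-study targets.
#' @param noise_sd White measurement noise per sample, semitones; default 0.1.
#' @param duration_means Named vector of mean durations (ms); default
#'   `c(subjective = 285, objective = 235)`.
#' @param duration_sd SD of drawn durations, ms; default 10.
#' @return A `contour_gen_params` list with orthonormalized component shapes
#'   (`mean_shape`, `comp_shapes` on `grid`).
#' @export
contour_gen_params <- function(grid_size = 101,
                               score_sds = c(1, 0.25, 0.2),
                               condition_means = list(
                                 subjective = c(s2 = +0.335, s3 = -0.065),
                                 objective = c(s2 = -0.515, s3 = +0.025)),
                               noise_sd = 0.1,
                               duration_means = c(subjective = 285,
                                                  objective = 235),
                               duration_sd = 10) {
  if (length(score_sds) != 3 || any(score_sds < 0) || noise_sd < 0 ||
      duration_sd < 0) {
    stop_cp("score_sds (length 3), noise_sd, duration_sd must be >= 0",
            "parameter_error")
  }
  g <- seq(0, 1, length.out = grid_size)
  # raw shapes: level/tilt, concave mid-span bulge, end-point tilt
  raw <- cbind(1 - 0.6 * g,
               sin(pi * g),
               g - 0.5)
  comps <- gram_schmidt(raw)
  comps <- apply(comps, 2, fix_component_sign)
  structure(list(grid = g,
                 mean_shape = 2 - 4 * g,
                 comp_shapes = comps,
                 score_sds = score_sds,
                 condition_means = condition_means,
                 noise_sd = noise_sd,
                 duration_means = duration_means,
                 duration_sd = duration_sd),
            class = "contour_gen_params")
}

gram_schmidt <- function(m) {
  q <- m
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    if (j > 1) {
      for (i in seq_len(j - 1)) v <- v - sum(v * q[, i]) * q[, i]
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) stop_cp("component shapes are collinear", "parameter_error")
    q[, j] <- v / nv
  }
  q
}

#' Generate synthetic connective contours
#'
#' Draws `n_per_condition` contours per prosodic condition from the low-rank
#' model in [contour_gen_params()]: each contour is
#' mean + s1 c1 + s2 c2 + s3 c3 + noise, sampled every 5 ms over a duration
#' drawn near the condition's mean. Output is reproducible under `seed`.
#'
#' @param n_per_condition Contours per condition (>= 2).
#' @param params A [contour_gen_params()].
#' @param seed Integer seed.
#' @return List of [contour()]s, labelled `"<condition>_<i>"`, with the
#'   generating scores attached as attribute `"scores"` (a data.frame).
#' @export
gen_contours <- function(n_per_condition, params = contour_gen_params(),
                         seed = 1) {
  stopifnot(inherits(params, "contour_gen_params"))
  if (n_per_condition < 2) {
    stop_cp("n_per_condition must be >= 2", "parameter_error")
  }
  with_seed(derive_seed(seed, 1), {
    out <- list()
    gen_scores <- NULL
    for (cond in c("subjective", "objective")) {
      cm <- params$condition_means[[cond]]
      for (i in seq_len(n_per_condition)) {
        s <- c(stats::rnorm(1, 0, params$score_sds[1]),
               stats::rnorm(1, cm[["s2"]], params$score_sds[2]),
               stats::rnorm(1, cm[["s3"]], params$score_sds[3]))
        dur <- max(50, stats::rnorm(1, params$duration_means[[cond]],
                                    params$duration_sd))
        times <- unique(c(seq(0, dur, by = 5), dur))
        u <- times / dur
        vals <- stats::approx(params$grid,
                              params$mean_shape +
                                drop(params$comp_shapes %*% s),
                              xout = u)$y +
          stats::rnorm(length(u), 0, params$noise_sd)
        out[[length(out) + 1]] <-
          contour(times, vals, label = sprintf("%s_%02d", cond, i))
        gen_scores <- rbind(gen_scores,
                            data.frame(label = sprintf("%s_%02d", cond, i),
                                       condition = cond,
                                       s1 = s[1], s2 = s[2], s3 = s[3]))
      }
    }
    attr(out, "scores") <- gen_scores
    out
  })
}

#' Parameters of the response generator
#'
#' The generative twin of the fullest model in the analysis ladder
#' (`choice ~ prosody + (1 + prosody | participant) + (1 + prosody | pair)`).
#' Defaults are the study's reported posterior means: intercept -1.06,
#' prosody slope 0.39, by-participant slope SD 0.51, by-pair slope SD 0.42.
#' Random-intercept SDs are not reported and default to 0.5 for both
#' grouping factors.
#'
#' @param beta0 Log-odds intercept.
#' @param beta_prosody Log-odds prosody slope.
#' @param sd_int_participant,sd_int_pair SDs of random intercepts (>= 0).
#' @param sd_slope_participant,sd_slope_pair SDs of random prosody slopes
#'   (>= 0).
#' @param n_pairs Number of item pairs; default 15.
#' @param seed Integer root seed.
#' @return A `generative_params` list.
#' @export
generative_params <- function(beta0 = -1.06,
                              beta_prosody = 0.39,
                              sd_int_participant = 0.5,
                              sd_int_pair = 0.5,
                              sd_slope_participant = 0.51,
                              sd_slope_pair = 0.42,
                              n_pairs = 15,
                              seed = 1) {
  sds <- c(sd_int_participant, sd_int_pair, sd_slope_participant,
           sd_slope_pair)
  if (any(sds < 0)) stop_cp("random-effect SDs must be >= 0",
                            "parameter_error")
  structure(list(beta0 = beta0, beta_prosody = beta_prosody,
                 sd_int_participant = sd_int_participant,
                 sd_int_pair = sd_int_pair,
                 sd_slope_participant = sd_slope_participant,
                 sd_slope_pair = sd_slope_pair,
                 n_pairs = as.integer(n_pairs), seed = seed),
            class = "generative_params")
}

#' Parameters of the intercept-only generative model
#'
#' Convenience wrapper: the generative twin of the intercept model (no
#' prosody effect, no slope variation), used for intercept-recovery runs.
#'
#' @inheritParams generative_params
#' @return A `generative_params` list with `beta_prosody = 0` and both slope
#'   SDs 0.
#' @export
generative_params_m0 <- function(beta0 = -1.06, sd_int_participant = 0.5,
                                 sd_int_pair = 0.5, n_pairs = 15, seed = 1) {
  generative_params(beta0 = beta0, beta_prosody = 0,
                    sd_int_participant = sd_int_participant,
                    sd_int_pair = sd_int_pair,
                    sd_slope_participant = 0, sd_slope_pair = 0,
                    n_pairs = n_pairs, seed = seed)
}

#' Simulate a forced-choice trial table
#'
#' Simulates the complete within-participant, within-pair design (every
#' participant sees every pair in both prosody conditions exactly once; 30
#' trials per participant in the default 15-pair design). For each trial,
#' P(choice = 1) = inverse-logit of
#' `beta0 + a_p + b_q + (beta_prosody + u_p + w_q) * prosody`, with the
#' random effects drawn independently normal at the parameter SDs, and the
#' choice a Bernoulli draw.
#'
#' @param n_participants Number of participants (>= 1).
#' @param params A [generative_params()].
#' @return A data.frame (`trial table`) with columns `participant_id`,
#'   `pair_id`, `prosody` (0 objective / 1 subjective), `choice`
#'   (0 objective / 1 subjective continuation).
#' @examples
#' tt <- gen_responses(4, generative_params(seed = 42))
#' nrow(tt)  # 4 x 15 x 2
#' @export
gen_responses <- function(n_participants, params = generative_params()) {
  stopifnot(inherits(params, "generative_params"))
  if (n_participants < 1) {
    stop_cp("n_participants must be >= 1", "parameter_error")
  }
  with_seed(derive_seed(params$seed, 2), {
    np <- as.integer(n_participants)
    nq <- params$n_pairs
    a <- stats::rnorm(np, 0, params$sd_int_participant)
    b <- stats::rnorm(nq, 0, params$sd_int_pair)
    u <- stats::rnorm(np, 0, params$sd_slope_participant)
    w <- stats::rnorm(nq, 0, params$sd_slope_pair)
    d <- expand.grid(participant_id = seq_len(np), pair_id = seq_len(nq),
                     prosody = c(0L, 1L))
    d <- d[order(d$participant_id, d$pair_id, d$prosody), ]
    eta <- params$beta0 + a[d$participant_id] + b[d$pair_id] +
      (params$beta_prosody + u[d$participant_id] + w[d$pair_id]) * d$prosody
    d$choice <- stats::rbinom(nrow(d), 1, stats::plogis(eta))
    attr(d, "out.attrs") <- NULL
    rownames(d) <- NULL
    d
  })
}

#' Simulate the filler-accuracy table
#'
#' Draws a 55-participant filler-accuracy table matching the study's printed
#' distribution exactly: 38 participants at 100%, 2 above 90%, 3 between 70%
#' and 89%, 8 between 50% and 69%, and 4 below 50%, with within-band values
#' randomized on the 20-filler lattice.
#'
#' @param seed Integer seed.
#' @param n_fillers Number of filler trials; default 20.
#' @return A data.frame with columns `participant_id`, `n_correct`,
#'   `n_fillers`, `accuracy`.
#' @export
gen_filler_accuracies <- function(seed = 1, n_fillers = 20) {
  with_seed(derive_seed(seed, 3), {
    lattice <- function(lo, hi) {
      k <- 0:n_fillers
      k[k / n_fillers > lo & k / n_fillers <= hi]
    }
    bands <- list(
      list(n = 38, k = n_fillers),            # exactly 100%
      list(n = 2, k = lattice(0.90, 0.999)),  # (90%, 100%)
      list(n = 3, k = lattice(0.699, 0.89)),  # [70%, 89%]
      list(n = 8, k = lattice(0.499, 0.69)),  # [50%, 69%]
      list(n = 4, k = lattice(-1, 0.499)))    # below 50%
    n_correct <- unlist(lapply(bands, function(b) {
      if (length(b$k) == 1) rep(b$k, b$n) else sample(b$k, b$n, replace = TRUE)
    }))
    data.frame(participant_id = seq_along(n_correct),
               n_correct = n_correct,
               n_fillers = n_fillers,
               accuracy = n_correct / n_fillers)
  })
}

#' Write / read a trial table as CSV
#'
#' Header: `participant_id,pair_id,prosody,choice` with prosody and choice
#' coded 0/1 (objective/subjective).
#'
#' @param table A trial table data.frame.
#' @param path CSV path.
#' @export
write_trial_table <- function(table, path) {
  check_trial_table(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  d <- utils::read.csv(path)
  check_trial_table(d)
  d
}

check_trial_table <- function(d) {
  need <- c("participant_id", "pair_id", "prosody", "choice")
  if (!is.data.frame(d) || !all(need %in% names(d))) {
    stop_cp(paste("trial table needs columns", paste(need, collapse = ", ")),
            "schema_error")
  }
  if (!all(d$prosody %in% 0:1) || !all(d$choice %in% 0:1)) {
    stop_cp("prosody and choice must be coded 0/1", "schema_error")
  }
  invisible(d)
}
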