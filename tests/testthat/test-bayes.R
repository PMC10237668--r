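test_that("the filler filter retains 40 of the 55 printed participants", {
  acc <- gen_filler_accuracies(seed = 4)
  kept <- filter_participants(acc)
  expect_length(kept, 40)
  # everyone at 100% passes
  all_perfect <- data.frame(participant_id = 1:10, n_correct = 20,
                            n_fillers = 20)
  expect_length(filter_participants(all_perfect), 10)
  # exactly 10% incorrect (2 of 20) fails; 1 of 20 passes
  edge <- data.frame(participant_id = 1:2, n_correct = c(18, 19),
                     n_fillers = 20)
  expect_equal(filter_participants(edge), 2L)
  # accuracy-only input works given the filler count
  acc2 <- data.frame(participant_id = 1:3, accuracy = c(1, 0.95, 0.9))
  expect_equal(filter_participants(acc2, n_fillers = 20), 1:2)
  expect_error(filter_participants(acc2), class = "schema_error")
})

test_that("the model ladder is nested as specified", {
  flags <- t(sapply(c("m0", "m1", "m2", "m3"), function(m) {
    s <- model_spec(m)
    c(s$prosody, s$slope_participant, s$slope_pair)
  }))
  expect_equal(unname(flags),
               rbind(c(FALSE, FALSE, FALSE), c(TRUE, FALSE, FALSE),
                     c(TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE)))
  # each model's terms are a superset of its predecessor's
  for (i in 1:3) expect_true(all(flags[i, ] <= flags[i + 1, ]))
  expect_error(model_spec("m4"))
  expect_error(prior_spec(0), class = "parameter_error")
})

test_that("Bayes-factor bands follow the reporting convention", {
  expect_equal(bf_band(c(32.7, 6.75, 1.5, 0.5, 0.05)),
               c("strong", "weak", "very weak", "none", "favors null"))
  expect_error(bf_band(-1), class = "argument_error")
})

test_that("fitting recovers coarse structure and reports diagnostics", {
  fit <- small_fit("m1")
  sm <- fit$summary
  expect_setequal(sm$parameter, c("b0", "bp", "sa", "sb"))
  # generating values: intercept -1.06, slope 0.39
  b0 <- sm[sm$parameter == "b0", ]
  expect_lt(b0$mean, 0)
  expect_true(b0$q2.5 <= b0$mean && b0$mean <= b0$q97.5)
  expect_true(all(c("rhat", "ess_bulk", "ess_tail", "divergences") %in%
                    names(fit$convergence)))
  expect_equal(fit$convergence$divergences, 0L)
  expect_equal(fit$convergence$n_kept, 2 * 900)
})

test_that("fit preconditions are enforced", {
  tt <- small_trials()
  expect_error(fit_choice_model(model_spec("m1"), tt[0, ], prior_spec()),
               class = "precondition_error")
  const <- tt
  const$prosody <- 0L
  expect_error(fit_choice_model(model_spec("m1"), const, prior_spec()),
               class = "precondition_error")
  # intercept model does not need both prosody levels
  expect_s3_class(suppressWarnings(
    fit_choice_model(model_spec("m0"), const, prior_spec(),
                     small_settings())), "cp_fit")
})

test_that("population summaries are invariant to participant relabelling", {
  tt <- small_trials()
  perm <- withr::with_seed(8, sample(unique(tt$participant_id)))
  tt2 <- tt
  tt2$participant_id <- perm[tt$participant_id]
  f1 <- small_fit("m1")
  f2 <- suppressWarnings(
    fit_choice_model(model_spec("m1"), tt2, prior_spec(1.5),
                     small_settings()))
  for (p in c("b0", "bp")) {
    expect_lt(abs(f1$summary$mean[f1$summary$parameter == p] -
                    f2$summary$mean[f2$summary$parameter == p]), 0.15)
  }
})

test_that("a convergence-contract violation is reported, never silent", {
  tt <- small_trials()
  harsh <- sampler_settings(chains = 2, iterations = 250, warmup = 50,
                            thin = 1, adapt = 100, seed = 3)
  expect_warning(
    fit_choice_model(model_spec("m2"), tt, prior_spec(1.5), harsh),
    class = "diagnostic_warning")
  expect_error(
    suppressWarnings(
      fit_choice_model(model_spec("m2"), tt, prior_spec(1.5), harsh,
                       strict = TRUE)),
    class = "diagnostic_failure")
})

test_that("effect summaries expose both exponentiation conventions", {
  fit <- small_fit("m3")
  eff <- summarize_effects(fit)
  pop <- eff$population
  bp <- pop[pop$parameter == "bp", ]
  draws <- fit$draws[, "bp"]
  expect_equal(bp$exp_mean_of_draws, mean(exp(draws)))
  expect_equal(bp$exp_of_mean, exp(mean(draws)))
  # Jensen: mean of exponentials exceeds exponential of the mean
  expect_gt(bp$exp_mean_of_draws, bp$exp_of_mean)
  # reciprocal odds on the intercept row
  b0 <- pop[pop$parameter == "b0", ]
  expect_equal(b0$reciprocal_odds, 1 / b0$odds)
  # variance table squares the SD posterior means
  expect_equal(eff$variances$variance, eff$variances$sd_mean^2)
  # per-participant table shape
  expect_equal(nrow(eff$participants), 15)
  expect_true(all(c("q2.5", "q97.5", "excludes_zero") %in%
                    names(eff$participants)))
  # capability error on models without participant slopes
  expect_error(summarize_effects(small_fit("m1"), participant_table = TRUE),
               class = "capability_error")
})

test_that("degenerate posteriors exponentiate exactly", {
  # intercept draws all equal to -1.06: odds are exactly exp(-1.06)
  draws <- matrix(-1.06, nrow = 50, ncol = 1,
                  dimnames = list(NULL, "b0"))
  sm <- causalprosody:::summarize_draws(draws, "b0")
  expect_equal(sm$exp_mean_of_draws, exp(-1.06))
  expect_equal(sm$exp_of_mean, exp(-1.06))
})
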