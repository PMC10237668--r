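test_that("the noiseless generator reduces to the pure condition contrast", {
  params <- contour_gen_params(score_sds = c(0, 0, 0), noise_sd = 0,
                               duration_means = c(subjective = 250,
                                                  objective = 250),
                               duration_sd = 0)
  ctr <- gen_contours(2, params, seed = 1)
  labels <- vapply(ctr, `[[`, "", "label")
  sub <- ctr[[grep("subjective", labels)[1]]]
  obj <- ctr[[grep("objective", labels)[1]]]
  expect_equal(sub$times, obj$times)
  u <- sub$times / 250
  dmeans <- params$condition_means
  expected <- (dmeans$subjective[["s2"]] - dmeans$objective[["s2"]]) *
    approx(params$grid, params$comp_shapes[, 2], xout = u)$y +
    (dmeans$subjective[["s3"]] - dmeans$objective[["s3"]]) *
    approx(params$grid, params$comp_shapes[, 3], xout = u)$y
  expect_equal(sub$values - obj$values, expected, tolerance = 1e-12)
})

test_that("contour generation is bit-reproducible under a seed", {
  a <- gen_contours(5, seed = 77)
  b <- gen_contours(5, seed = 77)
  expect_identical(a, b)
  c <- gen_contours(5, seed = 78)
  expect_false(identical(a, c))
})

test_that("FPCA on generated contours recovers the s2 condition contrast", {
  # three replicate sets of 200 contours; the averaged contrast estimate
  # has Monte-Carlo error well inside the +/- 0.05 band
  ds2 <- sapply(1:3, function(r) {
    raw <- gen_contours(100, seed = r)
    nc <- lapply(raw, normalize_time, grid_size = 101)
    fp <- fit_fpca(nc, 3)
    cond <- sub("_.*", "", fp$scores$label)
    mean(fp$scores$s2[cond == "subjective"]) -
      mean(fp$scores$s2[cond == "objective"])
  })
  expect_lt(abs(mean(ds2) - 0.85), 0.05)
})

test_that("response generation follows the hierarchical logistic model", {
  # null model: fair coin
  p0 <- generative_params(beta0 = 0, beta_prosody = 0,
                          sd_int_participant = 0, sd_int_pair = 0,
                          sd_slope_participant = 0, sd_slope_pair = 0,
                          seed = 5)
  tt <- gen_responses(200, p0)
  n <- nrow(tt)
  expect_lt(abs(mean(tt$choice) - 0.5), 3 * sqrt(0.25 / n))

  # SDs zero, defaults otherwise: objective rate = inverse-logit(-1.06)
  p1 <- generative_params(sd_int_participant = 0, sd_int_pair = 0,
                          sd_slope_participant = 0, sd_slope_pair = 0,
                          seed = 6)
  tt <- gen_responses(600, p1)
  obj <- tt$choice[tt$prosody == 0]
  expect_lt(abs(mean(obj) - plogis(-1.06)),
            3 * sqrt(plogis(-1.06) * (1 - plogis(-1.06)) / length(obj)))

  # saturation under an extreme prosody effect
  p2 <- generative_params(beta_prosody = 10, sd_int_participant = 0,
                          sd_int_pair = 0, sd_slope_participant = 0,
                          sd_slope_pair = 0, seed = 7)
  tt <- gen_responses(200, p2)
  expect_gt(mean(tt$choice[tt$prosody == 1]), 0.99)
})

test_that("trial tables are complete balanced crossings", {
  tt <- gen_responses(7, generative_params(seed = 9))
  expect_equal(nrow(tt), 7 * 15 * 2)
  counts <- table(tt$participant_id, tt$pair_id, tt$prosody)
  expect_true(all(counts == 1))
  expect_identical(gen_responses(7, generative_params(seed = 9)), tt)
})

test_that("random effects attenuate the marginal rate toward one half", {
  # population-average subjective-choice rate under nonzero random-effect
  # SDs lies strictly between the SDs = 0 rate and 0.5
  p <- generative_params_m0(seed = 31)
  withr::with_seed(42, {
    n <- 1e5
    eta <- p$beta0 + rnorm(n, 0, sqrt(p$sd_int_participant^2 +
                                        p$sd_int_pair^2))
    marginal <- mean(plogis(eta))
  })
  conditional <- plogis(p$beta0)
  expect_gt(marginal, conditional)
  expect_lt(marginal, 0.5)
  # and the generator agrees with the Monte-Carlo marginal
  tt <- gen_responses(2000, p)
  expect_lt(abs(mean(tt$choice) - marginal), 0.02)
})

test_that("filler accuracies reproduce the printed distribution", {
  acc <- gen_filler_accuracies(seed = 1)
  expect_equal(nrow(acc), 55)
  expect_equal(sum(acc$accuracy == 1), 38)
  band <- cut(acc$accuracy, c(-Inf, 0.4999, 0.6999, 0.8999, 0.9999, Inf),
              labels = c("lt50", "50-69", "70-89", "gt90", "100"))
  expect_equal(as.vector(table(band)), c(4, 8, 3, 2, 38))
  expect_equal(sum(table(band)), 55)
  # all values on the 20-filler lattice
  expect_true(all(acc$n_correct == round(acc$n_correct)))
  expect_true(all(acc$n_correct >= 0 & acc$n_correct <= 20))
  expect_identical(gen_filler_accuracies(seed = 1), acc)
})

test_that("trial tables round-trip through CSV", {
  tt <- gen_responses(3, generative_params(seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_table(tt, path)
  expect_equal(read_trial_table(path), tt)
  expect_error(write_trial_table(data.frame(a = 1), path),
               class = "schema_error")
})

test_that("invalid generator parameters are rejected", {
  expect_error(generative_params(sd_slope_pair = -0.1),
               class = "parameter_error")
  expect_error(gen_contours(1), class = "parameter_error")
  expect_error(contour_gen_params(noise_sd = -1), class = "parameter_error")
})
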