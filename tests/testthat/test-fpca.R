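test_that("fitted components are orthonormal with zero-mean scores", {
  nc <- toy_normalized_set(n = 14, grid_size = 31)
  fp <- fit_fpca(nc, 3)
  gram <- crossprod(fp$model$components)
  expect_lt(max(abs(gram - diag(3))), 1e-8)
  expect_lt(max(abs(colMeans(as.matrix(fp$scores[, c("s1", "s2", "s3")])))),
            1e-8)
  # eigenvalue ordering: score variances non-increasing
  v <- apply(as.matrix(fp$scores[, c("s1", "s2", "s3")]), 2, var)
  expect_true(all(diff(v) <= 1e-12))
  expect_true(all(diff(fp$model$score_sds) <= 1e-12))
  # sign convention: non-negative grid integral
  expect_true(all(colSums(fp$model$components) >= -1e-12))
})

test_that("a zero-variance training set gives the common curve and zero scores", {
  base <- normalize_time(contour(c(0, 50, 100), c(1, 2, 0)), 11)
  nc <- replicate(5, base, simplify = FALSE)
  fp <- fit_fpca(nc, 1)
  expect_equal(fp$model$mean_curve, base$values)
  expect_lt(max(abs(fp$scores$s1)), 1e-12)
})

test_that("components and scores match an SVD oracle on 50 contours", {
  raw <- gen_contours(25, contour_gen_params(grid_size = 41), seed = 9)
  nc <- lapply(raw, normalize_time, grid_size = 41)
  fp <- fit_fpca(nc, 3)
  X <- t(sapply(nc, `[[`, "values"))
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  for (k in 1:3) {
    v <- sv$v[, k]
    sgn <- sign(sum(v * fp$model$components[, k]))
    expect_lt(max(abs(fp$model$components[, k] - sgn * v)), 1e-8)
    expect_lt(max(abs(fp$scores[[paste0("s", k)]] -
                        sgn * sv$u[, k] * sv$d[k])), 1e-8)
  }
})

test_that("a single known component is recovered from rank-one data", {
  g <- seq(0, 1, length.out = 25)
  c1 <- sin(2 * pi * g)
  c1 <- c1 / sqrt(sum(c1^2))
  mu <- 1 - g
  set.seed(4)
  s_true <- rnorm(30, 0, 0.8)
  nc <- lapply(s_true, function(s) {
    structure(list(grid = g, values = mu + s * c1, label = NULL),
              class = "normalized_contour")
  })
  fp <- fit_fpca(nc, 1)
  sgn <- sign(sum(fp$model$components[, 1] * c1))
  expect_lt(max(abs(fp$model$components[, 1] - sgn * c1)), 1e-6)
  centered <- s_true - mean(s_true)
  expect_lt(max(abs(fp$scores$s1 - sgn * centered)) /
              max(abs(centered)), 1e-6)
  # rank error when asking for more structure than the data holds
  expect_error(fit_fpca(nc, 3), class = "rank_error")
})

test_that("projection is the orthonormal least-squares solution", {
  nc <- toy_normalized_set(n = 10, grid_size = 21)
  fp <- fit_fpca(nc, 3)
  target <- nc[[4]]
  s <- project(fp$model, target)
  ls <- qr.solve(fp$model$components, target$values - fp$model$mean_curve)
  expect_equal(unlist(s), ls, tolerance = 1e-10, ignore_attr = TRUE)
  expect_lt(max(abs(unlist(project(fp$model, structure(
    list(grid = fp$model$grid, values = fp$model$mean_curve, label = NULL),
    class = "normalized_contour"))))), 1e-10)
  bad <- normalize_time(contour(c(0, 10), c(0, 1)), 31)
  expect_error(project(fp$model, bad), class = "grid_error")
})

test_that("project then reconstruct round-trips scores to 1e-8", {
  nc <- toy_normalized_set(n = 12, grid_size = 101)
  fp <- fit_fpca(nc, 3)
  for (s in list(c(0, 0, 0), c(1.3, -0.5, 0.2), c(-2, 0.335, -0.065))) {
    rec <- reconstruct(fp$model, score_set(s), duration_ms = 200,
                       step_ms = 2)
    back <- project(fp$model, normalize_time(rec, 101))
    expect_equal(unlist(back), unlist(score_set(s)), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("reconstruction error is non-increasing in the number of components", {
  nc <- toy_normalized_set(n = 16, grid_size = 41)
  X <- t(sapply(nc, `[[`, "values"))
  errs <- sapply(1:3, function(k) {
    fp <- fit_fpca(nc, k)
    fitted <- sweep(as.matrix(fp$scores[, -1, drop = FALSE]) %*%
                      t(fp$model$components), 2, fp$model$mean_curve, `+`)
    mean((X - fitted)^2)
  })
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("reconstruction samples every step up to the duration", {
  nc <- toy_normalized_set(n = 8, grid_size = 101)
  fp <- fit_fpca(nc, 3)
  rec <- reconstruct(fp$model, score_set(c(0, 0, 0)), 285, 5)
  expect_equal(length(rec$times), 58)  # floor(285/5) + 1
  expect_equal(rec$times, seq(0, 285, by = 5))
  # mean curve comes back when all scores are zero
  expect_equal(rec$values,
               approx(fp$model$grid, fp$model$mean_curve,
                      xout = seq(0, 285, 5) / 285)$y)
  # no terminal extrapolated point when the duration is not divisible
  rec2 <- reconstruct(fp$model, score_set(c(0, 0, 0)), 283, 5)
  expect_equal(max(rec2$times), 280)
  expect_error(reconstruct(fp$model, score_set(0), -1, 5),
               class = "argument_error")
})

test_that("restyling substitutes the condition targets and is idempotent", {
  s <- score_set(c(0.2, 1.1, 0.4))
  expect_equal(unlist(restyle_scores(s, "subjective")),
               c(s1 = 0.2, s2 = 0.335, s3 = -0.065))
  expect_equal(unlist(restyle_scores(score_set(c(-0.7, 0, 0)), "objective")),
               c(s1 = -0.7, s2 = -0.515, s3 = 0.025))
  once <- restyle_scores(s, "subjective")
  expect_identical(restyle_scores(once, "subjective"), once)
  expect_error(restyle_scores(s, "emphatic"), class = "condition_error")
})

test_that("default condition targets give the production-study contrasts", {
  sub <- prosody_spec("subjective")
  obj <- prosody_spec("objective")
  expect_equal(sub$s2_target - obj$s2_target, +0.85, tolerance = 1e-15)
  expect_equal(sub$s3_target - obj$s3_target, -0.09, tolerance = 1e-15)
  expect_identical(sub$target_duration - obj$target_duration, 50)
})

test_that("a concave-positive FPC2 makes the subjective contour bulge mid-span", {
  params <- contour_gen_params(grid_size = 101)
  comps <- params$comp_shapes
  mid <- 51
  if (comps[mid, 2] < 0) comps[, 2] <- -comps[, 2]  # force concave-positive
  model <- structure(list(grid = params$grid, mean_shape = NULL,
                          mean_curve = params$mean_shape,
                          components = comps,
                          score_sds = c(1, 0.5, 0.2)),
                     class = "fpca_model")
  base <- score_set(c(0.4, 0, 0))
  sub <- reconstruct(model, restyle_scores(base, "subjective"), 285, 5)
  obj <- reconstruct(model, restyle_scores(base, "objective"), 285, 5)
  d <- sub$values - obj$values
  midpoint <- which.min(abs(sub$times - 285 / 2))
  expect_gt(d[midpoint], d[1])
  expect_gt(d[midpoint], d[length(d)])
})

test_that("FPCA models serialize to JSON and back", {
  nc <- toy_normalized_set(n = 8, grid_size = 21)
  fp <- fit_fpca(nc, 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_fpca_json(fp$model, path)
  back <- read_fpca_json(path)
  expect_equal(back$mean_curve, fp$model$mean_curve)
  expect_equal(back$components, fp$model$components)
  expect_equal(back$grid, fp$model$grid)
})

test_that("mismatched grids are rejected", {
  a <- normalize_time(contour(c(0, 100), c(0, 1)), 11)
  b <- normalize_time(contour(c(0, 100), c(0, 1)), 21)
  expect_error(fit_fpca(list(a, a, b), 1), class = "grid_error")
})
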