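#' Functional PCA of duration-normalized f0 contours
#'
#' Decomposes a set of contours on a shared grid into a mean curve plus up to
#' three orthonormal principal component curves, so that each contour is
#' approximated as
#' \deqn{F0(t) \approx \mu(t) + s_1 FPC_1(t) + s_2 FPC_2(t) + s_3 FPC_3(t),}
#' with the scores \eqn{s_k} specific to the contour and the curves shared by
#' the training set. The estimator is the eigendecomposition of the sample
#' covariance of the centered contours on the discretization grid (no
#' roughness penalty); components are orthonormal under the grid inner
#' product. The sign of each component is fixed by requiring a non-negative
#' grid integral (ties broken by making the first nonzero value positive), so
#' results are deterministic across platforms.
#'
#' @param contours List of [normalize_time()] outputs, all on the same grid.
#' @param n_components Number of components K, 1 to 3. Default 3.
#' @return A list with components:
#'   \describe{
#'     \item{model}{An `fpca_model`: `grid`, `mean_curve`, `components`
#'       (grid-size x K matrix), `score_sds`.}
#'     \item{scores}{A data.frame with columns `label`, `s1`..`sK`, one row
#'       per training contour.}
#'   }
#' @examples
#' set.seed(1)
#' raw <- gen_contours(20, seed = 1)
#' nc <- lapply(raw, normalize_time, grid_size = 51)
#' fp <- fit_fpca(nc, n_components = 3)
#' round(fp$model$score_sds, 2)
#' @export
fit_fpca <- function(contours, n_components = 3) {
  if (!length(contours) || !all(vapply(contours, inherits, TRUE,
                                       "normalized_contour"))) {
    stop_cp("fit_fpca expects a list of normalized contours",
            "invalid_contour_error")
  }
  n_components <- as.integer(n_components)
  if (is.na(n_components) || n_components < 1 || n_components > 3) {
    stop_cp("n_components must be 1, 2, or 3", "argument_error")
  }
  grid <- contours[[1]]$grid
  same <- vapply(contours, function(c) length(c$grid) == length(grid) &&
                   all(c$grid == grid), TRUE)
  if (!all(same)) stop_cp("all contours must share one grid", "grid_error")
  n <- length(contours)
  if (n < n_components + 1) {
    stop_cp("need at least n_components + 1 contours", "rank_error")
  }
  X <- t(vapply(contours, function(c) c$values, numeric(length(grid))))
  mean_curve <- colMeans(X)
  Xc <- sweep(X, 2, mean_curve, `-`)
  cv <- crossprod(Xc) / (n - 1)
  eg <- eigen(cv, symmetric = TRUE)
  if (sum(eg$values > max(eg$values, 0) * 1e-10) < n_components &&
      max(eg$values) > 0) {
    stop_cp("n_components exceeds the rank of the training set", "rank_error")
  }
  comps <- eg$vectors[, seq_len(n_components), drop = FALSE]
  comps <- apply(comps, 2, fix_component_sign)
  scores <- Xc %*% comps
  model <- structure(
    list(grid = grid, mean_curve = mean_curve, components = comps,
         score_sds = apply(scores, 2, stats::sd)),
    class = "fpca_model")
  labels <- vapply(seq_along(contours), function(i) {
    contours[[i]]$label %||% paste0("contour_", i)
  }, character(1))
  sc <- as.data.frame(scores)
  names(sc) <- paste0("s", seq_len(n_components))
  list(model = model, scores = cbind(data.frame(label = labels), sc))
}

# Sign convention: non-negative grid integral; if the integral is (numerically)
# zero, first nonzero value positive.
fix_component_sign <- function(v) {
  s <- sum(v)
  if (abs(s) > 1e-12) {
    if (s < 0) -v else v
  } else {
    nz <- v[abs(v) > 1e-12]
    if (length(nz) && nz[1] < 0) -v else v
  }
}

#' @export
print.fpca_model <- function(x, ...) {
  cat(sprintf("<fpca_model: %d grid points, %d components, score SDs %s>\n",
              length(x$grid), ncol(x$components),
              paste(sprintf("%.3f", x$score_sds), collapse = ", ")))
  invisible(x)
}

#' Project a contour onto a fitted FPCA model
#'
#' Scores are the inner products of the centered contour with each component
#' curve; under orthonormality this is also the least-squares fit of the
#' components to the centered contour.
#'
#' @param model An `fpca_model`.
#' @param ncontour A `normalized_contour` on the model's grid.
#' @return A `score_set`: named list with `s1`..`sK`.
#' @export
project <- function(model, ncontour) {
  stopifnot(inherits(model, "fpca_model"))
  if (!inherits(ncontour, "normalized_contour")) {
    stop_cp("project expects a normalized contour", "invalid_contour_error")
  }
  if (length(ncontour$grid) != length(model$grid) ||
      !all(ncontour$grid == model$grid)) {
    stop_cp("contour grid does not match the model grid", "grid_error")
  }
  s <- drop(crossprod(model$components, ncontour$values - model$mean_curve))
  score_set(s)
}

#' Construct a score set
#' @param s Numeric vector of component weights (length K <= 3).
#' @return A `score_set` list with elements `s1`..`sK`.
#' @export
score_set <- function(s) {
  s <- as.numeric(s)
  if (!length(s) || length(s) > 3 || !all(is.finite(s))) {
    stop_cp("scores must be 1-3 finite values", "argument_error")
  }
  structure(as.list(stats::setNames(s, paste0("s", seq_along(s)))),
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat("<score_set:", paste(sprintf("%s = %+.3f", names(x), unlist(x)),
                           collapse = ", "), ">\n")
  invisible(x)
}

#' Restyle component scores to a prosodic condition
#'
#' Imposes a prosodic category on a contour by replacing the second and third
#' component weights with the condition's target values while preserving the
#' token's own first component weight (overall level/tilt). Defaults follow
#' the production-study targets: subjective s2 = +0.335, s3 = -0.065;
#' objective s2 = -0.515, s3 = +0.025.
#'
#' @param scores A [score_set()] with three components.
#' @param condition `"subjective"` or `"objective"`.
#' @param spec A [prosody_spec()]; defaults to `prosody_spec(condition)`.
#' @return A restyled `score_set`.
#' @examples
#' restyle_scores(score_set(c(0.2, 1.1, 0.4)), "subjective")
#' @export
restyle_scores <- function(scores, condition, spec = prosody_spec(condition)) {
  stopifnot(inherits(scores, "score_set"))
  condition <- check_condition(condition)
  if (spec$condition != condition) {
    stop_cp("spec condition does not match the requested condition",
            "condition_error")
  }
  if (length(scores) < 3) {
    stop_cp("restyling requires a 3-component score set", "argument_error")
  }
  score_set(c(scores$s1, spec$s2_target, spec$s3_target))
}

check_condition <- function(condition) {
  if (length(condition) != 1 ||
      !condition %in% c("subjective", "objective")) {
    stop_cp("condition must be \"subjective\" or \"objective\"",
            "condition_error")
  }
  condition
}

#' Reconstruct an f0 contour from a model and scores
#'
#' Evaluates mu + sum_k s_k FPC_k on the normalized grid, then resamples the
#' curve (linear interpolation) at 0, `step_ms`, 2 `step_ms`, ... up to
#' `duration_ms` (the endpoint is included only when the duration is an exact
#' multiple of the step).
#'
#' @param model An `fpca_model`.
#' @param scores A [score_set()] with at most K components.
#' @param duration_ms Target duration in ms (> 0).
#' @param step_ms Sampling step in ms (> 0), default 5.
#' @param label Optional label for the output contour.
#' @return A [contour()] sampled every `step_ms`.
#' @export
reconstruct <- function(model, scores, duration_ms, step_ms = 5,
                        label = NULL) {
  stopifnot(inherits(model, "fpca_model"), inherits(scores, "score_set"))
  if (!is.numeric(duration_ms) || duration_ms <= 0 ||
      !is.numeric(step_ms) || step_ms <= 0) {
    stop_cp("duration_ms and step_ms must be positive", "argument_error")
  }
  k <- length(scores)
  if (k > ncol(model$components)) {
    stop_cp("more scores than model components", "argument_error")
  }
  curve <- model$mean_curve
  for (i in seq_len(k)) {
    curve <- curve + scores[[i]] * model$components[, i]
  }
  times <- seq(0, duration_ms, by = step_ms)
  vals <- stats::approx(model$grid, curve, xout = times / duration_ms,
                        rule = 2)$y
  contour(times, vals, label = label)
}

#' Serialize / load an FPCA model as JSON
#'
#' @param model An `fpca_model`.
#' @param path File path for the JSON document.
#' @return `write_fpca_json()` returns `path` invisibly; `read_fpca_json()`
#'   returns the `fpca_model`.
#' @export
write_fpca_json <- function(model, path) {
  stopifnot(inherits(model, "fpca_model"))
  jsonlite::write_json(
    list(grid = model$grid, mean_curve = model$mean_curve,
         components = unclass(as.data.frame(model$components)),
         score_sds = model$score_sds),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_fpca_json
#' @export
read_fpca_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  comps <- as.matrix(as.data.frame(j$components))
  dimnames(comps) <- NULL
  structure(list(grid = j$grid, mean_curve = j$mean_curve,
                 components = comps, score_sds = j$score_sds),
            class = "fpca_model")
}
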