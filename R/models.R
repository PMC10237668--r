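#' Filter participants by filler accuracy
#'
#' Participants who answered 10% or more of the filler trials incorrectly
#' are treated as having failed the attention check and are excluded; the
#' boundary case (exactly 10% incorrect) fails. The comparison is done on
#' integer counts so lattice values are handled exactly.
#'
#' @param accuracies A data.frame from [gen_filler_accuracies()] or with at
#'   least `participant_id` and either `n_correct` + `n_fillers` or
#'   `accuracy`.
#' @param fail_fraction Incorrect fraction at (and above) which a
#'   participant fails; default 0.10.
#' @param n_fillers Filler count used when only `accuracy` is present.
#' @return Integer vector of retained participant ids.
#' @examples
#' acc <- gen_filler_accuracies(seed = 1)
#' length(filter_participants(acc))  # 40
#' @export
filter_participants <- function(accuracies, fail_fraction = 0.10,
                                n_fillers = NULL) {
  if (!is.data.frame(accuracies) || !"participant_id" %in% names(accuracies)) {
    stop_cp("accuracies needs a participant_id column", "schema_error")
  }
  if (all(c("n_correct", "n_fillers") %in% names(accuracies))) {
    nf <- accuracies$n_fillers
    wrong <- nf - accuracies$n_correct
  } else if ("accuracy" %in% names(accuracies)) {
    if (is.null(n_fillers)) {
      stop_cp("n_fillers is required when only accuracy is given",
              "schema_error")
    }
    nf <- rep(n_fillers, nrow(accuracies))
    wrong <- round((1 - accuracies$accuracy) * nf)
  } else {
    stop_cp("accuracies needs n_correct/n_fillers or accuracy columns",
            "schema_error")
  }
  retained <- wrong < fail_fraction * nf - 1e-9
  accuracies$participant_id[retained]
}

#' Specify a model in the analysis ladder
#'
#' The four nested Bayesian logistic models compared in the analysis:
#' \describe{
#'   \item{m0}{`~ 1 + (1|participant) + (1|pair)`}
#'   \item{m1}{`~ prosody + (1|participant) + (1|pair)`}
#'   \item{m2}{`~ prosody + (1+prosody|participant) + (1|pair)`}
#'   \item{m3}{`~ prosody + (1+prosody|participant) + (1+prosody|pair)`}
#' }
#' Intercept/slope pairs are modelled as independent (no correlation
#' parameter).
#'
#' @param name One of `"m0"`, `"m1"`, `"m2"`, `"m3"`.
#' @return A `model_spec` with logical fields `prosody`,
#'   `slope_participant`, `slope_pair`.
#' @export
model_spec <- function(name = c("m0", "m1", "m2", "m3")) {
  name <- match.arg(name)
  structure(list(name = name,
                 prosody = name != "m0",
                 slope_participant = name %in% c("m2", "m3"),
                 slope_pair = name == "m3"),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  f <- paste0("choice ~ ", if (x$prosody) "prosody" else "1",
              if (x$slope_participant) " + (1+prosody|participant)"
              else " + (1|participant)",
              if (x$slope_pair) " + (1+prosody|pair)" else " + (1|pair)")
  cat(sprintf("<model_spec %s: %s>\n", x$name, f))
  invisible(x)
}

#' Specify a prior for the population-level coefficients
#'
#' A zero-mean normal prior with the given SD, applied to the intercept and
#' the prosody coefficient. Random-effect SDs always carry a half-normal(0, 1)
#' prior (see the methods vignette).
#'
#' @param sd Prior SD (> 0); the study screens SDs 10, 1.5, 1, 0.5, 0.25 in
#'   prior predictive checks and uses 1.5, 1, 0.5 for Bayes factors.
#' @return A `prior_spec`.
#' @export
prior_spec <- function(sd = 1.5) {
  if (!is.numeric(sd) || sd <= 0) stop_cp("prior sd must be > 0",
                                          "parameter_error")
  structure(list(family = "normal", mean = 0, sd = sd), class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("<prior_spec: normal(0, %g)>\n", x$sd))
  invisible(x)
}

#' Interpret a Bayes factor on the conventional scale
#'
#' @param bf10 Positive Bayes factor for the richer model.
#' @return Character band: `"strong"` (> 10), `"weak"` (3-10), `"very weak"`
#'   (1-3), `"none"` (0.1-1), `"favors null"` (< 0.1).
#' @export
bf_band <- function(bf10) {
  if (!is.numeric(bf10) || any(bf10 <= 0)) {
    stop_cp("bf10 must be positive", "argument_error")
  }
  cut(bf10, breaks = c(0, 0.1, 1, 3, 10, Inf),
      labels = c("favors null", "none", "very weak", "weak", "strong"),
      right = FALSE) |> as.character()
}
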