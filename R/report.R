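#' Render a human-readable report of a pipeline run
#'
#' Writes a plain-text summary mirroring the analysis narrative (baseline
#' odds, prosody odds ratio under both exponentiation conventions, random
#' slope variability, the Bayes-factor table) plus two forest-style figures:
#' the population/SD parameters of the fullest fitted model, and the
#' per-participant prosody slopes. Every table footer carries the run's
#' config hash.
#'
#' @param run The list returned by [run_pipeline()].
#' @param outdir Output directory; defaults to the run's.
#' @return Invisibly, the path of the text report.
#' @export
report_run <- function(run, outdir = run$config$outdir) {
  if (is.null(run$effects) || is.null(run$bf_table)) {
    stop_cp("run is missing stage outputs (effects/bf_table); run the pipeline first",
            "reporting_error")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  eff <- run$effects
  pop <- eff$population
  lines <- c(
    sprintf("Pipeline report  [config %s, seed %d]", run$hash,
            run$config$seed),
    sprintf("Stimuli built: %d; participants retained: %d",
            length(run$stimuli), length(run$retained)),
    "")
  b0 <- pop[pop$parameter == "b0", ]
  lines <- c(lines, sprintf(
    "Baseline (intercept): %.2f log-odds; odds of subjective choice %.2f, of objective choice %.2f (1/odds)",
    b0$mean, b0$odds, b0$reciprocal_odds))
  if ("bp" %in% pop$parameter) {
    bp <- pop[pop$parameter == "bp", ]
    spans1 <- bp$q2.5 <= 0 && bp$q97.5 >= 0
    lines <- c(lines, sprintf(
      "Prosody effect: %.2f log-odds (95%% CrI [%.2f, %.2f]); odds ratio %.2f (mean of exponentiated draws) / %.2f (exp of posterior mean)%s",
      bp$mean, bp$q2.5, bp$q97.5, bp$exp_mean_of_draws, bp$exp_of_mean,
      if (spans1) " - CrI for the odds ratio spans 1" else ""))
  }
  for (i in seq_len(nrow(eff$variances))) {
    v <- eff$variances[i, ]
    lines <- c(lines, sprintf(
      "sd(%s) by %s: %.2f (variance %.2f)", v$term, v$group, v$sd_mean,
      v$variance))
  }
  lines <- c(lines, "", "Bayes factors (BF10):")
  for (i in seq_len(nrow(run$bf_table))) {
    r <- run$bf_table[i, ]
    lines <- c(lines, sprintf("  %-18s prior normal(0, %g): %8.3g  [%s]",
                              r$parameter, r$prior_sd, r$bf10, r$band))
  }
  lines <- c(lines, "", sprintf("[config %s]", run$hash))
  path <- file.path(outdir, "report.txt")
  writeLines(lines, path)

  top_fit_key <- sprintf("%s_sd%g",
                         run$config$models[length(run$config$models)],
                         run$config$prior_sds[1])
  fit <- run$fits[[top_fit_key]]
  sm <- fit$summary
  sm$parameter <- factor(sm$parameter, levels = rev(sm$parameter))
  g1 <- ggplot2::ggplot(sm, ggplot2::aes(x = mean,
                                         y = parameter)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = q2.5,
                                         xmax = q97.5),
                            height = 0, linewidth = 0.4) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = q25,
                                         xmax = q75),
                            height = 0, linewidth = 1.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "posterior (log-odds / SD scale)", y = NULL,
                  title = sprintf("Posterior summaries, %s", fit$spec$name),
                  caption = sprintf("config %s", run$hash)) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(outdir, "population_forest.png"), g1,
                  width = 6, height = 4, dpi = 120)

  if (!is.null(eff$participants)) {
    pt <- eff$participants
    pt <- pt[order(pt$mean), ]
    pt$participant_id <- factor(pt$participant_id,
                                levels = pt$participant_id)
    g2 <- ggplot2::ggplot(pt, ggplot2::aes(x = mean,
                                           y = participant_id)) +
      ggplot2::geom_errorbarh(ggplot2::aes(xmin = q2.5,
                                           xmax = q97.5),
                              height = 0, linewidth = 0.3) +
      ggplot2::geom_errorbarh(ggplot2::aes(xmin = q25,
                                           xmax = q75),
                              height = 0, linewidth = 1) +
      ggplot2::geom_point(size = 1) +
      ggplot2::geom_vline(xintercept = 0, linetype = 2) +
      ggplot2::labs(x = "prosody slope (log-odds)", y = "participant",
                    title = "Per-participant prosody slopes",
                    caption = sprintf("config %s", run$hash)) +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(outdir, "participant_slopes.png"), g2,
                    width = 5, height = 7, dpi = 120)
  }
  invisible(path)
}
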