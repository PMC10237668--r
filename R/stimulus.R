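#' Per-condition prosody targets
#'
#' Bundles the acoustic targets that define a prosodic condition for the
#' connective "so": the target total duration and the substitution values for
#' the second and third FPCA score. Defaults reproduce the production-study
#' contrasts: subjective 285 ms, s2 = +0.335, s3 = -0.065; objective 235 ms,
#' s2 = -0.515, s3 = +0.025 (differences +0.85, -0.09, 50 ms).
#'
#' @param condition `"subjective"` or `"objective"`.
#' @param target_duration Target connective duration, ms (> 0).
#' @param s2_target,s3_target Substitution weights for FPC2 / FPC3.
#' @return A `prosody_spec` list.
#' @examples
#' prosody_spec("subjective")
#' prosody_spec("objective")$target_duration
#' @export
prosody_spec <- function(condition,
                         target_duration = NULL,
                         s2_target = NULL,
                         s3_target = NULL) {
  condition <- check_condition(condition)
  defaults <- list(
    subjective = list(target_duration = 285, s2_target = +0.335,
                      s3_target = -0.065),
    objective = list(target_duration = 235, s2_target = -0.515,
                     s3_target = +0.025))[[condition]]
  td <- target_duration %||% defaults$target_duration
  if (!is.numeric(td) || td <= 0) {
    stop_cp("target_duration must be positive", "argument_error")
  }
  structure(list(condition = condition,
                 target_duration = td,
                 s2_target = s2_target %||% defaults$s2_target,
                 s3_target = s3_target %||% defaults$s3_target),
            class = "prosody_spec")
}

#' @export
print.prosody_spec <- function(x, ...) {
  cat(sprintf("<prosody_spec %s: %g ms, s2 -> %+.3f, s3 -> %+.3f>\n",
              x$condition, x$target_duration, x$s2_target, x$s3_target))
  invisible(x)
}

#' A segmented speech token
#'
#' A token (here, the connective "so") as an ordered list of phone segments
#' with durations, plus the f0 contour spanning the token. The contour's time
#' extent must match the summed segment durations to within 1 ms.
#'
#' @param segments data.frame with columns `label` and `duration` (ms > 0).
#' @param contour A [contour()] spanning the token.
#' @param tol Permitted mismatch (ms) between contour extent and total
#'   segment duration; default 1.
#' @return A `segmented_token`.
#' @examples
#' tok <- segmented_token(
#'   data.frame(label = c("s", "@U"), duration = c(100, 150)),
#'   contour(c(0, 125, 250), c(0, 1, -1)))
#' @export
segmented_token <- function(segments, contour, tol = 1) {
  if (!is.data.frame(segments) ||
      !all(c("label", "duration") %in% names(segments)) ||
      !nrow(segments)) {
    stop_cp("segments must be a data.frame with label and duration",
            "argument_error")
  }
  if (any(segments$duration <= 0)) {
    stop_cp("segment durations must be positive", "degenerate_token_error")
  }
  stopifnot(inherits(contour, "contour"))
  total <- sum(segments$duration)
  if (abs(duration(contour) - total) > tol) {
    stop_cp("contour extent must equal total segment duration",
            "invalid_contour_error")
  }
  structure(list(segments = segments, contour = contour),
            class = "segmented_token")
}

#' Total duration of a segmented token, ms
#' @param token A [segmented_token()].
#' @export
token_duration <- function(token) {
  stopifnot(inherits(token, "segmented_token"))
  sum(token$segments$duration)
}

#' Rescale a token's duration, preserving segment ratios
#'
#' Multiplies every segment duration (and the contour's time axis) by
#' `target_total / current_total`, so the relative share of each phone is
#' untouched while the token reaches the condition's target length.
#'
#' @param token A [segmented_token()].
#' @param target_total Target total duration, ms (> 0).
#' @return The rescaled `segmented_token`.
#' @examples
#' tok <- segmented_token(
#'   data.frame(label = c("s", "@U"), duration = c(100, 150)),
#'   contour(c(0, 125, 250), c(0, 1, -1)))
#' scale_duration(tok, 285)$segments$duration  # 114, 171
#' @export
scale_duration <- function(token, target_total) {
  stopifnot(inherits(token, "segmented_token"))
  if (!is.numeric(target_total) || target_total <= 0) {
    stop_cp("target_total must be positive", "argument_error")
  }
  current <- token_duration(token)
  if (current <= 0) stop_cp("token has zero duration", "degenerate_token_error")
  f <- target_total / current
  segments <- token$segments
  segments$duration <- segments$duration * f
  ctr <- token$contour
  segmented_token(segments, contour(ctr$times * f, ctr$values,
                                    label = ctr$label))
}

#' A built (or to-be-built) stimulus
#'
#' One audio stimulus: an untouched "event"-clause contour followed, after an
#' optional silent gap, by the (manipulated) connective token.
#'
#' @param clip_id Identifier of the clip.
#' @param pair_id Item pair number (1-15).
#' @param condition `"subjective"`, `"objective"`, or NA before building.
#' @param event_clause_contour A [contour()] for the event clause.
#' @param connective A [segmented_token()] for the connective "so".
#' @param gap_ms Silent interval between clause offset and connective onset
#'   (ms >= 0).
#' @return A `stimulus_record`. The connective onset (`connective_onset_ms`)
#'   is the clause extent plus the gap.
#' @export
stimulus_record <- function(clip_id, pair_id, condition = NA_character_,
                            event_clause_contour, connective, gap_ms = 0) {
  stopifnot(inherits(event_clause_contour, "contour"),
            inherits(connective, "segmented_token"))
  if (!is.numeric(gap_ms) || gap_ms < 0) {
    stop_cp("gap_ms must be >= 0", "argument_error")
  }
  if (!is.na(condition)) condition <- check_condition(condition)
  structure(list(clip_id = clip_id,
                 pair_id = as.integer(pair_id),
                 condition = condition,
                 event_clause_contour = event_clause_contour,
                 connective = connective,
                 gap_ms = gap_ms,
                 connective_onset_ms = duration(event_clause_contour) + gap_ms),
            class = "stimulus_record")
}

#' @export
print.stimulus_record <- function(x, ...) {
  cat(sprintf(
    "<stimulus_record %s: pair %d, %s, connective %.1f ms, gap %.1f ms>\n",
    x$clip_id, x$pair_id, if (is.na(x$condition)) "unbuilt" else x$condition,
    token_duration(x$connective), x$gap_ms))
  invisible(x)
}

#' Remove the clause-connective silent interval
#'
#' Sets the gap to zero and shifts the connective onset earlier by the
#' removed amount; both contours are unchanged internally, so the total
#' stimulus duration shrinks by exactly the gap.
#'
#' @param record A [stimulus_record()].
#' @return The record with `gap_ms = 0`.
#' @export
remove_gap <- function(record) {
  stopifnot(inherits(record, "stimulus_record"))
  record$connective_onset_ms <- record$connective_onset_ms - record$gap_ms
  record$gap_ms <- 0
  record
}

#' Total stimulus duration (clause + gap + connective), ms
#' @param record A [stimulus_record()].
#' @export
stimulus_duration <- function(record) {
  stopifnot(inherits(record, "stimulus_record"))
  duration(record$event_clause_contour) + record$gap_ms +
    token_duration(record$connective)
}

#' Build one manipulated stimulus
#'
#' Composes the full manipulation chain for a clip: the connective contour is
#' duration-normalized and projected onto the FPCA model, its s2/s3 scores
#' are replaced by the condition targets, a new contour is reconstructed at
#' the condition's target duration every `step_ms`, the connective segments
#' are rescaled (ratio-preserving) to the same target, and the silent gap is
#' removed. The event-clause contour is left bit-identical.
#'
#' @param clip A [stimulus_record()] holding the raw clip.
#' @param model A fitted `fpca_model`.
#' @param spec A [prosody_spec()].
#' @param step_ms Reconstruction step, ms; default 5.
#' @return The built `stimulus_record`, annotated with the condition.
#' @export
build_stimulus <- function(clip, model, spec, step_ms = 5) {
  stopifnot(inherits(clip, "stimulus_record"),
            inherits(model, "fpca_model"),
            inherits(spec, "prosody_spec"))
  nc <- normalize_time(clip$connective$contour,
                       grid_size = length(model$grid))
  scores <- restyle_scores(project(model, nc), spec$condition, spec)
  new_contour <- reconstruct(model, scores, spec$target_duration,
                             step_ms = step_ms,
                             label = clip$connective$contour$label)
  scaled <- scale_duration(clip$connective, spec$target_duration)
  segments <- scaled$segments
  connective <- segmented_token(segments, new_contour, tol = step_ms)
  out <- stimulus_record(clip_id = clip$clip_id, pair_id = clip$pair_id,
                         condition = spec$condition,
                         event_clause_contour = clip$event_clause_contour,
                         connective = connective, gap_ms = clip$gap_ms)
  out <- remove_gap(out)
  out$scores <- scores
  out
}

#' Build the full stimulus set
#'
#' Applies [build_stimulus()] to each clip under both prosodic conditions
#' (15 pairs x 2 conditions = 30 records in the default design).
#'
#' @param clips List of raw [stimulus_record()]s, one per pair.
#' @param model A fitted `fpca_model`.
#' @param specs List of [prosody_spec()]s; default both conditions at their
#'   default targets.
#' @return List of built `stimulus_record`s.
#' @export
build_stimulus_set <- function(clips, model,
                               specs = list(prosody_spec("subjective"),
                                            prosody_spec("objective"))) {
  out <- list()
  for (clip in clips) {
    for (spec in specs) {
      rec <- build_stimulus(clip, model, spec)
      rec$clip_id <- paste0(clip$clip_id, "_",
                            substr(spec$condition, 1, 1))
      out[[length(out) + 1]] <- rec
    }
  }
  out
}

#' Export a built stimulus for external resynthesis
#'
#' Writes the restyling specification an external PSOLA resynthesizer needs:
#' a PitchTier with the restyled connective contour (point times are relative
#' to the stimulus, i.e. offset by the connective onset) and a TextGrid with
#' a clause/connective tier plus a segment tier. Durations are rounded
#' half-up to 0.1 ms at export only.
#'
#' @param record A built [stimulus_record()].
#' @param path Base path; writes `<path>.PitchTier` and `<path>.TextGrid`.
#' @return Named character vector of the written paths, invisibly.
#' @export
export_praat <- function(record, path) {
  stopifnot(inherits(record, "stimulus_record"))
  onset <- record$connective_onset_ms
  ctr <- record$connective$contour
  shifted <- contour(round((ctr$times - ctr$times[1] + onset) * 10) / 10,
                     ctr$values, label = ctr$label)
  pt_path <- paste0(path, ".PitchTier")
  tg_path <- paste0(path, ".TextGrid")
  write_pitchtier(shifted, pt_path)
  seg <- record$connective$segments
  seg_end <- onset + cumsum(round(seg$duration * 10) / 10)
  seg_start <- c(onset, seg_end[-length(seg_end)])
  tiers <- list(
    clause = data.frame(
      xmin = c(0, onset),
      xmax = c(onset, onset + token_duration(record$connective)),
      text = c("event clause", "so")),
    segments = data.frame(xmin = seg_start, xmax = seg_end,
                          text = seg$label))
  write_textgrid(tiers, tg_path)
  invisible(c(pitchtier = pt_path, textgrid = tg_path))
}

#' Write a JSON manifest of built stimuli
#'
#' @param records List of built [stimulus_record()]s.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_stimulus_manifest <- function(records, path) {
  rows <- lapply(records, function(r) {
    list(clip_id = r$clip_id, pair_id = r$pair_id, condition = r$condition,
         connective_duration_ms = token_duration(r$connective),
         gap_ms = r$gap_ms,
         n_pitch_points = length(r$connective$contour$times),
         scores = if (!is.null(r$scores)) unclass(r$scores))
  })
  jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
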