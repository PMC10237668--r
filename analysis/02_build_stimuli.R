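#!/usr/bin/env Rscript
# Stage 2: assemble the 30 manipulated stimuli (15 pairs x 2 prosodic
# conditions) from the fitted FPCA model and export the restyling
# specifications (PitchTier + TextGrid) for an external resynthesizer.

suppressPackageStartupMessages(library(causalprosody))

seed <- 1
outdir <- "results"
praat_dir <- file.path(outdir, "praat")
dir.create(praat_dir, recursive = TRUE, showWarnings = FALSE)

params <- contour_gen_params()
contours <- gen_contours(15, params, seed = seed)
nc <- lapply(contours, normalize_time, grid_size = 101)
fp <- fit_fpca(nc, n_components = 3)

labels <- vapply(contours, `[[`, "", "label")
clips <- lapply(1:15, function(i) {
  ctr <- contours[grep("^objective", labels)][[i]]
  seg <- data.frame(label = c("s", "@U"),
                    duration = c(0.4, 0.6) * duration(ctr))
  stimulus_record(sprintf("clip_%02d", i), i,
                  event_clause_contour = contour(c(0, 800), c(2, -2)),
                  connective = segmented_token(seg, ctr), gap_ms = 80)
})

records <- build_stimulus_set(clips, fp$model)
write_stimulus_manifest(records, file.path(outdir, "stimulus_manifest.json"))
for (r in records) export_praat(r, file.path(praat_dir, r$clip_id))

durs <- vapply(records, function(r) token_duration(r$connective), 0)
conds <- vapply(records, `[[`, "", "condition")
cat(sprintf("built %d stimuli; connective durations %g ms (subjective) / %g ms (objective)\n",
            length(records), round(mean(durs[conds == "subjective"]), 6),
            round(mean(durs[conds == "objective"]), 6)))
cat(sprintf("restyled scores: subjective (%+.3f, %+.3f), objective (%+.3f, %+.3f)\n",
            records[[1]]$scores$s2, records[[1]]$scores$s3,
            records[[2]]$scores$s2, records[[2]]$scores$s3))
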