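#!/usr/bin/env Rscript
# Stage 6: one-command end-to-end run with the pipeline orchestrator,
# rendering the text report and forest-style figures under results/run/.

suppressPackageStartupMessages(library(causalprosody))

cfg <- run_config(seed = 1, outdir = file.path("results", "run"))
run <- suppressWarnings(run_pipeline(cfg))
report <- report_run(run)
cat(readLines(report), sep = "\n")
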