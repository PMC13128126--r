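#!/usr/bin/env Rscript
# Stage 6 — the orchestrated end-to-end run: every stage through
# run_pipeline() with content-hash caching, producing the machine-readable
# run report. Also records the flow-cytometry genome-size arithmetic.

source("analysis/_common.R")
cfg <- study_config()
outdir <- results_dir("pipeline")

gs <- estimate_genome_size(570, 0.68)
say("flow-cytometry genome size: %.1f Mb (rounded %d Mb)",
    gs$size_mb, gs$size_mb_rounded)

report <- run_pipeline(cfg, outdir, codons = 300)
print(report)
say("report written to %s", file.path(outdir, "report.json"))
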