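# Shared setup for the numbered analysis drivers. One study configuration is
# used throughout: an XY system with the full F1 phenotype panel
# (38 F / 89 M / 59 non-flowering), a 4 Mb SDR in the middle of a 10 Mb sex
# chromosome plus one autosome, 30x coverage with negative-binomial noise,
# 22 gametolog pairs near the expected median divergence, and two planted
# candidate genes. Every stage is seeded, so the drivers can be run
# independently and still describe the same simulated study.

library(sexscan)

results_dir <- function(sub = NULL) {
  d <- file.path("results", sub %||% "")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}
`%||%` <- function(x, y) if (is.null(x)) y else x

study_config <- function(seed = 1L) {
  sim_config(n_chromosomes = 2, chromosome_length_bp = 1e7,
             sdr_chromosome = 2, sdr_interval = c(4000001, 8000000),
             seed = seed)
}

say <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...))
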