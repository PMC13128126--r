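#!/usr/bin/env Rscript
# Stage 1 — simulate the study: genome architecture (truth), the F1 cross
# genotypes, and the sample sheet. Writes the reference tables other stages
# and external tools consume.

source("analysis/_common.R")
cfg <- study_config()
outdir <- results_dir("sim")

truth <- simulate_truth(cfg)
paths <- write_truth_files(truth, outdir)
say("truth: %s system, SDR on %s at %s-%s (%.1f Mb)",
    truth$system, truth$sdr$chrom,
    format(truth$sdr$specific[1], big.mark = ","),
    format(truth$sdr$specific[2], big.mark = ","),
    diff(truth$sdr$specific) / 1e6)
say("genes: %d total, %d Y-region (%d gametolog pairs, %d Y-specific)",
    nrow(truth$genes),
    sum(truth$genes$haplotype == "Y" & truth$genes$region == "SDR"),
    sum(truth$genes$haplotype == "Y" & truth$genes$y_specificity == "XY_gametolog",
        na.rm = TRUE),
    sum(truth$genes$haplotype == "Y" & truth$genes$y_specificity == "Y_specific",
        na.rm = TRUE))

cross <- simulate_cross_genotypes(truth, cfg)
write_genotypes_tsv(cross, file.path(outdir, "genotypes.tsv"))
write_sample_sheet(cross$phenotypes, file.path(outdir, "samples.tsv"))
sexes <- table(cross$phenotypes$sex)
say("progeny: %d F, %d M flowering; %d non-flowering (phenotype U)",
    sexes[["F"]], sexes[["M"]], sexes[["U"]])
say("markers: %d (%d SNP, %d PA)", nrow(cross$genotypes),
    sum(cross$genotypes$type == "SNP"), sum(cross$genotypes$type == "PA"))
say("wrote %s", paste(basename(c(paths, "genotypes.tsv", "samples.tsv")),
                      collapse = ", "))
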