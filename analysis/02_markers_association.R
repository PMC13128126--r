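#!/usr/bin/env Rscript
# Stage 2 — pseudo-testcross marker classification, segregation filtering and
# the Fisher/BH sex-association scan; calls the heterogametic system.

source("analysis/_common.R")
cfg <- study_config()
outdir <- results_dir("assoc")

truth <- simulate_truth(cfg)
cross <- simulate_cross_genotypes(truth, cfg)
cls <- classify_markers(cross$genotypes, cross$female_parent, cross$male_parent)
say("marker categories:")
print(table(cls$category, cls$type))

# segregation distortion screen on informative markers (1:1 expectation)
flower <- cross$phenotypes$id[cross$phenotypes$sex %in% c("F", "M")]
inf <- cls[!is.na(cls$category) & cls$category != "uninformative", ]
gm <- as.matrix(cross$genotypes[match(inf$marker_id, cross$genotypes$marker_id),
                                flower, with = FALSE])
carrier <- gm == "AB" | gm == "P"
seg <- filter_segregation(data.frame(marker_id = inf$marker_id,
                                     n_carrier = rowSums(carrier, na.rm = TRUE),
                                     n_noncarrier = rowSums(!carrier, na.rm = TRUE)))
data.table::fwrite(seg, file.path(outdir, "segregation.tsv"), sep = "\t")
say("segregation filter: %d/%d pass at alpha 0.01 (SDR-linked markers are
  expected to distort toward the 38:89 sex ratio)", sum(seg$pass), nrow(seg))

scan <- association_scan(cls, cross$genotypes, cross$phenotypes,
                         cross$female_parent, cross$male_parent, fdr = 0.05)
data.table::fwrite(scan, file.path(outdir, "association_scan.tsv"), sep = "\t")
bal <- association_scan(cls, cross$genotypes, cross$phenotypes,
                        cross$female_parent, cross$male_parent, fdr = 0.05,
                        balanced = TRUE, seed = cfg$seed)
data.table::fwrite(bal, file.path(outdir, "association_scan_balanced.tsv"),
                   sep = "\t")

sys_call <- classify_sex_system(scan)
say("significant markers: %d male-het, %d female-het; balanced replicate: %d male-het",
    sys_call$n_significant[["male_het"]], sys_call$n_significant[["female_het"]],
    sum(bal$significant[grepl("^male_het", bal$category)]))
say("sex-determination system verdict: %s; peak %s:%s-%s",
    sys_call$verdict, sys_call$peak$chrom,
    format(sys_call$peak$start, big.mark = ","),
    format(sys_call$peak$end, big.mark = ","))
jsonlite::write_json(sys_call, file.path(outdir, "sex_system.json"),
                     auto_unbox = TRUE, digits = NA, na = "null")
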