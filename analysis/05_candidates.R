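#!/usr/bin/env Rscript
# Stage 5 — candidate sex-determining genes: differential expression of
# Y-region genes in the two contrasts (male vs female early flowers; male
# flowers vs non-reproductive organs) and the three-stage filter cascade.
# Also replays the cascade on the shipped printed Y-region table.

source("analysis/_common.R")
cfg <- study_config()
outdir <- results_dir("candidates")
truth <- simulate_truth(cfg)

expr <- simulate_expression_counts(truth, cfg)
write_counts_tsv(expr$counts, file.path(outdir, "counts.tsv"))
data.table::fwrite(expr$design, file.path(outdir, "design.tsv"), sep = "\t")
de1 <- de_summary(expr$counts, expr$design, c("M_flower", "F_flower"))
de2 <- de_summary(expr$counts, expr$design, c("M_flower", "nonreproductive"))
data.table::fwrite(de1, file.path(outdir, "de_male_vs_female.tsv"), sep = "\t")
data.table::fwrite(de2, file.path(outdir, "de_male_vs_nonrep.tsv"), sep = "\t")

yg <- truth$genes[truth$genes$haplotype == truth$hap_specific &
                  truth$genes$region == "SDR", ]
rows <- data.frame(gene = yg$gene_id, y_specificity = yg$y_specificity,
                   padj1 = de1$padj[match(yg$gene_id, de1$gene)],
                   log2FC1 = de1$log2FC[match(yg$gene_id, de1$gene)],
                   padj2 = de2$padj[match(yg$gene_id, de2$gene)],
                   log2FC2 = de2$log2FC[match(yg$gene_id, de2$gene)])
casc <- filter_cascade(rows, alpha = 0.05, lfc_min = 2)
print(casc)
say("planted candidates: %s; recovered exactly: %s",
    paste(truth$candidate_effects$gene_id, collapse = ", "),
    setequal(casc$final_candidates, truth$candidate_effects$gene_id))
jsonlite::write_json(unclass(casc), file.path(outdir, "cascade.json"),
                     auto_unbox = TRUE, digits = NA)

# the same cascade applied to the shipped printed table
tab <- read_de_table(system.file("extdata", "table1_y_region_de.tsv",
                                 package = "sexscan"))
printed <- filter_cascade(tab, alpha = 0.05, lfc_min = 2)
print(printed)
jsonlite::write_json(unclass(printed), file.path(outdir, "cascade_printed_table.json"),
                     auto_unbox = TRUE, digits = NA)
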