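#' Genome size from flow-cytometry fluorescence ratio
#'
#' The genome size of a sample is the reference standard's genome size times
#' the ratio of the sample and reference fluorescence signals.
#'
#' @param reference_size_mb reference standard genome size (Mb).
#' @param fluorescence_ratio sample/reference fluorescence ratio.
#' @return list with `size_mb` (raw product) and `size_mb_rounded`.
#' @export
estimate_genome_size <- function(reference_size_mb, fluorescence_ratio) {
  if (!is.numeric(reference_size_mb) || reference_size_mb <= 0 ||
      !is.numeric(fluorescence_ratio) || fluorescence_ratio <= 0)
    stopf("both inputs must be positive numbers")
  raw <- reference_size_mb * fluorescence_ratio
  list(size_mb = raw, size_mb_rounded = round(raw))
}

# stage-level cache keyed by a content hash of the stage configuration;
# reruns with an unchanged config reuse the stored stage output
stage_cached <- function(outdir, name, key, compute, use_cache = TRUE) {
  h <- hash_object(key)
  rds <- file.path(outdir, sprintf("stage_%s.rds", name))
  hf <- file.path(outdir, sprintf("stage_%s.hash", name))
  if (use_cache && file.exists(rds) && file.exists(hf) &&
      identical(readLines(hf, warn = FALSE)[1], h)) {
    return(readRDS(rds))
  }
  val <- tryCatch(compute(), error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  saveRDS(val, rds)
  writeLines(h, hf)
  val
}

#' Run the full simulated-study pipeline
#'
#' Orchestrates simulate -> marker classification -> association scan ->
#' depth scan on both haplotype assemblies -> gametolog divergence ->
#' expression cascade, and writes a machine-readable run report. Stage
#' outputs are cached in `outdir` keyed by a content hash of the stage
#' configuration, so unchanged stages are reused on partial reruns.
#'
#' @param config a [sim_config()].
#' @param outdir output directory for stage artifacts and the report.
#' @param fdr association-scan false discovery rate.
#' @param th [depth_thresholds()] for the depth scan.
#' @param window_bp,step_bp coarse depth windows (defaults 150 kb / 10 kb).
#' @param refine_window_bp,refine_step_bp refinement windows (20 kb / 1 kb).
#' @param codons CDS length used for simulated gametologs.
#' @param alpha,lfc_min cascade thresholds (0.05, 2).
#' @param use_cache reuse cached stage outputs when the config is unchanged.
#' @return list of class `run_report` (also written as `report.json`).
#' @export
run_pipeline <- function(config, outdir,
                         fdr = 0.05, th = depth_thresholds(),
                         window_bp = 150000, step_bp = 10000,
                         refine_window_bp = 20000, refine_step_bp = 1000,
                         codons = 200L, alpha = 0.05, lfc_min = 2.0,
                         use_cache = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_key <- unclass(config)

  truth <- stage_cached(outdir, "truth", cfg_key,
                        function() simulate_truth(config), use_cache)
  write_truth_files(truth, outdir)

  cross <- stage_cached(outdir, "cross", cfg_key,
                        function() simulate_cross_genotypes(truth, config), use_cache)
  write_genotypes_tsv(cross, file.path(outdir, "genotypes.tsv"))
  write_sample_sheet(cross$phenotypes, file.path(outdir, "samples.tsv"))

  assoc <- stage_cached(outdir, "assoc", c(cfg_key, fdr = fdr), function() {
    cls <- classify_markers(cross$genotypes, cross$female_parent, cross$male_parent)
    scan <- association_scan(cls, cross$genotypes, cross$phenotypes,
                             cross$female_parent, cross$male_parent, fdr = fdr)
    list(classes = cls, scan = scan, system = classify_sex_system(scan, fdr))
  }, use_cache)
  fwrite(assoc$scan, file.path(outdir, "association_scan.tsv"), sep = "\t")

  depth_key <- c(cfg_key, window_bp = window_bp, step_bp = step_bp,
                 refine_window_bp = refine_window_bp,
                 refine_step_bp = refine_step_bp, th = unclass(th))
  depth <- stage_cached(outdir, "depth", depth_key, function() {
    search <- c(1, config$chromosome_length_bp)
    sdr_chrom <- truth$sdr$chrom
    one <- function(hap, kind) {
      tr <- simulate_depth_tracks(truth, config, haplotype = hap)
      # the copy-number contrast is heterogametic (hemizygous) vs homogametic
      # sample; under ZW the female plays the role the male plays under XY
      het <- if (truth$het_sex == "M") tr$male else tr$female
      hom <- if (truth$het_sex == "M") tr$female else tr$male
      hn <- normalize_depth(het); on_ <- normalize_depth(hom)
      wins <- classify_windows(window_means(hn, window_bp, step_bp),
                               window_means(on_, window_bp, step_bp), th)
      regs <- call_regions(wins, kind, sdr_chrom, search, hn, on_, th,
                           refine_window_bp, refine_step_bp,
                           max_gap_bp = window_bp)
      list(windows = wins, regions = regs, het_norm = hn, hom_norm = on_)
    }
    list(shared = one("shared", "X_specific"),
         specific = one("specific", "Y_specific"))
  }, use_cache)
  for (hap in c("shared", "specific"))
    write_regions(depth[[hap]]$regions,
                  tsv_path = file.path(outdir, sprintf("regions_%s.tsv", hap)))

  gam <- stage_cached(outdir, "gametologs", c(cfg_key, codons = codons), function() {
    cds <- simulate_gametolog_cds(truth, config, codons = codons)
    pr <- pair_gametologs(cds$y_cds, cds$x_cds)
    xg <- truth$genes[truth$genes$haplotype == truth$hap_shared, ]
    div <- if (nrow(pr$pairs)) gametolog_divergence(pr$pairs, cds$y_cds, cds$x_cds,
                                                    x_genes = xg)
           else data.table()
    list(cds = cds, pairs = pr$pairs,
         divergence = div, summary = summarize_divergence(div))
  }, use_cache)
  if (nrow(gam$divergence))
    fwrite(gam$divergence, file.path(outdir, "gametolog_ds.tsv"), sep = "\t")

  cand <- stage_cached(outdir, "candidates", c(cfg_key, alpha = alpha,
                                               lfc_min = lfc_min), function() {
    expr <- simulate_expression_counts(truth, config)
    het_fl <- paste0(truth$het_sex, "_flower")
    hom_fl <- paste0(setdiff(c("M", "F"), truth$het_sex), "_flower")
    de1 <- de_summary(expr$counts, expr$design, c(het_fl, hom_fl))
    de2 <- de_summary(expr$counts, expr$design, c(het_fl, "nonreproductive"))
    regs <- depth$specific$regions
    yg <- truth$genes[truth$genes$haplotype == truth$hap_specific &
                      truth$genes$region == "SDR", ]
    inside <- vapply(seq_len(nrow(yg)), function(i)
      any(regs$seq == yg$seq[i] & regs$start <= yg$start[i] &
          regs$end >= yg$end[i]), logical(1))
    yspec <- classify_y_specificity(yg[inside, ], regs,
                                    depth$specific$hom_norm, gam$pairs,
                                    absent_max = th$absent_max)
    rows <- data.table(gene = yspec$gene_id,
                       y_specificity = yspec$y_specificity)
    rows[, `:=`(padj1 = de1$padj[match(gene, de1$gene)],
                log2FC1 = de1$log2FC[match(gene, de1$gene)],
                padj2 = de2$padj[match(gene, de2$gene)],
                log2FC2 = de2$log2FC[match(gene, de2$gene)])]
    list(de1 = de1, de2 = de2, y_specificity = yspec, rows = rows,
         cascade = filter_cascade(rows, alpha = alpha, lfc_min = lfc_min))
  }, use_cache)

  region_summary <- lapply(c("shared", "specific"), function(hap) {
    regs <- depth[[hap]]$regions
    if (!nrow(regs)) return(NULL)
    r <- regs[which.max(regs$end - regs$start)]
    ann <- annotate_regions(r, truth_genes_granges(
      truth, if (hap == "shared") "shared" else "specific"))
    list(haplotype = if (hap == "shared") truth$hap_shared else truth$hap_specific,
         kind = r$kind, seq = r$seq, start = r$start, end = r$end,
         span_bp = ann$span_bp, span_mb = ann$span_mb, n_genes = ann$n_genes)
  })
  names(region_summary) <- c("shared", "specific")

  report <- structure(list(
    verdict = assoc$system$verdict,
    n_significant = as.list(assoc$system$n_significant),
    peak = assoc$system$peak,
    regions = region_summary,
    gametologs = list(n_pairs = gam$summary$n_pairs,
                      n_retained = gam$summary$n_retained,
                      median_dS = gam$summary$median_dS),
    cascade = unclass(cand$cascade)[c("n_input", "n_y_specific", "n_stage1",
                                      "n_stage2", "n_final", "final_candidates")],
    provenance = list(seed = config$seed, config_hash = hash_object(cfg_key),
                      package_version = as.character(utils::packageVersion("sexscan")))
  ), class = "run_report")
  jsonlite::write_json(unclass(report), file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("sex-determination system verdict: %s\n", x$verdict))
  for (hap in names(x$regions)) {
    r <- x$regions[[hap]]
    if (is.null(r)) next
    cat(sprintf("  %s (%s): %s:%d-%d, %.1f Mb, %d genes\n", r$kind, r$haplotype,
                r$seq, as.integer(r$start), as.integer(r$end), r$span_mb, r$n_genes))
  }
  cat(sprintf("  gametologs retained: %d, median dS = %s\n",
              x$gametologs$n_retained, format(x$gametologs$median_dS, digits = 3)))
  cat(sprintf("  cascade: %d -> %d -> %d -> %d final (%s)\n",
              x$cascade$n_y_specific, x$cascade$n_stage1, x$cascade$n_stage2,
              x$cascade$n_final, paste(x$cascade$final_candidates, collapse = ", ")))
  invisible(x)
}
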