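#' Simulate an RNA-seq count matrix with planted candidate effects
#'
#' Generates negative-binomial counts for every gene on the sex-limited
#' haplotype assembly (autosomal background genes plus SDR genes, emulating
#' quantification against the heterogametic parent's reference). The design
#' covers male and female flowers at three early developmental stages
#' (S0, S1, S2) with `expression_replicates` biological replicates each, plus
#' a panel of non-reproductive organ samples. Library sizes vary uniformly by
#' +-30%. Genes listed in the truth's `candidate_effects` receive their
#' configured log2 fold-change in the configured contrasts:
#' * `contrast1` (male vs female flowers): effect applied to male flower
#'   samples only;
#' * `contrast2` (male flowers vs non-reproductive organs): implied by the
#'   male-sample effect; when only one contrast is flagged the complementary
#'   groups are co-scaled so the other contrast stays null.
#' A small fraction of genes is silent (zero counts everywhere).
#'
#' @param truth a [simulate_truth()] object.
#' @param config the matching [sim_config()].
#' @param n_nonreproductive number of non-reproductive organ samples.
#' @return list with `counts` (integer matrix, genes x samples), `design`
#'   (data.table: `sample`, `group`, `stage`, `sex`), `baseline` per-gene true
#'   means, and `effects` (the planted effect table).
#' @export
simulate_expression_counts <- function(truth, config, n_nonreproductive = 8L) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(derive_seed(config$seed, "expression"))
  g <- truth$genes
  genes <- g[g$haplotype %in% c("both", truth$hap_specific), ]$gene_id

  reps <- config$expression_replicates
  stages <- c("S0", "S1", "S2")
  design <- rbind(
    CJ(sex = c("M", "F"), stage = stages, rep = seq_len(reps))[
      , .(sample = sprintf("%s_%s_r%d", sex, stage, rep),
          group = paste0(sex, "_flower"), stage, sex)],
    data.table(sample = sprintf("NR_r%d", seq_len(n_nonreproductive)),
               group = "nonreproductive", stage = "NR", sex = "U"))

  n_g <- length(genes); n_s <- nrow(design)
  baseline <- exp(rnorm(n_g, mean = config$expression_mean_log, sd = 1))
  baseline[runif(n_g) < 0.05] <- 0  # silent genes
  names(baseline) <- genes

  mult <- matrix(1, n_g, n_s, dimnames = list(genes, design$sample))
  eff <- truth$candidate_effects
  if (is.data.frame(eff) && nrow(eff)) {
    for (i in seq_len(nrow(eff))) {
      gid <- eff$gene_id[i]
      if (!gid %in% genes) next
      if (baseline[gid] == 0) baseline[gid] <- exp(config$expression_mean_log)
      f <- 2^eff$log2fc[i]
      # planted effects upregulate the heterogametic sex's flowers (male
      # under XY, female under ZW)
      male_fl <- design$group == paste0(truth$het_sex, "_flower")
      female_fl <- design$group == paste0(setdiff(c("M", "F"), truth$het_sex),
                                          "_flower")
      nr <- design$group == "nonreproductive"
      if (isTRUE(eff$contrast1[i]) && isTRUE(eff$contrast2[i])) {
        mult[gid, male_fl] <- f
      } else if (isTRUE(eff$contrast1[i])) {
        mult[gid, male_fl] <- f; mult[gid, nr] <- f
      } else if (isTRUE(eff$contrast2[i])) {
        mult[gid, male_fl] <- f; mult[gid, female_fl] <- f
      }
    }
  }

  libsize <- runif(n_s, 0.7, 1.3)
  mu <- sweep(mult * baseline, 2, libsize, `*`)
  counts <- matrix(0L, n_g, n_s, dimnames = dimnames(mu))
  pos <- mu > 0
  counts[pos] <- rnbinom(sum(pos), size = 1 / config$expression_dispersion,
                         mu = mu[pos])
  list(counts = counts, design = design, baseline = baseline,
       effects = eff, libsize = libsize)
}

#' Write a count matrix as a genes x samples TSV
#' @param counts integer matrix with gene rownames and sample colnames.
#' @param path output TSV.
#' @return invisibly, `path`.
#' @export
write_counts_tsv <- function(counts, path) {
  dt <- data.table(gene = rownames(counts))
  dt <- cbind(dt, as.data.table(counts))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}
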