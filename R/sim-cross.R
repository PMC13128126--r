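#' Simulate pseudo-testcross genotypes for an F1 family
#'
#' Draws RAD-style SNP and presence/absence (PA) markers along every
#' chromosome and transmits them to the configured numbers of female, male and
#' non-flowering progeny by Mendelian segregation. Markers inside the SDR are
#' heterozygous in the heterogametic parent with the variant allele phased to
#' the sex-limited haplotype, and recombination is fully suppressed inside the
#' SDR in that parent, so SDR markers co-segregate perfectly with the
#' heterogametic sex. Outside the SDR each chromosome experiences one obligate
#' crossover per meiosis. Non-flowering progeny receive phenotype `"U"`.
#'
#' @param truth a [simulate_truth()] object.
#' @param config the [sim_config()] used to build `truth`.
#' @return list with `genotypes` (markers x individuals table; parent columns
#'   `P_F`, `P_M`), `phenotypes` (`id`, `sex` in F/M/U, `true_sex`),
#'   `marker_truth` (true category, phase and SDR membership per marker), and
#'   the parent column names.
#' @export
simulate_cross_genotypes <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"))
  n_prog <- config$n_female + config$n_male + config$n_nonflowering
  set.seed(derive_seed(config$seed, "cross"))

  chroms <- truth$chrom_sizes$seq
  L <- config$chromosome_length_bp
  sdr <- truth$sdr
  het_sex <- truth$het_sex

  # marker map
  mk <- rbindlist(lapply(chroms, function(ch) {
    pos <- seq(from = config$marker_spacing_bp / 2, to = L,
               by = config$marker_spacing_bp)
    data.table(seq = ch, pos = round(pos))
  }))
  mk[, in_sdr := seq == sdr$chrom & pos >= sdr$specific[1] & pos <= sdr$specific[2]]
  mk[, type := ifelse(runif(.N) < ifelse(in_sdr, config$pa_fraction_sdr,
                                         config$pa_fraction_autosomal), "PA", "SNP")]
  mk[, uninformative := !in_sdr & runif(.N) < config$uninformative_fraction]
  # which parent is heterozygous: SDR markers segregate from the heterogametic
  # parent; elsewhere either parent with equal probability
  mk[, het_parent := ifelse(in_sdr, het_sex, ifelse(runif(.N) < 0.5, "F", "M"))]
  mk[is.na(het_parent) | uninformative, het_parent := NA_character_]
  # phase: haplotype (1 = shared/X-like, 2 = sex-limited/Y-like on the sex
  # chromosome of the heterogametic parent) carrying the variant allele
  mk[, phase := ifelse(in_sdr, 2L, sample(1:2, .N, replace = TRUE))]
  mk[, marker_id := sprintf("mk_%s_%06d", sub("chr", "c", seq), pos %/% 1000)]

  if (n_prog == 0L) {
    warning("zero progeny requested: returning an empty genotype matrix")
    geno <- cbind(mk[, .(marker_id, seq, pos, type)],
                  P_F = parent_call(mk, "F"), P_M = parent_call(mk, "M"))
    return(list(genotypes = geno,
                phenotypes = data.table(id = character(), sex = character(),
                                        true_sex = character()),
                marker_truth = marker_truth_table(mk),
                female_parent = "P_F", male_parent = "P_M"))
  }

  true_sex <- c(rep("F", config$n_female), rep("M", config$n_male),
                sample(c("F", "M"), config$n_nonflowering, replace = TRUE))
  pheno <- c(rep("F", config$n_female), rep("M", config$n_male),
             rep("U", config$n_nonflowering))
  ids <- sprintf("F1_%03d", seq_len(n_prog))

  # gamete haplotype index per (parent, chromosome, progeny, marker)
  gamete_haps <- function(parent) {
    res <- matrix(NA_integer_, nrow = nrow(mk), ncol = n_prog)
    for (ch in chroms) {
      rows <- which(mk$seq == ch)
      pos <- mk$pos[rows]
      suppress <- ch == sdr$chrom && parent == het_sex
      u <- if (!suppress) runif(n_prog, 1, L) else {
        # one obligate crossover outside the SDR, uniform over the complement
        left <- sdr$specific[1] - 1; right <- L - sdr$specific[2]
        raw <- runif(n_prog, 0, left + right)
        ifelse(raw < left, 1 + raw, sdr$specific[2] + (raw - left))
      }
      ori <- sample(1:2, n_prog, replace = TRUE)  # haplotype before crossover
      if (ch == sdr$chrom && parent == het_sex) {
        # condition the transmitted sex haplotype on the progeny's true sex
        need <- ifelse(true_sex == het_sex, 2L, 1L)
        mid <- mean(sdr$specific)
        got <- ifelse(mid < u, ori, 3L - ori)
        ori <- ifelse(got == need, ori, 3L - ori)
      }
      before <- outer(pos, u, FUN = "<")    # markers before the crossover
      hap <- ifelse(before, rep(ori, each = length(rows)),
                    rep(3L - ori, each = length(rows)))
      res[rows, ] <- hap
    }
    res
  }
  hapF <- gamete_haps("F")
  hapM <- gamete_haps("M")

  # allele carried by a transmitted haplotype: 1 = variant (B / presence)
  variant_from <- function(hap, parent) {
    het <- !is.na(mk$het_parent) & mk$het_parent == parent
    both <- mk$uninformative
    out <- matrix(0L, nrow = nrow(mk), ncol = n_prog)
    out[het | both, ] <- (hap[het | both, , drop = FALSE] ==
                            mk$phase[het | both]) * 1L
    # uninformative markers are heterozygous in both parents
    out[both, ] <- (hap[both, , drop = FALSE] == mk$phase[both]) * 1L
    out
  }
  vF <- variant_from(hapF, "F")
  vM <- variant_from(hapM, "M")
  ndose <- vF + vM

  snp <- mk$type == "SNP"
  calls <- matrix(NA_character_, nrow = nrow(mk), ncol = n_prog)
  calls[snp, ] <- c("AA", "AB", "BB")[ndose[snp, , drop = FALSE] + 1L]
  calls[!snp, ] <- ifelse(ndose[!snp, , drop = FALSE] > 0L, "P", "A")
  colnames(calls) <- ids

  geno <- cbind(mk[, .(marker_id, seq, pos, type)],
                P_F = parent_call(mk, "F"), P_M = parent_call(mk, "M"),
                as.data.table(calls))
  list(genotypes = geno,
       phenotypes = data.table(id = ids, sex = pheno, true_sex = true_sex),
       marker_truth = marker_truth_table(mk),
       female_parent = "P_F", male_parent = "P_M")
}

parent_call <- function(mk, parent) {
  het <- !is.na(mk$het_parent) & mk$het_parent == parent
  out <- character(nrow(mk))
  out[mk$type == "SNP"] <- "AA"
  out[mk$type == "SNP" & (het | mk$uninformative)] <- "AB"
  out[mk$type == "PA"] <- "A"
  out[mk$type == "PA" & (het | mk$uninformative)] <- "P"
  out
}

marker_truth_table <- function(mk) {
  cat <- ifelse(mk$uninformative | is.na(mk$het_parent), "uninformative",
                paste0(ifelse(mk$het_parent == "F", "female_het_", "male_het_"),
                       mk$type))
  data.table(marker_id = mk$marker_id, seq = mk$seq, pos = mk$pos,
             type = mk$type, category = cat, phase = mk$phase,
             in_sdr = mk$in_sdr)
}

#' Write a genotype table in the package TSV dialect
#'
#' Two comment lines name the parent columns (`#female_parent=`,
#' `#male_parent=`), followed by a header and one row per marker with values
#' `AA/AB/BB/NA` (SNP rows) or `P/A/NA` (PA rows).
#'
#' @param cross result of [simulate_cross_genotypes()] (or a compatible list).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_genotypes_tsv <- function(cross, path) {
  con <- file(path, "w")
  writeLines(c(sprintf("#female_parent=%s", cross$female_parent),
               sprintf("#male_parent=%s", cross$male_parent)), con)
  close(con)
  fwrite(cross$genotypes, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a genotype table in the package TSV dialect
#'
#' @param path file written by [write_genotypes_tsv()] or hand-assembled in
#'   the same dialect.
#' @return list with `genotypes`, `female_parent`, `male_parent`.
#' @export
read_genotypes_tsv <- function(path) {
  hdr <- readLines(path, n = 10L)
  fp <- sub("^#female_parent=", "", grep("^#female_parent=", hdr, value = TRUE))
  mp <- sub("^#male_parent=", "", grep("^#male_parent=", hdr, value = TRUE))
  if (!length(fp) || !length(mp))
    stopf("genotype TSV must declare #female_parent= and #male_parent= headers")
  geno <- fread(path, skip = 2L, sep = "\t", na.strings = c("NA", ""))
  list(genotypes = geno, female_parent = fp[1], male_parent = mp[1])
}

#' Write the sample sheet (individual id and sex phenotype)
#' @param phenotypes data.frame with columns `id` and `sex` (F/M/U).
#' @param path output TSV.
#' @return invisibly, `path`.
#' @export
write_sample_sheet <- function(phenotypes, path) {
  fwrite(as.data.table(phenotypes)[, .(id, sex)], path, sep = "\t")
  invisible(path)
}
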