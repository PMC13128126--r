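#' Simulate the ground-truth genome architecture
#'
#' Lays out two haplotype assemblies (the shared sex chromosome copy, X or Z,
#' and the sex-limited copy, Y or W) with identical chromosome coordinates, an
#' SDR on the configured chromosome, gene models inside and outside the SDR,
#' gametolog pairs with per-pair target synonymous divergence, and
#' hemizygous-only genes. Under a ZW system the roles of the sexes are
#' swapped symmetrically (the female carries the hemizygous region).
#'
#' All placement is deterministic given the config, so two calls with the same
#' config produce identical truth tables and identical exported files.
#'
#' @param config a [sim_config()] object.
#' @return object of class `sim_truth`: a list with `system`, `het_sex`
#'   (heterogametic sex, `"M"` or `"F"`), haplotype labels, `sdr` coordinates
#'   per haplotype, `chrom_sizes`, and a `genes` table carrying per-gene
#'   sex-specificity, gametolog partner and true dS.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  hap_shared <- if (config$system == "XY") "X" else "Z"
  hap_specific <- if (config$system == "XY") "Y" else "W"
  het_sex <- if (config$system == "XY") "M" else "F"

  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  chrom_sizes <- data.table(seq = chroms,
                            length = rep(config$chromosome_length_bp, config$n_chromosomes))
  sdr_chrom <- chroms[config$sdr_chromosome]
  sdr <- list(chrom = sdr_chrom,
              shared = config$sdr_interval,
              specific = config$sdr_interval)

  glen <- config$gene_length_bp
  gene_tabs <- list()
  # background genes present on both haplotypes, skipping the SDR
  for (ch in chroms) {
    starts <- seq(from = config$gene_spacing_bp / 2,
                  to = config$chromosome_length_bp - glen,
                  by = config$gene_spacing_bp)
    if (ch == sdr_chrom) {
      inside <- starts + glen - 1 >= sdr$shared[1] & starts <= sdr$shared[2]
      starts <- starts[!inside]
    }
    if (!length(starts)) next
    gene_tabs[[length(gene_tabs) + 1L]] <- data.table(
      gene_id = sprintf("gene_%s_%03d", sub("^chr", "c", ch), seq_along(starts)),
      haplotype = "both", seq = ch, start = starts, end = starts + glen - 1,
      strand = rep_len(c("+", "-"), length(starts)),
      region = "autosomal", y_specificity = NA_character_,
      partner = NA_character_, true_dS = NA_real_)
  }

  place_in_sdr <- function(n) {
    if (n == 0L) return(numeric(0))
    span <- sdr$specific[2] - sdr$specific[1] + 1 - glen
    round(sdr$specific[1] + span * (seq_len(n) - 0.5) / n)
  }
  n_pairs <- length(config$target_dS_list)

  # sex-limited haplotype SDR genes: gametologs interleaved with
  # hemizygous-only ("Y_specific") genes along the interval
  n_spec <- config$n_y_specific_genes
  spec_types <- sample_free_interleave(n_pairs, n_spec)
  starts <- place_in_sdr(n_pairs + n_spec)
  pair_idx <- cumsum(spec_types == "XY_gametolog")
  spec_genes <- data.table(
    gene_id = sprintf("%sgene_%02d", tolower(hap_specific), seq_along(starts)),
    haplotype = hap_specific, seq = sdr_chrom, start = starts,
    end = starts + glen - 1, strand = rep_len(c("+", "-"), length(starts)),
    region = "SDR", y_specificity = spec_types,
    partner = NA_character_, true_dS = NA_real_)

  # shared-haplotype SDR genes: the gametolog partners plus X(Z)-specific genes
  n_xspec <- config$n_x_specific_genes
  shared_types <- sample_free_interleave(n_pairs, n_xspec)
  sh_starts <- place_in_sdr(n_pairs + n_xspec)
  shared_genes <- data.table(
    gene_id = sprintf("%sgene_%02d", tolower(hap_shared), seq_along(sh_starts)),
    haplotype = hap_shared, seq = sdr_chrom, start = sh_starts,
    end = sh_starts + glen - 1, strand = rep_len(c("+", "-"), length(sh_starts)),
    region = "SDR",
    y_specificity = ifelse(shared_types == "XY_gametolog", "XY_gametolog", "X_specific"),
    partner = NA_character_, true_dS = NA_real_)

  # link gametolog partners in pair order along each interval
  sg <- which(spec_genes$y_specificity == "XY_gametolog")
  xg <- which(shared_genes$y_specificity == "XY_gametolog")
  spec_genes$partner[sg] <- shared_genes$gene_id[xg]
  shared_genes$partner[xg] <- spec_genes$gene_id[sg]
  spec_genes$true_dS[sg] <- config$target_dS_list
  shared_genes$true_dS[xg] <- config$target_dS_list

  genes <- rbindlist(c(gene_tabs, list(spec_genes, shared_genes)))
  setkey(genes, seq, start)

  ce <- config$candidate_effects
  if (identical(ce, "auto")) {
    cand <- head(spec_genes$gene_id[spec_genes$y_specificity == "Y_specific"], 2L)
    ce <- data.frame(gene_id = cand, log2fc = 5,
                     contrast1 = TRUE, contrast2 = TRUE)
  }

  structure(list(system = config$system, het_sex = het_sex,
                 hap_shared = hap_shared, hap_specific = hap_specific,
                 chrom_sizes = chrom_sizes, sdr = sdr, genes = genes,
                 candidate_effects = ce, config = config),
            class = "sim_truth")
}

# deterministic interleaving of gametolog/specific gene types with exact
# counts: spreads the gametolog class evenly along the interval (no RNG, the
# truth layout is static given the config)
sample_free_interleave <- function(n_a, n_b) {
  n <- n_a + n_b
  if (n == 0L) return(character(0))
  out <- rep("Y_specific", n)
  if (n_a > 0L) {
    pos <- unique(pmin(n, pmax(1L, as.integer(ceiling(seq(0.5, n, length.out = n_a))))))
    short <- n_a - length(pos)
    if (short > 0L) pos <- c(pos, setdiff(seq_len(n), pos)[seq_len(short)])
    out[pos] <- "XY_gametolog"
  }
  out
}

#' Genes of a truth object as a GRanges
#' @param truth a `sim_truth` object.
#' @param haplotype `"shared"` or `"specific"` assembly.
#' @return `GRanges` of gene models on that haplotype assembly.
#' @export
truth_genes_granges <- function(truth, haplotype = c("specific", "shared")) {
  haplotype <- match.arg(haplotype)
  lab <- if (haplotype == "specific") truth$hap_specific else truth$hap_shared
  g <- truth$genes[truth$genes$haplotype %in% c("both", lab), ]
  gr <- GenomicRanges::GRanges(
    seqnames = g$seq,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand)
  gr$type <- "gene"
  gr$ID <- g$gene_id
  gr$source <- "sexscan_sim"
  names(gr) <- g$gene_id
  gr
}

#' Write truth reference tables to disk
#'
#' Emits the chromosome-sizes TSV, one GFF3 of gene models per haplotype
#' assembly, and the machine-readable truth JSON. Output is byte-identical
#' across runs with the same config.
#'
#' @param truth a `sim_truth` object.
#' @param outdir output directory (created if missing).
#' @return invisibly, the vector of written paths.
#' @export
write_truth_files <- function(truth, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sizes_path <- file.path(outdir, "chrom_sizes.tsv")
  fwrite(truth$chrom_sizes, sizes_path, sep = "\t")
  paths <- sizes_path
  for (hap in c("shared", "specific")) {
    lab <- if (hap == "specific") truth$hap_specific else truth$hap_shared
    p <- file.path(outdir, sprintf("genes_%s.gff3", lab))
    rtracklayer::export(truth_genes_granges(truth, hap), p, format = "gff3")
    paths <- c(paths, p)
  }
  tj <- file.path(outdir, "truth.json")
  jsonlite::write_json(list(system = truth$system, het_sex = truth$het_sex,
                            sdr = truth$sdr,
                            genes = truth$genes,
                            candidate_effects = truth$candidate_effects),
                       tj, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(paths, tj))
}
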