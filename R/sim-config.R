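#' Configuration for the synthetic sequencing study
#'
#' Builds the parameter set the generator modules share. Defaults reproduce
#' the design of the motivating cross: 186 F1 progeny (38 female, 89 male,
#' 59 non-flowering, so 127 flowering individuals enter the analysis), a
#' male-heterogametic (XY) system with a multi-megabase sex-determination
#' region (SDR) embedded mid-chromosome, ~30x short-read coverage with
#' negative-binomial noise, 22 gametolog pairs near the observed median
#' synonymous divergence, and two planted candidate genes with strong
#' male-flower-specific expression in both tested contrasts.
#'
#' @param n_chromosomes number of chromosomes per haplotype assembly.
#' @param chromosome_length_bp length of every chromosome (bp).
#' @param system `"XY"` (male heterogametic) or `"ZW"` (female heterogametic).
#' @param sdr_chromosome 1-based index of the sex chromosome.
#' @param sdr_interval length-2 integer vector, 1-based inclusive SDR bounds.
#' @param n_female,n_male,n_nonflowering progeny counts by phenotype class.
#' @param marker_spacing_bp spacing between simulated RAD markers.
#' @param read_depth_mean mean sequencing coverage (x) for depth tracks.
#' @param depth_dispersion negative-binomial dispersion alpha (var =
#'   mu + alpha mu^2); 0 gives Poisson noise.
#' @param target_dS_list per-gametolog-pair target synonymous divergence.
#' @param n_y_specific_genes,n_x_specific_genes counts of hemizygous-only
#'   genes planted inside the specific/shared SDR intervals.
#' @param gene_spacing_bp spacing of autosomal gene models.
#' @param gene_length_bp length of each gene model.
#' @param candidate_effects data.frame (`gene_id`, `log2fc`, `contrast1`,
#'   `contrast2`) of planted expression effects, or `"auto"` to flag the first
#'   two Y(W)-specific SDR genes with log2FC 5 in both contrasts.
#' @param expression_replicates biological replicates per stage x sex group.
#' @param expression_mean_log mean of the log-normal baseline expression.
#' @param expression_dispersion negative-binomial dispersion of counts.
#' @param pa_fraction_sdr fraction of SDR markers that are presence/absence
#'   (PA) type, emulating the repeat-driven PA enrichment seen in real SDRs.
#' @param pa_fraction_autosomal fraction of PA markers elsewhere.
#' @param uninformative_fraction fraction of markers heterozygous in both
#'   parents (not usable for the pseudo-testcross).
#' @param seed integer seed; the same config and seed give byte-identical
#'   generator output.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 3L,
                       chromosome_length_bp = 10e6,
                       system = c("XY", "ZW"),
                       sdr_chromosome = 2L,
                       sdr_interval = c(4000001L, 8000000L),
                       n_female = 38L,
                       n_male = 89L,
                       n_nonflowering = 59L,
                       marker_spacing_bp = 100000L,
                       read_depth_mean = 30,
                       depth_dispersion = 0.2,
                       target_dS_list = rep(0.02, 22L),
                       n_y_specific_genes = 34L,
                       n_x_specific_genes = 32L,
                       gene_spacing_bp = 150000L,
                       gene_length_bp = 3000L,
                       candidate_effects = "auto",
                       expression_replicates = 3L,
                       expression_mean_log = 4,
                       expression_dispersion = 0.1,
                       pa_fraction_sdr = 0.8,
                       pa_fraction_autosomal = 0.3,
                       uninformative_fraction = 0.1,
                       seed = 1L) {
  system <- match.arg(system)
  assert_scalar_num(n_chromosomes, "n_chromosomes", min = 1)
  assert_scalar_num(chromosome_length_bp, "chromosome_length_bp", min = 1)
  assert_scalar_num(sdr_chromosome, "sdr_chromosome", min = 1, max = n_chromosomes)
  if (length(sdr_interval) != 2L || any(is.na(sdr_interval)))
    stopf("'sdr_interval' must be two positions")
  sdr_interval <- as.numeric(sdr_interval)
  if (sdr_interval[1] < 1 || sdr_interval[2] > chromosome_length_bp ||
      sdr_interval[1] > sdr_interval[2])
    stopf("SDR interval [%s, %s] must lie within [1, %s]",
          sdr_interval[1], sdr_interval[2], chromosome_length_bp)
  for (nm in c("n_female", "n_male", "n_nonflowering"))
    assert_scalar_num(get(nm), nm, min = 0)
  assert_scalar_num(read_depth_mean, "read_depth_mean", min = 0)
  assert_scalar_num(depth_dispersion, "depth_dispersion", min = 0)
  if (any(target_dS_list < 0) || any(target_dS_list > 0.7))
    stopf("'target_dS_list' values must lie in [0, 0.7]")
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length_bp = as.numeric(chromosome_length_bp),
    system = system,
    sdr_chromosome = as.integer(sdr_chromosome),
    sdr_interval = sdr_interval,
    n_female = as.integer(n_female),
    n_male = as.integer(n_male),
    n_nonflowering = as.integer(n_nonflowering),
    marker_spacing_bp = as.numeric(marker_spacing_bp),
    read_depth_mean = read_depth_mean,
    depth_dispersion = depth_dispersion,
    target_dS_list = as.numeric(target_dS_list),
    n_y_specific_genes = as.integer(n_y_specific_genes),
    n_x_specific_genes = as.integer(n_x_specific_genes),
    gene_spacing_bp = as.numeric(gene_spacing_bp),
    gene_length_bp = as.numeric(gene_length_bp),
    candidate_effects = candidate_effects,
    expression_replicates = as.integer(expression_replicates),
    expression_mean_log = expression_mean_log,
    expression_dispersion = expression_dispersion,
    pa_fraction_sdr = pa_fraction_sdr,
    pa_fraction_autosomal = pa_fraction_autosomal,
    uninformative_fraction = uninformative_fraction,
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}
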