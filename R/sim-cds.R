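#' Simulate one gametolog CDS pair at a target synonymous divergence
#'
#' Starts from a random stop-free coding sequence and applies synonymous-only
#' single-nucleotide substitutions to one copy. The number of substitution
#' events is Poisson with mean `target_dS x S`, where `S` is the NG86
#' synonymous site count of the ancestral sequence, so `target_dS` is the true
#' expected number of synonymous substitutions per synonymous site (the
#' quantity the Jukes-Cantor-corrected estimator recovers). Each event picks
#' uniformly among all currently available synonymous single-base changes,
#' which reproduces the equal-rate substitution model underlying the JC
#' correction restricted to synonymous moves; multiple hits at one codon are
#' possible and are what the correction accounts for. Because every change is
#' synonymous, the realized dN is exactly zero and no internal stop codon can
#' arise; stop codons proposed while drawing the ancestral sequence are
#' rejected and resampled.
#'
#' @param target_dS target synonymous divergence (substitutions per
#'   synonymous site); must be attainable under the JC model
#'   (`p = 3/4 (1 - exp(-4 dS / 3)) < 3/4`, i.e. any finite `dS >= 0`), and
#'   is capped at 0.7 where the estimator is still well conditioned.
#' @param codons number of codons (>= 50).
#' @param seed integer seed.
#' @return list with `x` and `y` (character CDS strings), `n_events`
#'   (substitution events applied) and `S_true` (ancestral synonymous sites).
#' @export
simulate_cds_pair <- function(target_dS, codons, seed = 1L) {
  if (target_dS < 0) stopf("target_dS must be >= 0")
  if (target_dS > 0.7)
    stopf("target_dS %.3f exceeds the supported range (0.7); the JC-corrected estimator is unstable there", target_dS)
  if (codons < 50) stopf("at least 50 codons are required")
  tab <- codon_tables()
  set.seed(seed)

  # ancestral CDS: uniform draws over all codons, resampling stops
  anc <- character(codons)
  for (i in seq_len(codons)) {
    repeat {
      cd <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")
      if (tab$aa[cd] != "*") { anc[i] <- cd; break }
    }
  }
  S_true <- sum(tab$syn_sites[anc])

  derived <- anc
  n_events <- rpois(1L, target_dS * S_true)
  for (e in seq_len(n_events)) {
    w <- vapply(tab$syn_opts[derived], length, integer(1))
    i <- sample.int(codons, 1L, prob = w)
    opts <- tab$syn_opts[[derived[i]]]
    derived[i] <- opts[sample.int(length(opts), 1L)]
  }
  list(x = paste(anc, collapse = ""), y = paste(derived, collapse = ""),
       n_events = n_events, S_true = S_true)
}

#' Simulate CDS sets for all SDR genes of a truth object
#'
#' Gametolog pairs are generated at their per-pair true dS; hemizygous-only
#' genes (Y/W-specific and X/Z-specific) receive unrelated random CDS, so the
#' reciprocal-best-hit pairing stage sees realistic decoys.
#'
#' @param truth a [simulate_truth()] object.
#' @param config the matching [sim_config()].
#' @param codons CDS length in codons for every gene.
#' @return list with `y_cds` and `x_cds` ([Biostrings::DNAStringSet] named by
#'   gene id; `y_cds` holds the sex-limited haplotype's genes) and
#'   `pair_truth` (gene ids and true dS per pair).
#' @export
simulate_gametolog_cds <- function(truth, config, codons = 500L) {
  stopifnot(inherits(truth, "sim_truth"))
  g <- truth$genes
  ygenes <- g[g$haplotype == truth$hap_specific & g$region == "SDR", ]
  xgenes <- g[g$haplotype == truth$hap_shared & g$region == "SDR", ]

  y_seqs <- character(0); x_seqs <- character(0)
  pairs <- list()
  k <- 0L
  for (i in seq_len(nrow(ygenes))) {
    gid <- ygenes$gene_id[i]
    sd <- derive_seed(config$seed, paste0("cds_", gid))
    if (!is.na(ygenes$partner[i])) {
      k <- k + 1L
      pr <- simulate_cds_pair(ygenes$true_dS[i], codons, seed = sd)
      y_seqs[gid] <- pr$y
      x_seqs[ygenes$partner[i]] <- pr$x
      pairs[[k]] <- data.table(y_gene = gid, x_gene = ygenes$partner[i],
                               true_dS = ygenes$true_dS[i],
                               n_events = pr$n_events, S_true = pr$S_true)
    } else {
      y_seqs[gid] <- simulate_cds_pair(0, codons, seed = sd)$x
    }
  }
  solo_x <- xgenes[is.na(xgenes$partner), ]
  for (i in seq_len(nrow(solo_x))) {
    gid <- solo_x$gene_id[i]
    sd <- derive_seed(config$seed, paste0("cds_", gid))
    x_seqs[gid] <- simulate_cds_pair(0, codons, seed = sd)$x
  }
  list(y_cds = Biostrings::DNAStringSet(y_seqs),
       x_cds = Biostrings::DNAStringSet(x_seqs),
       pair_truth = if (k) rbindlist(pairs) else data.table())
}
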