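#' Simulate per-base read-depth tracks for one male and one female
#'
#' Depths are drawn per base from a negative binomial with mean
#' `coverage x copy-multiplier` and dispersion `alpha` (variance
#' `mu + alpha mu^2`; `alpha = 0` gives Poisson noise). The copy multiplier
#' encodes the expected mapping behaviour of short reads on each haplotype
#' assembly:
#' * shared haplotype (X/Z): both sexes diploid (1) outside the SDR; inside,
#'   the heterogametic sex is hemizygous (0.5), the homogametic sex stays 1;
#' * sex-limited haplotype (Y/W): outside the SDR both sexes map at 1; inside,
#'   the heterogametic sex is hemizygous (0.5) and the homogametic sex lacks
#'   the region entirely (0).
#'
#' @param truth a [simulate_truth()] object.
#' @param config the matching [sim_config()].
#' @param haplotype `"shared"` or `"specific"` assembly to simulate against.
#' @return object of class `depth_track_pair`: list with `male` and `female`,
#'   each a named list of integer depth vectors (one per chromosome), plus the
#'   haplotype label and chromosome sizes.
#' @export
simulate_depth_tracks <- function(truth, config, haplotype = c("specific", "shared")) {
  stopifnot(inherits(truth, "sim_truth"))
  haplotype <- match.arg(haplotype)
  if (config$read_depth_mean <= 0) stopf("coverage must be > 0")
  if (config$depth_dispersion < 0) stopf("depth dispersion must be >= 0")
  set.seed(derive_seed(config$seed, paste0("depth_", haplotype)))

  sdr <- truth$sdr
  interval <- if (haplotype == "specific") sdr$specific else sdr$shared
  het_sex <- truth$het_sex

  one_track <- function(sex) {
    lapply(seq_len(nrow(truth$chrom_sizes)), function(i) {
      ch <- truth$chrom_sizes$seq[i]
      n <- as.integer(truth$chrom_sizes$length[i])
      mult <- rep(1, n)
      if (ch == sdr$chrom) {
        idx <- interval[1]:interval[2]
        mult[idx] <- if (sex == het_sex) 0.5 else if (haplotype == "specific") 0 else 1
      }
      draw_depth(mult * config$read_depth_mean, config$depth_dispersion)
    }) |> setNames(truth$chrom_sizes$seq)
  }
  structure(list(male = one_track("M"), female = one_track("F"),
                 haplotype = haplotype,
                 chrom_sizes = truth$chrom_sizes),
            class = "depth_track_pair")
}

# NB draw with mean mu (vector) and dispersion alpha; exact zeros stay zero
draw_depth <- function(mu, alpha) {
  out <- integer(length(mu))
  pos <- mu > 0
  if (any(pos)) {
    out[pos] <- if (alpha == 0) rpois(sum(pos), mu[pos])
                else rnbinom(sum(pos), size = 1 / alpha, mu = mu[pos])
  }
  out
}

#' Write a per-base depth track as a three-column TSV
#'
#' Columns: sequence name, 1-based position, depth. Zero-depth positions are
#' written too, so the file is dense over the assembly.
#'
#' @param track named list of per-chromosome integer depth vectors.
#' @param path output TSV (no header, matching `samtools depth -a` layout).
#' @return invisibly, `path`.
#' @export
write_depth_tsv <- function(track, path) {
  dt <- rbindlist(lapply(names(track), function(ch) {
    data.table(seq = ch, pos = seq_along(track[[ch]]), depth = track[[ch]])
  }))
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a three-column per-base depth TSV into per-chromosome vectors
#'
#' Positions absent from the file are treated as uncovered (depth 0).
#'
#' @param path three-column TSV (sequence, 1-based position, depth).
#' @param chrom_sizes data.frame with columns `seq`, `length`; defines the
#'   dense coordinate space.
#' @return named list of integer depth vectors.
#' @export
read_depth_tsv <- function(path, chrom_sizes) {
  dt <- fread(path, sep = "\t", header = FALSE,
              col.names = c("seq", "pos", "depth"))
  cs <- as.data.table(chrom_sizes)
  out <- lapply(seq_len(nrow(cs)), function(i) {
    v <- integer(as.integer(cs$length[i]))
    sub <- dt[seq == cs$seq[i]]
    if (nrow(sub)) v[sub$pos] <- sub$depth
    v
  })
  setNames(out, cs$seq)
}
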