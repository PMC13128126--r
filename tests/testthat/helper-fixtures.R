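# Small study configuration used across tests: 2 x 1 Mb chromosomes with a
# 400 kb SDR mid-chromosome-2, full-size progeny panel, 30x coverage.
small_config <- function(seed = 7, ...) {
  args <- list(n_chromosomes = 2, chromosome_length_bp = 1e6,
               sdr_interval = c(400001, 800000), marker_spacing_bp = 20000,
               target_dS_list = rep(0.02, 4), n_y_specific_genes = 6,
               n_x_specific_genes = 5, gene_spacing_bp = 50000,
               gene_length_bp = 2000, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# independent brute-force two-sided Fisher p for a 2x2 table: exact
# hypergeometric enumeration with binomial coefficients
fisher_oracle <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    choose(m, x) * choose(n, k - x) / choose(m + n, k), numeric(1))
  obs <- probs[a - lo + 1]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# independent BH step-up: q_(i) = min_{j >= i} p_(j) m / j, original order
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(sort(p) * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# independent NG86 difference counting: recursive depth-first enumeration of
# every mutational pathway between two codons, equal weights
ng86_path_oracle <- function(a, b) {
  gc <- Biostrings::GENETIC_CODE
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  pos <- which(av != bv)
  if (!length(pos)) return(c(Sd = 0, Nd = 0))
  paths <- list()
  recurse <- function(cur, remaining, sd_, nd_) {
    if (!length(remaining)) {
      paths[[length(paths) + 1L]] <<- c(sd_, nd_)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur; nxt[p] <- bv[p]
      syn <- gc[paste(cur, collapse = "")] == gc[paste(nxt, collapse = "")]
      recurse(nxt, setdiff(remaining, p), sd_ + syn, nd_ + !syn)
    }
  }
  recurse(av, pos, 0, 0)
  m <- do.call(rbind, paths)
  c(Sd = mean(m[, 1]), Nd = mean(m[, 2]))
}

# independent NG86 site counting for one codon: fraction of the 9 possible
# single-base changes that preserve the amino acid (stops nonsynonymous)
ng86_sites_oracle <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  s <- strsplit(codon, "")[[1]]
  syn <- 0
  for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"), s[p])) {
    t <- s; t[p] <- b
    alt <- paste(t, collapse = "")
    if (gc[alt] == gc[codon] && gc[codon] != "*") syn <- syn + 1
  }
  syn / 3
}

random_sense_codons <- function(n, seed) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  set.seed(seed)
  sample(sense, n, replace = TRUE)
}
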