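#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computes the exact two-sided p-value by the point-probability rule: the sum
#' of hypergeometric probabilities, over all tables with the observed margins,
#' whose point probability does not exceed that of the observed table (a
#' relative tolerance of 1e-7 guards ties against floating-point error).
#' Probabilities are evaluated in log space via the hypergeometric density, so
#' large margins are handled without underflow. A table with any zero margin
#' carries no information and returns p = 1 by convention.
#'
#' @param tab 2x2 matrix (or length-4 vector, column-major) of non-negative
#'   counts.
#' @return the two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  x <- as.numeric(tab)
  if (length(x) != 4L || any(is.na(x)) || any(x < 0))
    stopf("'tab' must be four non-negative counts")
  a <- x[1]; c_ <- x[2]; b <- x[3]; d <- x[4]
  m <- a + b          # row-1 total
  n <- c_ + d         # row-2 total
  k <- a + c_         # column-1 total
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  logp <- dhyper(support, m, n, k, log = TRUE)
  obs <- dhyper(a, m, n, k, log = TRUE)
  p <- sum(exp(logp[logp <= obs + 1e-7]))
  min(1, p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, order-preserving wrapper over the standard BH step-up procedure:
#' `q_(i) = min_{j >= i} p_(j) m / j`, clipped at 1.
#'
#' @param pvals vector of p-values in `[0, 1]` (NA passed through).
#' @return adjusted q-values in the original order.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Per-marker Fisher's exact sex-association scan
#'
#' Builds one 2x2 table per informative marker (allele/presence carrier vs
#' non-carrier, female vs male) over flowering progeny, tests it with
#' [fisher_exact_2x2()], and applies BH-FDR. Non-flowering individuals
#' (phenotype `"U"`) and missing genotypes are dropped per marker. Carriers
#' are progeny bearing the heterozygous parent's variant allele (`AB` for SNP
#' markers, `P` for PA markers). The adjustment is applied separately within
#' the female-parent-heterozygous and male-parent-heterozygous marker sets
#' (mirroring per-panel Manhattan thresholds) unless `fdr_scope = "global"`.
#'
#' @param classes marker classification ([classify_markers()] output).
#' @param genotypes genotype table including progeny columns.
#' @param phenotypes data.frame with `id` and `sex` (`F`/`M`/`U`).
#' @param female_parent,male_parent parent column names (excluded from the
#'   scan).
#' @param fdr false discovery rate threshold (default 0.05).
#' @param fdr_scope `"category"` (separate BH per marker category) or
#'   `"global"`.
#' @param pool_types pool SNP and PA markers within a category before BH
#'   (default TRUE); FALSE adjusts SNP and PA sets separately.
#' @param balanced subsample the majority sex down to the minority count
#'   (without replacement) before testing.
#' @param seed seed for the balanced subsample.
#' @return data.table: marker id/seq/pos/category, the 2x2 cells (`a` =
#'   carrier-female, `b` = carrier-male, `c` = noncarrier-female, `d` =
#'   noncarrier-male), `p`, `q`, `neglog10q`, `significant`, `all_missing`.
#' @export
association_scan <- function(classes, genotypes, phenotypes,
                             female_parent, male_parent,
                             fdr = 0.05,
                             fdr_scope = c("category", "global"),
                             pool_types = TRUE,
                             balanced = FALSE, seed = 1L) {
  fdr_scope <- match.arg(fdr_scope)
  cls <- as.data.table(classes)
  g <- as.data.table(genotypes)
  ph <- as.data.table(phenotypes)
  flowering <- ph[sex %in% c("F", "M")]
  if (nrow(flowering[sex == "F"]) < 1 || nrow(flowering[sex == "M"]) < 1)
    stopf("need at least one flowering female and one flowering male")
  if (balanced) {
    set.seed(seed)
    n_min <- min(table(flowering$sex))
    flowering <- flowering[, .SD[sample(.N, n_min)], by = sex]
  }
  ids <- intersect(flowering$id, names(g))
  sex <- setNames(flowering$sex, flowering$id)[ids]

  informative <- cls[!is.na(category) & category != "uninformative"]
  gm <- as.matrix(g[match(informative$marker_id, g$marker_id), ..ids])
  carrier <- matrix(NA, nrow(gm), ncol(gm))
  carrier[gm == "AB" | gm == "P"] <- TRUE
  carrier[gm == "AA" | gm == "BB" | gm == "A"] <- FALSE

  isF <- sex == "F"
  a <- rowSums(carrier & rep(isF, each = nrow(carrier)), na.rm = TRUE)
  b <- rowSums(carrier & rep(!isF, each = nrow(carrier)), na.rm = TRUE)
  c_ <- rowSums((!carrier) & rep(isF, each = nrow(carrier)), na.rm = TRUE)
  d <- rowSums((!carrier) & rep(!isF, each = nrow(carrier)), na.rm = TRUE)

  res <- cbind(informative, data.table(a = a, b = b, c = c_, d = d))
  res[, all_missing := (a + b + c + d) == 0]
  res[, p := vapply(seq_len(.N), function(i)
    if (all_missing[i]) 1 else fisher_exact_2x2(c(a[i], b[i], c[i], d[i])),
    numeric(1))]
  res[, parent_side := fifelse(grepl("^female_het", category), "female_het", "male_het")]
  res[, adj_group := if (fdr_scope == "global") "all"
                     else if (pool_types) parent_side else category]
  res[, q := bh_adjust(p), by = adj_group]
  res[, adj_group := NULL]
  res[, neglog10q := -log10(q)]
  res[, significant := !all_missing & q < fdr]
  res[, parent_side := NULL]
  res[]
}

#' Call the heterogametic sex-determination system from scan results
#'
#' Significant male-parent-heterozygous markers with no significant
#' female-parent-heterozygous markers indicate XY (male heterogametic);
#' the mirror image indicates ZW; both significant is ambiguous; neither
#' gives no call. The peak interval is the span of significant markers on the
#' modal chromosome of the winning category.
#'
#' @param results [association_scan()] output.
#' @param fdr threshold used for `significant` (informational).
#' @return list with `verdict` (`XY`/`ZW`/`ambiguous`/`none`), per-category
#'   significant counts, and `peak` (chromosome, start, end) or NULL.
#' @export
classify_sex_system <- function(results, fdr = 0.05) {
  res <- copy(as.data.table(results))
  res[, side := fifelse(grepl("^female_het", category), "female_het", "male_het")]
  n_sig <- res[, .(n = sum(significant)), by = side]
  nm <- sum(n_sig[side == "male_het"]$n)
  nf <- sum(n_sig[side == "female_het"]$n)
  verdict <- if (nm > 0 && nf == 0) "XY"
             else if (nf > 0 && nm == 0) "ZW"
             else if (nm > 0 && nf > 0) "ambiguous" else "none"
  peak <- NULL
  if (verdict %in% c("XY", "ZW")) {
    side_want <- if (verdict == "XY") "male_het" else "female_het"
    sig <- res[significant & side == side_want]
    modal <- names(sort(table(sig$seq), decreasing = TRUE))[1]
    sig <- sig[seq == modal]
    peak <- list(chrom = modal, start = min(sig$pos), end = max(sig$pos))
  }
  list(verdict = verdict,
       n_significant = setNames(c(nf, nm), c("female_het", "male_het")),
       fdr = fdr, peak = peak)
}
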