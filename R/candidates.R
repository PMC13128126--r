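#' Classify Y(W)-region genes as sex-specific or gametologous
#'
#' A gene inside a called sex-limited region is an `XY_gametolog` when it has
#' a reciprocal-best partner on the shared haplotype; otherwise it is
#' `Y_specific` when the homogametic sex's mean normalized depth over the
#' gene body is below `absent_max` (no reads from the homogametic sex, the
#' hemizygosity signature); genes failing both rules are `unresolved`.
#'
#' @param genes data.frame of Y-region genes (`gene_id`, `seq`, `start`,
#'   `end`).
#' @param regions called regions table (`seq`, `start`, `end`); every gene
#'   must fall inside one.
#' @param female_norm normalized per-base depth track of the homogametic sex
#'   over the sex-limited haplotype assembly.
#' @param pairs gametolog pairing table (`y_gene`, `x_gene`).
#' @param absent_max depth bound for "absent" (default 0.15).
#' @return data.table: `gene_id`, `female_gene_depth`, `y_specificity`.
#' @export
classify_y_specificity <- function(genes, regions, female_norm, pairs,
                                   absent_max = 0.15) {
  g <- as.data.table(genes)
  r <- as.data.table(regions)
  inside <- vapply(seq_len(nrow(g)), function(i)
    any(r$seq == g$seq[i] & r$start <= g$start[i] & r$end >= g$end[i]),
    logical(1))
  if (!all(inside))
    stopf("gene(s) outside any called region: %s",
          paste(g$gene_id[!inside], collapse = ", "))
  depth <- vapply(seq_len(nrow(g)), function(i) {
    v <- female_norm[[g$seq[i]]]
    mean(v[g$start[i]:g$end[i]])
  }, numeric(1))
  paired <- g$gene_id %in% pairs$y_gene
  spec <- ifelse(paired, "XY_gametolog",
                 ifelse(depth < absent_max, "Y_specific", "unresolved"))
  data.table(gene_id = g$gene_id, female_gene_depth = depth,
             y_specificity = spec)
}

#' Differential-expression summary for one contrast
#'
#' A compact negative-binomial differential-expression test: size factors by
#' median-of-ratios over genes with all-positive counts; `baseMean` is the
#' mean of normalized counts over the contrast's samples; `log2FC` the log2
#' ratio of group means with a +0.5 pseudo-count (kept finite, no shrinkage);
#' the p-value is a Wald test of the log ratio with a per-gene
#' method-of-moments negative-binomial dispersion (floored at 0.01),
#' referenced against a t distribution with `nA + nB - 2` degrees of freedom;
#' BH adjustment within the contrast. Genes with `baseMean < 1` are not
#' tested (`padj` missing).
#'
#' @param counts integer matrix, genes x samples.
#' @param design data.frame with `sample` and `group` columns.
#' @param contrast length-2 character: groups A and B (log2FC is A over B).
#' @return data.table: `gene`, `baseMean`, `log2FC`, `p`, `padj`.
#' @export
de_summary <- function(counts, design, contrast) {
  d <- as.data.table(design)
  if (length(contrast) != 2L || !all(contrast %in% d$group))
    stopf("contrast groups not found in design")
  sa <- d$sample[d$group == contrast[1]]
  sb <- d$sample[d$group == contrast[2]]
  if (length(sa) < 2L || length(sb) < 2L)
    stopf("each contrast group needs >= 2 samples")
  counts <- as.matrix(counts)
  if (any(colSums(counts[, c(sa, sb), drop = FALSE]) == 0))
    stopf("a library in the contrast has all-zero counts")

  # median-of-ratios size factors over all samples in the matrix
  allpos <- rowSums(counts == 0) == 0
  if (!any(allpos)) stopf("no gene with all-positive counts: cannot estimate size factors")
  logg <- rowMeans(log(counts[allpos, , drop = FALSE]))
  sf <- apply(counts[allpos, , drop = FALSE], 2, function(cj)
    exp(median(log(cj) - logg)))
  norm <- sweep(counts, 2, sf, `/`)

  na_ <- length(sa); nb_ <- length(sb)
  A <- norm[, sa, drop = FALSE]; B <- norm[, sb, drop = FALSE]
  mA <- rowMeans(A); mB <- rowMeans(B)
  baseMean <- rowMeans(norm[, c(sa, sb), drop = FALSE])
  log2FC <- log2((mA + 0.5) / (mB + 0.5))

  vA <- apply(A, 1, var); vB <- apply(B, 1, var)
  # pooled method-of-moments NB dispersion, floored
  alpha <- pmax(0.01, ((vA - mA) / pmax(mA, 1e-8)^2 * (na_ - 1) +
                       (vB - mB) / pmax(mB, 1e-8)^2 * (nb_ - 1)) / (na_ + nb_ - 2))
  varA <- (mA + alpha * mA^2) / na_
  varB <- (mB + alpha * mB^2) / nb_
  se <- sqrt(varA / (mA + 0.5)^2 + varB / (mB + 0.5)^2) / log(2)
  z <- log2FC / pmax(se, 1e-12)
  p <- 2 * pt(-abs(z), df = na_ + nb_ - 2)
  testable <- baseMean >= 1
  padj <- rep(NA_real_, length(p))
  padj[testable] <- bh_adjust(p[testable])
  data.table(gene = rownames(counts), baseMean = baseMean, log2FC = log2FC,
             p = ifelse(testable, p, NA_real_), padj = padj)
}

#' Three-stage candidate filter cascade
#'
#' Starting from the sex-limited (Y/W-specific) genes of a two-contrast
#' differential-expression table:
#' * stage 1: adjusted p of contrast 1 (male vs female flowers) `< alpha`;
#' * stage 2: stage 1 and contrast-1 `log2FC > lfc_min` (upregulated in male
#'   flowers);
#' * stage 3 (final): stage 2 and contrast 2 (male flowers vs non-reproductive
#'   organs) significant with `log2FC > lfc_min`.
#' Missing adjusted p-values (untested low-count genes) never pass. Stage 1
#' deliberately applies no sign constraint (it is a significance screen; the
#' direction is enforced by the fold-change stages).
#'
#' @param rows data.frame with `gene`, `y_specificity`, `padj1`, `log2FC1`,
#'   `padj2`, `log2FC2`.
#' @param alpha significance threshold (default 0.05).
#' @param lfc_min log2 fold-change threshold (default 2).
#' @return list of class `cascade_report`: input/stage counts and the final
#'   candidate gene ids.
#' @export
filter_cascade <- function(rows, alpha = 0.05, lfc_min = 2.0) {
  dt <- as.data.table(rows)
  need <- c("gene", "y_specificity", "padj1", "log2FC1", "padj2", "log2FC2")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(dt$gene)) stopf("duplicated gene ids in cascade input")
  yspec <- dt[y_specificity == "Y_specific"]
  s1 <- yspec[!is.na(padj1) & padj1 < alpha]
  s2 <- s1[log2FC1 > lfc_min]
  s3 <- s2[!is.na(padj2) & padj2 < alpha & log2FC2 > lfc_min]
  structure(list(n_input = nrow(dt), n_y_specific = nrow(yspec),
                 n_stage1 = nrow(s1), n_stage2 = nrow(s2),
                 n_final = nrow(s3),
                 stage1_genes = s1$gene, stage2_genes = s2$gene,
                 final_candidates = s3$gene,
                 alpha = alpha, lfc_min = lfc_min),
            class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat(sprintf(
    "candidate filter cascade: %d genes (%d sex-limited) -> %d (padj1 < %g) -> %d (log2FC1 > %g) -> %d final\n",
    x$n_input, x$n_y_specific, x$n_stage1, x$alpha, x$n_stage2, x$lfc_min, x$n_final))
  if (length(x$final_candidates))
    cat("final candidates:", paste(x$final_candidates, collapse = ", "), "\n")
  invisible(x)
}

#' Read a two-contrast differential-expression table
#'
#' Expects the columns `gene`, `y_specificity`, `baseMean1`, `padj1`,
#' `log2FC1`, `baseMean2`, `padj2`, `log2FC2` (the layout of the shipped
#' Y-region example table).
#'
#' @param path TSV path.
#' @return data.table in cascade-ready form.
#' @export
read_de_table <- function(path) {
  dt <- fread(path, sep = "\t", na.strings = c("NA", ""))
  need <- c("gene", "y_specificity", "baseMean1", "padj1", "log2FC1",
            "baseMean2", "padj2", "log2FC2")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stopf("DE table lacks columns: %s", paste(miss, collapse = ", "))
  dt
}
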