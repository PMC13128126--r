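#' Classify SNP markers into pseudo-testcross categories
#'
#' A marker is usable for the pseudo-testcross when it is heterozygous in
#' exactly one parent and homozygous in the other: `AB x AA` (female parent
#' het) gives `female_het_SNP`, `AA x AB` gives `male_het_SNP`. Markers
#' heterozygous in both parents, identically homozygous, or fixed-different
#' (`AA x BB`, which does not segregate) are `uninformative`. Rows where
#' either parent call is missing are skipped and counted.
#'
#' @param genotypes genotype table (columns `marker_id`, `seq`, `pos`,
#'   optionally `type`, then one column per individual with `AA/AB/BB/NA`).
#' @param female_parent,male_parent names of the two parent columns.
#' @return data.table: `marker_id`, `seq`, `pos`, `category`, `skipped`
#'   (missing-parent rows), with attribute `n_skipped`.
#' @export
classify_snp_markers <- function(genotypes, female_parent, male_parent) {
  g <- as.data.table(genotypes)
  check_parents(g, female_parent, male_parent)
  fp <- g[[female_parent]]; mp <- g[[male_parent]]
  is_snp <- fp %in% c("AA", "AB", "BB") | mp %in% c("AA", "AB", "BB")
  skipped <- is.na(fp) | is.na(mp)
  hetf <- !skipped & fp == "AB" & mp %in% c("AA", "BB")
  hetm <- !skipped & mp == "AB" & fp %in% c("AA", "BB")
  category <- rep("uninformative", nrow(g))
  category[hetf] <- "female_het_SNP"
  category[hetm] <- "male_het_SNP"
  category[skipped] <- NA_character_
  out <- data.table(marker_id = g$marker_id, seq = g$seq, pos = g$pos,
                    category = category, skipped = skipped)
  out <- out[is_snp | skipped]
  n_skip <- sum(out$skipped)
  if (n_skip > 0)
    message(sprintf("classify_snp_markers: skipped %d rows with a missing parent call", n_skip))
  setattr(out, "n_skipped", n_skip)
  out[]
}

#' Call presence/absence markers from per-locus read counts
#'
#' A locus state is `present` at `count >= min_present` reads, `absent` at 0
#' reads, and `missing` in between (too few reads to call either way). A
#' locus is a PA marker when one parent is present and the other absent; its
#' category follows the parent carrying the presence allele (which segregates
#' ~1:1 among progeny under the pseudo-testcross). Loci that are missing in
#' every individual are dropped.
#'
#' @param read_counts data.frame/matrix-like with `marker_id`, `seq`, `pos`
#'   then one integer read-count column per individual.
#' @param female_parent,male_parent parent column names.
#' @param min_present minimum reads to call presence (default 3).
#' @return list with `states` (same layout, values `P/A/NA`) and `classes`
#'   (`marker_id`, `seq`, `pos`, `category`).
#' @export
call_pa_markers <- function(read_counts, female_parent, male_parent,
                            min_present = 3L) {
  rc <- as.data.table(read_counts)
  check_parents(rc, female_parent, male_parent)
  meta <- intersect(c("marker_id", "seq", "pos"), names(rc))
  ind <- setdiff(names(rc), meta)
  cnt <- as.matrix(rc[, ..ind])
  if (any(cnt < 0, na.rm = TRUE)) stopf("read counts must be >= 0")
  st <- matrix(NA_character_, nrow(cnt), ncol(cnt), dimnames = dimnames(cnt))
  st[cnt >= min_present] <- "P"
  st[cnt == 0] <- "A"
  keep <- rowSums(!is.na(st)) > 0
  states <- cbind(rc[, ..meta], as.data.table(st))[keep]
  fp <- st[keep, female_parent]; mp <- st[keep, male_parent]
  category <- rep("uninformative", sum(keep))
  category[!is.na(fp) & !is.na(mp) & fp == "P" & mp == "A"] <- "female_het_PA"
  category[!is.na(fp) & !is.na(mp) & fp == "A" & mp == "P"] <- "male_het_PA"
  category[is.na(fp) | is.na(mp)] <- NA_character_
  classes <- cbind(rc[keep, ..meta], data.table(category = category))
  list(states = states, classes = classes)
}

#' Test marker segregation against the expected 1:1 ratio
#'
#' Chi-squared goodness of fit of carrier vs non-carrier counts among
#' non-missing flowering progeny against 1:1. Markers fail at `p < alpha`;
#' markers with fewer than 20 informative progeny are flagged `low_n` rather
#' than failed (the test is unreliable there).
#'
#' @param counts data.frame with columns `marker_id`, `n_carrier`,
#'   `n_noncarrier`.
#' @param alpha significance level for the distortion filter (default 0.01).
#' @return data.table adding `chisq`, `p`, `pass`, `low_n`.
#' @export
filter_segregation <- function(counts, alpha = 0.01) {
  ct <- as.data.table(counts)
  n <- ct$n_carrier + ct$n_noncarrier
  chisq <- ifelse(n > 0, (ct$n_carrier - ct$n_noncarrier)^2 / n, NA_real_)
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  low_n <- n < 20
  ct[, `:=`(chisq = chisq, p = p,
            pass = low_n | (!is.na(p) & p >= alpha), low_n = low_n)]
  ct[]
}

#' Classify every marker row of a combined SNP + PA genotype table
#'
#' Dispatches SNP-coded rows (`AA/AB/BB`) to [classify_snp_markers()] and
#' presence-coded rows (`P/A`) to the PA parent rule, returning one category
#' per marker.
#'
#' @inheritParams classify_snp_markers
#' @return data.table: `marker_id`, `seq`, `pos`, `type`, `category`.
#' @export
classify_markers <- function(genotypes, female_parent, male_parent) {
  g <- as.data.table(genotypes)
  check_parents(g, female_parent, male_parent)
  fp <- g[[female_parent]]; mp <- g[[male_parent]]
  pa_row <- fp %in% c("P", "A") | mp %in% c("P", "A")
  category <- rep(NA_character_, nrow(g))
  snp <- !pa_row & !is.na(fp) & !is.na(mp)
  category[snp & fp == "AB" & mp %in% c("AA", "BB")] <- "female_het_SNP"
  category[snp & mp == "AB" & fp %in% c("AA", "BB")] <- "male_het_SNP"
  category[snp & is.na(category)] <- "uninformative"
  pa <- pa_row & !is.na(fp) & !is.na(mp)
  category[pa & fp == "P" & mp == "A"] <- "female_het_PA"
  category[pa & fp == "A" & mp == "P"] <- "male_het_PA"
  category[pa & is.na(category)] <- "uninformative"
  data.table(marker_id = g$marker_id, seq = g$seq, pos = g$pos,
             type = ifelse(pa_row, "PA", "SNP"), category = category)
}

check_parents <- function(dt, female_parent, male_parent) {
  missing_cols <- setdiff(c(female_parent, male_parent), names(dt))
  if (length(missing_cols))
    stopf("parent column(s) not found: %s", paste(missing_cols, collapse = ", "))
  if (female_parent == male_parent)
    stopf("female and male parent columns must differ")
  invisible(TRUE)
}

#' Read biallelic genotypes from a VCF into the package genotype dialect
#'
#' Uses the GT field; biallelic SNP records become `AA/AB/BB` calls.
#' Multiallelic records are skipped with a warning (the pseudo-testcross
#' requires biallelic configurations).
#'
#' @param path VCF file (plain or bgzipped).
#' @param female_parent,male_parent sample names of the two parents.
#' @return list with `genotypes`, `female_parent`, `male_parent`.
#' @export
read_genotypes_vcf <- function(path, female_parent, male_parent) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warning(sprintf("skipping %d multiallelic VCF records", sum(multi)))
  }
  gt <- vcfR::extract.gt(v)
  code <- function(x) {
    x <- sub("\\|", "/", x)
    out <- rep(NA_character_, length(x))
    out[x %in% c("0/0")] <- "AA"
    out[x %in% c("0/1", "1/0")] <- "AB"
    out[x %in% c("1/1")] <- "BB"
    out
  }
  calls <- apply(gt, 2, code)
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = nrow(gt),
                                           dimnames = dimnames(gt))
  geno <- data.table(marker_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                        sprintf("%s_%s", fix$CHROM, fix$POS), fix$ID),
                     seq = fix$CHROM, pos = as.integer(fix$POS))
  geno <- cbind(geno, as.data.table(calls))[!multi]
  check_parents(geno, female_parent, male_parent)
  list(genotypes = geno, female_parent = female_parent, male_parent = male_parent)
}
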