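#' Pair candidate gametologs by reciprocal best protein hit
#'
#' Translates both CDS sets, aligns all pairs at the protein level (local
#' alignment, BLOSUM62, affine gaps) and keeps, per query, up to
#' `max_targets` hits meeting the identity/length criteria; a pair is a
#' gametolog candidate when the two genes are each other's best hit.
#' Sequences with an internal stop codon are excluded (and reported in the
#' `excluded` element). The identity-over-aligned-length criterion replaces a
#' database E-value model.
#'
#' @param y_cds,x_cds [Biostrings::DNAStringSet] of coding sequences from the
#'   sex-limited and shared haplotype regions.
#' @param min_identity minimum percent identity over the aligned residues
#'   (default 60).
#' @param min_aln_length minimum aligned residues (default 100).
#' @param max_targets best hits retained per query (default 2).
#' @return list with `pairs` (data.table `y_gene`, `x_gene`, `score`,
#'   `identity`, `aln_length`) and `excluded` (untranslatable ids).
#' @export
pair_gametologs <- function(y_cds, x_cds, min_identity = 60,
                            min_aln_length = 100, max_targets = 2L) {
  tr <- function(ss) {
    prot <- list(); bad <- character(0)
    for (nm in names(ss)) {
      s <- as.character(ss[[nm]])
      s <- substr(s, 1, 3 * (nchar(s) %/% 3))
      aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
      aa <- sub("\\*$", "", aa)  # trim terminal stop
      if (grepl("\\*", aa)) bad <- c(bad, nm) else prot[[nm]] <- aa
    }
    list(prot = prot, bad = bad)
  }
  ty <- tr(y_cds); tx <- tr(x_cds)
  if (length(ty$bad) || length(tx$bad))
    message("pair_gametologs: excluded CDS with internal stop: ",
            paste(c(ty$bad, tx$bad), collapse = ", "))
  hits <- list()
  data("BLOSUM62", package = "Biostrings", envir = environment())
  BLOSUM62 <- get("BLOSUM62", envir = environment())
  for (yn in names(ty$prot)) {
    scores <- lapply(names(tx$prot), function(xn) {
      al <- Biostrings::pairwiseAlignment(ty$prot[[yn]], tx$prot[[xn]],
                                          type = "local",
                                          substitutionMatrix = BLOSUM62,
                                          gapOpening = 10, gapExtension = 0.5)
      len <- nchar(as.character(Biostrings::pattern(al)))
      data.table(y_gene = yn, x_gene = xn,
                 score = Biostrings::score(al),
                 identity = Biostrings::pid(al),
                 aln_length = len)
    })
    sc <- rbindlist(scores)
    sc <- sc[identity >= min_identity & aln_length >= min_aln_length]
    if (nrow(sc)) hits[[yn]] <- head(sc[order(-score)], max_targets)
  }
  if (!length(hits))
    return(list(pairs = data.table(y_gene = character(), x_gene = character(),
                                   score = numeric(), identity = numeric(),
                                   aln_length = integer()),
                excluded = c(ty$bad, tx$bad)))
  all_hits <- rbindlist(hits)
  best_y <- all_hits[, .SD[which.max(score)], by = y_gene]
  best_x <- all_hits[, .SD[which.max(score)], by = x_gene]
  pairs <- merge(best_y, best_x[, .(y_gene, x_gene)], by = c("y_gene", "x_gene"))
  list(pairs = pairs[order(y_gene)], excluded = c(ty$bad, tx$bad))
}

#' Codon-aware alignment of a gametolog pair
#'
#' Globally aligns the two translated proteins (BLOSUM62, affine gaps) and
#' threads the alignment back onto the nucleotide sequences, so every gap has
#' a length that is a multiple of 3 in nucleotide space. Terminal partial
#' codons and terminal stops are trimmed first. Codon columns containing a
#' gap or an ambiguity code are flagged and excluded from difference
#' counting.
#'
#' @param y_seq,x_seq CDS character strings (or `DNAString`s).
#' @return list of class `codon_alignment`: `y_codons`, `x_codons` (aligned
#'   codon vectors including `"---"` gaps) and `counted` (logical: codon
#'   columns used for NG86 counting).
#' @export
codon_align <- function(y_seq, x_seq) {
  prep <- function(s) {
    s <- toupper(as.character(s))
    s <- substr(s, 1, 3 * (nchar(s) %/% 3))
    cod <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    gc <- Biostrings::GENETIC_CODE
    if (length(cod) && !is.na(gc[cod[length(cod)]]) && gc[cod[length(cod)]] == "*")
      cod <- cod[-length(cod)]
    cod
  }
  yc <- prep(y_seq); xc <- prep(x_seq)
  aa_of <- function(cod) {
    gc <- Biostrings::GENETIC_CODE
    aa <- unname(gc[cod])
    aa[is.na(aa)] <- "X"  # ambiguity codes
    paste(aa, collapse = "")
  }
  data("BLOSUM62", package = "Biostrings", envir = environment())
  BLOSUM62 <- get("BLOSUM62", envir = environment())
  al <- Biostrings::pairwiseAlignment(aa_of(yc), aa_of(xc), type = "global",
                                      substitutionMatrix = BLOSUM62,
                                      gapOpening = 10, gapExtension = 0.5)
  ay <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
  ax <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
  iy <- ix <- 0L
  n <- length(ay)
  y_out <- x_out <- character(n)
  for (i in seq_len(n)) {
    if (ay[i] == "-") y_out[i] <- "---" else { iy <- iy + 1L; y_out[i] <- yc[iy] }
    if (ax[i] == "-") x_out[i] <- "---" else { ix <- ix + 1L; x_out[i] <- xc[ix] }
  }
  counted <- !grepl("-", y_out) & !grepl("-", x_out) &
             grepl("^[ACGT]{3}$", y_out) & grepl("^[ACGT]{3}$", x_out)
  if (!any(counted)) stopf("zero aligned codons: pair dropped")
  structure(list(y_codons = y_out, x_codons = x_out, counted = counted),
            class = "codon_alignment")
}

#' NG86 divergence with Jukes-Cantor correction
#'
#' Classical Nei-Gojobori (1986) counting on an in-frame codon alignment:
#' synonymous site counts per codon are the per-position fractions of the
#' three possible changes that are synonymous (changes to stop codons count
#' as nonsynonymous, so S + N = 3 x counted codons), averaged over the two
#' sequences; synonymous/nonsynonymous differences in multi-difference codons
#' are averaged over all mutational pathways with equal weights (a pathway
#' step is synonymous iff it preserves the amino acid). The proportions
#' pS = Sd/S and pN = Nd/N are corrected with the Jukes-Cantor formula
#' `d = -(3/4) log(1 - (4/3) p)`, undefined (NA with flag) at `p >= 3/4`.
#'
#' @param alignment a [codon_align()] result, or a list with `y_codons`,
#'   `x_codons` and optionally `counted`.
#' @return list: `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`,
#'   `dS_defined`, `dN_defined`, `n_codons` counted.
#' @export
ng86_divergence <- function(alignment) {
  tab <- codon_tables()
  yc <- alignment$y_codons; xc <- alignment$x_codons
  counted <- alignment$counted %||% (grepl("^[ACGT]{3}$", yc) & grepl("^[ACGT]{3}$", xc))
  yc <- yc[counted]; xc <- xc[counted]
  if (!length(yc)) stopf("no counted codons in alignment")
  if (any(tab$aa[yc] == "*") || any(tab$aa[xc] == "*"))
    stopf("internal stop codon in counted region")
  S <- (sum(tab$syn_sites[yc]) + sum(tab$syn_sites[xc])) / 2
  N <- 3 * length(yc) - S
  diffs <- vapply(seq_along(yc), function(i) codon_path_diffs(yc[i], xc[i], tab),
                  numeric(2))
  Sd <- sum(diffs[1, ]); Nd <- sum(diffs[2, ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       dS = jc(pS), dN = jc(pN),
       dS_defined = pS < 0.75, dN_defined = pN < 0.75,
       n_codons = length(yc))
}

# average synonymous/nonsynonymous step counts over all k! mutational
# pathways between two codons (equal path weights)
codon_path_diffs <- function(a, b, tab) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(0, 0))
  perms <- list(seq_along(pos))
  if (k == 2L) perms <- list(1:2, 2:1)
  if (k == 3L) perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  acc <- c(0, 0)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  for (pm in perms) {
    cur <- av; sd_ <- 0; nd_ <- 0
    for (j in pm) {
      nxt <- cur; nxt[pos[j]] <- bv[pos[j]]
      if (tab$aa[paste(cur, collapse = "")] == tab$aa[paste(nxt, collapse = "")])
        sd_ <- sd_ + 1 else nd_ <- nd_ + 1
      cur <- nxt
    }
    acc <- acc + c(sd_, nd_)
  }
  acc / length(perms)
}

#' Summarize gametolog divergence and scan for strata
#'
#' Pairs with `dS > ds_exclude` (default 1) are removed as likely paralogs;
#' the median dS is taken over the retained pairs. The strata table sorts
#' retained pairs by position on the shared (X/Z) haplotype and applies the
#' stricter `ds_strata_cut` (default 0.5) as an alternative filter, enabling
#' visual inspection for discrete divergence bands. Optional comparison dS
#' distributions (e.g. genome-wide intraspecific or interspecific pair sets)
#' are summarized by their medians and the ratio to the gametolog median.
#'
#' @param pair_ds data.frame with `y_gene`, `x_gene`, `dS` (NA allowed) and
#'   optionally `x_position`.
#' @param ds_exclude exclusion threshold for paralog-like pairs (default 1).
#' @param ds_strata_cut stricter threshold for the strata scan (default 0.5).
#' @param comparisons optional named list of numeric dS vectors.
#' @return list: `n_pairs`, `n_retained`, `median_dS`, `strata` (position,
#'   dS, within-cut flags) and `comparisons` (medians and ratios).
#' @export
summarize_divergence <- function(pair_ds, ds_exclude = 1.0, ds_strata_cut = 0.5,
                                 comparisons = NULL) {
  dt <- as.data.table(pair_ds)
  retained <- dt[!is.na(dS) & dS <= ds_exclude]
  med <- if (nrow(retained)) median(retained$dS) else NA_real_
  strata <- NULL
  if ("x_position" %in% names(retained) && nrow(retained)) {
    strata <- retained[order(x_position),
                       .(x_gene, y_gene, x_position, dS,
                         below_strata_cut = dS < ds_strata_cut)]
  }
  comp <- NULL
  if (!is.null(comparisons)) {
    comp <- lapply(comparisons, function(v) {
      m <- median(v[!is.na(v) & v <= ds_exclude])
      list(median = m, ratio_to_gametologs = if (!is.na(med) && med > 0) m / med else NA_real_)
    })
  }
  list(n_pairs = nrow(dt), n_retained = nrow(retained), median_dS = med,
       retained = retained, strata = strata, comparisons = comp)
}

#' NG86/JC divergence for every paired gametolog
#'
#' Convenience wrapper: aligns each pair in codon frame and estimates the
#' NG86 quantities, attaching the X-haplotype gene position when gene models
#' are supplied.
#'
#' @param pairs pairing table (`y_gene`, `x_gene`).
#' @param y_cds,x_cds the CDS sets.
#' @param x_genes optional data.frame (`gene_id`, `start`) giving positions
#'   on the shared haplotype.
#' @return data.table with the NG86 fields per pair.
#' @export
gametolog_divergence <- function(pairs, y_cds, x_cds, x_genes = NULL) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    al <- codon_align(y_cds[[pairs$y_gene[i]]], x_cds[[pairs$x_gene[i]]])
    d <- ng86_divergence(al)
    data.table(y_gene = pairs$y_gene[i], x_gene = pairs$x_gene[i],
               S = d$S, N = d$N, Sd = d$Sd, Nd = d$Nd, pS = d$pS, pN = d$pN,
               dS = d$dS, dN = d$dN, n_codons = d$n_codons)
  })
  out <- rbindlist(rows)
  if (!is.null(x_genes)) {
    xg <- as.data.table(x_genes)
    out[, x_position := xg$start[match(out$x_gene, xg$gene_id)]]
  }
  out[]
}
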