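test_that("NG86 counting matches hand-computed values and the JC domain", {
  # 9 codons, one synonymous third-position difference (TTT/TTC, Phe):
  # S = 9 x 1/3 = 3, Sd = 1, pS = 1/3, dS = -0.75 log(5/9)
  al <- list(y_codons = rep("TTT", 9), x_codons = c("TTC", rep("TTT", 8)))
  d <- ng86_divergence(al)
  expect_equal(d$S, 3)
  expect_equal(d$N, 24)
  expect_equal(d$Sd, 1)
  expect_equal(d$Nd, 0)
  expect_equal(d$pS, 1 / 3)
  expect_equal(d$dS, -0.75 * log(1 - 4 / 9), tolerance = 1e-6)
  expect_equal(d$dN, 0)

  ident <- ng86_divergence(list(y_codons = c("ATG", "GCT"), x_codons = c("ATG", "GCT")))
  expect_equal(ident$dS, 0)
  expect_equal(ident$dN, 0)

  # pS beyond the JC domain (every codon hit at a low-opportunity site:
  # Sd = 6 against S = 2) leaves dS undefined with the flag set
  sat <- ng86_divergence(list(y_codons = rep("TTT", 6), x_codons = rep("TTC", 6)))
  expect_gte(sat$pS, 0.75)
  expect_false(sat$dS_defined)
  expect_true(is.na(sat$dS))

  expect_error(ng86_divergence(list(y_codons = "TAA", x_codons = "TAC",
                                    counted = TRUE)), "stop codon")
})

test_that("NG86 counts equal exhaustive path enumeration on short alignments", {
  set.seed(5)
  for (rep_i in 1:120) {
    n <- sample(1:5, 1)
    yc <- random_sense_codons(n, seed = rep_i)
    xc <- random_sense_codons(n, seed = rep_i + 1000)
    ok <- !any(Biostrings::GENETIC_CODE[yc] == "*") &&
          !any(Biostrings::GENETIC_CODE[xc] == "*")
    if (!ok) next
    d <- ng86_divergence(list(y_codons = yc, x_codons = xc))
    oracle_d <- colSums(t(vapply(seq_len(n), function(i)
      ng86_path_oracle(yc[i], xc[i]), c(Sd = 0, Nd = 0))))
    expect_equal(d$Sd, unname(oracle_d["Sd"]), tolerance = 1e-10)
    expect_equal(d$Nd, unname(oracle_d["Nd"]), tolerance = 1e-10)
    oracle_S <- (sum(vapply(yc, ng86_sites_oracle, numeric(1))) +
                 sum(vapply(xc, ng86_sites_oracle, numeric(1)))) / 2
    expect_equal(d$S, oracle_S, tolerance = 1e-10)
    expect_equal(d$S + d$N, 3 * n, tolerance = 1e-6)
  }
})

test_that("NG86 divergence is symmetric and linear at small divergence", {
  set.seed(9)
  for (i in 1:15) {
    p <- simulate_cds_pair(runif(1, 0, 0.3), 100, seed = i)
    a <- ng86_divergence(codon_align(p$x, p$y))
    b <- ng86_divergence(codon_align(p$y, p$x))
    expect_equal(a[c("S", "N", "Sd", "Nd", "pS", "pN", "dS", "dN")],
                 b[c("S", "N", "Sd", "Nd", "pS", "pN", "dS", "dN")])
  }
  # small-divergence limit: dS -> pS as pS -> 0
  for (s in 1:10) {
    p <- simulate_cds_pair(0.01, 500, seed = 100 + s)
    d <- ng86_divergence(codon_align(p$x, p$y))
    if (d$pS == 0) next
    expect_lt(abs(d$dS - d$pS) / d$pS, 0.02)
  }
})

test_that("codon alignment is in-frame and gap-aware", {
  p <- simulate_cds_pair(0, 60, seed = 2)
  al <- codon_align(p$x, p$y)
  expect_false(any(grepl("-", al$y_codons)))
  expect_identical(al$y_codons, al$x_codons)

  # inserting one codon into the X copy produces a single 3-bp gap
  ins <- paste0(substr(p$x, 1, 90), "GCT", substr(p$x, 91, nchar(p$x)))
  al2 <- codon_align(p$y, ins)
  expect_equal(sum(al2$y_codons == "---"), 1)
  expect_equal(sum(al2$x_codons == "---"), 0)
  expect_equal(sum(!al2$counted), 1)
  d <- ng86_divergence(al2)
  expect_equal(d$Sd + d$Nd, 0)   # gap codon excluded, rest identical

  # ambiguity codons are excluded from counting
  amb <- sub("^...", "NNN", p$y)
  al3 <- codon_align(p$x, amb)
  expect_equal(sum(!al3$counted), 1)
})

test_that("reciprocal best hit pairing recovers simulated gametologs", {
  cfg <- small_config()
  tr <- simulate_truth(cfg)
  cds <- simulate_gametolog_cds(tr, cfg, codons = 120)
  pr <- pair_gametologs(cds$y_cds, cds$x_cds, min_aln_length = 60)
  truth_pairs <- cds$pair_truth
  m <- merge(pr$pairs, truth_pairs, by = "y_gene")
  expect_equal(nrow(m), nrow(truth_pairs))
  expect_identical(m$x_gene.x, m$x_gene.y)
  # identical CDS in both sets pair trivially
  two <- Biostrings::DNAStringSet(c(g1 = cds$y_cds[["ygene_01"]]))
  names(two) <- "same"
  pr2 <- pair_gametologs(two, two, min_aln_length = 60)
  expect_equal(pr2$pairs$x_gene, "same")
  # a shuffled random sequence pairs with nothing
  set.seed(3)
  shuf <- Biostrings::DNAStringSet(
    c(junk = paste(sample(c("A", "C", "G", "T"), 360, replace = TRUE),
                   collapse = "")))
  pr3 <- pair_gametologs(shuf, cds$x_cds, min_aln_length = 60)
  expect_equal(nrow(pr3$pairs), 0)
})

test_that("divergence summary applies exclusion and strata thresholds", {
  pd <- data.frame(y_gene = c("a", "b", "c", "d"),
                   x_gene = c("A", "B", "C", "D"),
                   dS = c(0.01, 0.02, 0.03, 1.4),
                   x_position = c(100, 400, 200, 300))
  s <- summarize_divergence(pd)
  expect_equal(s$n_retained, 3)       # dS = 1.4 removed as paralog-like
  expect_equal(s$median_dS, 0.02)
  expect_equal(s$strata$x_position, c(100, 200, 400))
  expect_true(all(s$strata$below_strata_cut))
  comp <- summarize_divergence(pd, comparisons = list(interspecific = c(0.4, 0.5, 0.6)))
  expect_equal(comp$comparisons$interspecific$median, 0.5)
  expect_equal(comp$comparisons$interspecific$ratio_to_gametologs, 25)
  empty <- summarize_divergence(data.frame(y_gene = character(),
                                           x_gene = character(), dS = numeric()))
  expect_equal(empty$n_retained, 0)
  expect_true(is.na(empty$median_dS))
})
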