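test_that("truth layout honours the configured SDR and swaps carriers under ZW", {
  cfg <- small_config()
  tr <- simulate_truth(cfg)
  expect_equal(tr$sdr$shared, c(400001, 800000))
  expect_equal(tr$sdr$specific[2] - tr$sdr$specific[1] + 1, 400000)
  expect_equal(tr$system, "XY")
  expect_equal(tr$het_sex, "M")
  # every SDR gene is typed, partners are mutual, true dS recorded per pair
  yg <- tr$genes[tr$genes$haplotype == "Y" & tr$genes$region == "SDR", ]
  expect_equal(sum(yg$y_specificity == "XY_gametolog"), 4)
  expect_equal(sum(yg$y_specificity == "Y_specific"), 6)
  expect_true(all(!is.na(yg$true_dS[yg$y_specificity == "XY_gametolog"])))
  partners <- tr$genes[match(yg$partner[!is.na(yg$partner)], tr$genes$gene_id), ]
  expect_true(all(partners$partner == yg$gene_id[!is.na(yg$partner)]))

  zw <- simulate_truth(small_config(system = "ZW"))
  expect_equal(zw$het_sex, "F")
  expect_equal(zw$hap_specific, "W")
  # the female is the hemizygous carrier: her depth is halved inside the SDR
  # on the W assembly while the male lacks the region entirely
  cfgz <- small_config(system = "ZW", depth_dispersion = 0)
  dp <- simulate_depth_tracks(simulate_truth(cfgz), cfgz, "specific")
  idx <- 400001:800000
  expect_equal(mean(dp$female$chr2[idx]) / cfgz$read_depth_mean, 0.5, tolerance = 0.02)
  expect_true(all(dp$male$chr2[idx] == 0))

  expect_error(sim_config(chromosome_length_bp = 1e6, sdr_interval = c(1, 2e6)),
               "SDR interval")
})

test_that("the generators are byte-deterministic under a fixed seed", {
  cfg <- small_config(seed = 11)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  for (d in c(d1, d2)) {
    tr <- simulate_truth(cfg)
    write_truth_files(tr, d)
    cross <- simulate_cross_genotypes(tr, cfg)
    write_genotypes_tsv(cross, file.path(d, "genotypes.tsv"))
    dp <- simulate_depth_tracks(tr, cfg, "specific")
    write_depth_tsv(list(chr2 = dp$male$chr2[1:5000]), file.path(d, "depth.tsv"))
  }
  for (f in c("genes_Y.gff3", "genes_X.gff3", "truth.json", "genotypes.tsv",
              "depth.tsv", "chrom_sizes.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("SDR markers co-segregate with sex; autosomal markers do not", {
  cfg <- small_config()
  tr <- simulate_truth(cfg)
  cross <- simulate_cross_genotypes(tr, cfg)
  mt <- cross$marker_truth
  geno <- cross$genotypes
  flowering <- cross$phenotypes[cross$phenotypes$sex %in% c("F", "M"), ]

  sdr_male_snp <- mt[mt$in_sdr & mt$category == "male_het_SNP", ]$marker_id[1]
  row <- geno[geno$marker_id == sdr_male_snp, flowering$id, with = FALSE]
  tab <- table(unlist(row) == "AB", flowering$sex)
  # perfectly diagonal: carriers are exactly the males
  expect_equal(tab["TRUE", "M"], sum(flowering$sex == "M"))
  expect_equal(tab["FALSE", "F"], sum(flowering$sex == "F"))

  # heterozygous-in-both-parents markers are flagged uninformative in truth
  expect_true(any(mt$category == "uninformative"))
  expect_true(all(!mt$in_sdr[mt$category == "uninformative"]))

  # law of large numbers: allele-sex correlation of off-SDR-chromosome
  # markers vanishes with 10,000 progeny
  big <- small_config(seed = 3, n_female = 5000, n_male = 5000,
                      n_nonflowering = 0, marker_spacing_bp = 200000)
  trb <- simulate_truth(big)
  crb <- simulate_cross_genotypes(trb, big)
  ph <- crb$phenotypes
  auto <- crb$marker_truth[crb$marker_truth$seq == "chr1" &
                           crb$marker_truth$category != "uninformative", ]$marker_id
  for (mid in auto[1:3]) {
    row <- unlist(crb$genotypes[crb$genotypes$marker_id == mid, ph$id, with = FALSE])
    carrier <- as.numeric(row %in% c("AB", "P"))
    r <- suppressWarnings(cor(carrier, as.numeric(ph$sex == "M")))
    expect_lt(abs(r), 0.05)
  }

  empty <- small_config(n_female = 0, n_male = 0, n_nonflowering = 0)
  expect_warning(res <- simulate_cross_genotypes(simulate_truth(empty), empty),
                 "zero progeny")
  expect_equal(nrow(res$phenotypes), 0)
})

test_that("depth tracks follow the copy multipliers at 30x coverage", {
  cfg <- small_config()
  tr <- simulate_truth(cfg)
  idx <- 400001:800000
  # sex-limited assembly: homogametic sex has no reads over the region
  sp <- simulate_depth_tracks(tr, cfg, "specific")
  expect_true(all(sp$female$chr2[idx] == 0))
  expect_equal(mean(sp$male$chr2[idx]) / cfg$read_depth_mean, 0.5, tolerance = 0.05)
  # shared assembly: the heterogametic sex is hemizygous over the region
  sh <- simulate_depth_tracks(tr, cfg, "shared")
  expect_equal(mean(sh$male$chr2[idx]) / cfg$read_depth_mean, 0.5, tolerance = 0.05)
  expect_equal(mean(sh$female$chr2[idx]) / cfg$read_depth_mean, 1, tolerance = 0.05)
  # autosome: both sexes diploid
  expect_equal(mean(sp$male$chr1) / cfg$read_depth_mean, 1, tolerance = 0.05)
  expect_equal(mean(sp$female$chr1) / cfg$read_depth_mean, 1, tolerance = 0.05)
  # Poisson limit: variance/mean ratio ~1 when dispersion is 0
  cfg0 <- small_config(depth_dispersion = 0)
  p0 <- simulate_depth_tracks(simulate_truth(cfg0), cfg0, "shared")
  expect_equal(var(p0$male$chr1) / mean(p0$male$chr1), 1, tolerance = 0.05)
})

test_that("planted expression effects are recovered and silent genes excluded", {
  cfg <- small_config()
  tr <- simulate_truth(cfg)
  expr <- simulate_expression_counts(tr, cfg)
  expect_setequal(tr$candidate_effects$gene_id,
                  c("ygene_02", "ygene_03"))
  d <- expr$design
  for (gid in tr$candidate_effects$gene_id) {
    mM <- mean(expr$counts[gid, d$sample[d$group == "M_flower"]])
    mF <- mean(expr$counts[gid, d$sample[d$group == "F_flower"]])
    expect_equal(log2((mM + 0.5) / (mF + 0.5)), 5, tolerance = 1)
  }
  de <- de_summary(expr$counts, expr$design, c("M_flower", "F_flower"))
  silent <- names(which(expr$baseline == 0))
  expect_true(length(silent) > 0)
  expect_true(all(de$baseMean[match(silent, de$gene)] == 0))
  expect_true(all(is.na(de$padj[match(silent, de$gene)])))
})

test_that("gametolog CDS pairs hit their target divergence", {
  p0 <- simulate_cds_pair(0, 80, seed = 1)
  expect_identical(p0$x, p0$y)
  gc <- Biostrings::GENETIC_CODE
  codons <- substring(p0$x, seq(1, nchar(p0$x), 3), seq(3, nchar(p0$x), 3))
  expect_false(any(gc[codons] == "*"))  # stop-free by construction

  p <- simulate_cds_pair(0.05, 300, seed = 5)
  d <- ng86_divergence(codon_align(p$x, p$y))
  expect_equal(d$dN, 0)                  # synonymous-only mutation
  expect_gt(d$dS, 0)
  expect_error(simulate_cds_pair(0.9, 100), "exceeds")
  expect_error(simulate_cds_pair(0.02, 10), "50 codons")
})
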