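test_that("Fisher's exact p matches closed forms and the stats cross-check", {
  expect_equal(fisher_exact_2x2(matrix(c(10, 10, 10, 10), 2)), 1)
  # margins (5,5)/(5,5): only the two diagonal tables are as extreme
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(4, 0, 0, 4), 2)), 2 / 70,
               tolerance = 1e-12)
  # zero margin carries no information
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 5, 7), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(0, 3, 0, 7), 2)), 1)
  expect_error(fisher_exact_2x2(c(1, -1, 2, 2)), "non-negative")

  set.seed(42)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(c(2, 10, 40), 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-9, label = paste(tab, collapse = ","))
  }
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.001, 0.5)), c(0.002, 0.5))
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(1)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    # monotone non-decreasing in sorted-p order
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("association scan flags SDR markers and controls the null", {
  cfg <- small_config()
  cross <- simulate_cross_genotypes(simulate_truth(cfg), cfg)
  cls <- classify_markers(cross$genotypes, "P_F", "P_M")
  scan <- association_scan(cls, cross$genotypes, cross$phenotypes, "P_F", "P_M")
  mt <- cross$marker_truth
  sdr_male <- mt$marker_id[mt$in_sdr & grepl("^male_het", mt$category)]
  expect_true(all(scan$significant[match(sdr_male, scan$marker_id)]))
  # no female-het marker reaches significance in an XY system
  expect_equal(sum(scan$significant[grepl("^female_het", scan$category)]), 0)
  expect_true(all(scan$q >= scan$p - 1e-12))
  expect_equal(scan$neglog10q, -log10(scan$q))

  # balanced subsampling analyzes equal numbers of each sex
  bal <- association_scan(cls, cross$genotypes, cross$phenotypes, "P_F", "P_M",
                          balanced = TRUE, seed = 9)
  tots <- bal[!bal$all_missing, ]
  expect_true(all(tots$a + tots$c == 38))
  expect_true(all(tots$b + tots$d == 38))

  # permuting individual columns never changes p or q
  perm <- data.table::copy(cross$genotypes)
  prog <- setdiff(names(perm), c("marker_id", "seq", "pos", "type", "P_F", "P_M"))
  data.table::setcolorder(perm, c("marker_id", "seq", "pos", "type", "P_F",
                                  "P_M", rev(prog)))
  scan2 <- association_scan(cls, perm, cross$phenotypes, "P_F", "P_M")
  expect_equal(scan2$p, scan$p)
  expect_equal(scan2$q, scan$q)
})

test_that("autosomal-only markers give no significant associations", {
  cfg <- small_config(seed = 21)
  cross <- simulate_cross_genotypes(simulate_truth(cfg), cfg)
  cls <- classify_markers(cross$genotypes, "P_F", "P_M")
  auto <- cls[cls$seq == "chr1", ]   # chromosome without the SDR
  scan <- association_scan(auto, cross$genotypes, cross$phenotypes, "P_F", "P_M")
  expect_lte(mean(scan$significant), 0.05)
})

test_that("the sex-system verdict follows the significant marker categories", {
  mk <- function(cat, sig, seq = "chr3", pos = 1:length(sig) * 1e5)
    data.table::data.table(marker_id = paste0(cat, seq_along(sig)), seq = seq,
                           pos = pos, category = cat, significant = sig)
  xy <- rbind(mk("male_het_SNP", c(TRUE, TRUE, FALSE)),
              mk("female_het_SNP", c(FALSE, FALSE, FALSE)))
  v <- classify_sex_system(xy)
  expect_equal(v$verdict, "XY")
  expect_equal(v$peak$chrom, "chr3")
  expect_equal(v$peak$start, 1e5)
  expect_equal(v$peak$end, 2e5)
  zw <- rbind(mk("male_het_SNP", c(FALSE, FALSE, FALSE)),
              mk("female_het_PA", c(TRUE, TRUE, TRUE)))
  expect_equal(classify_sex_system(zw)$verdict, "ZW")
  both <- rbind(mk("male_het_SNP", TRUE), mk("female_het_SNP", TRUE))
  expect_equal(classify_sex_system(both)$verdict, "ambiguous")
  none <- rbind(mk("male_het_SNP", FALSE), mk("female_het_SNP", FALSE))
  expect_equal(classify_sex_system(none)$verdict, "none")
})

test_that("the verdict is recovered across seeds for both systems", {
  for (seed in c(2, 13)) {
    for (sys in c("XY", "ZW")) {
      cfg <- small_config(seed = seed, system = sys)
      cross <- simulate_cross_genotypes(simulate_truth(cfg), cfg)
      cls <- classify_markers(cross$genotypes, "P_F", "P_M")
      scan <- association_scan(cls, cross$genotypes, cross$phenotypes,
                               "P_F", "P_M")
      expect_equal(classify_sex_system(scan)$verdict, sys,
                   label = sprintf("seed %d system %s", seed, sys))
    }
  }
})
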