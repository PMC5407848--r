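# Site frequency summaries, population comparison and multi-allelic
# Hardy-Weinberg testing.

test_that("site frequencies count gene copies and individuals correctly", {
  # a single Leu/Ser heterozygote
  sf <- site_frequencies("TCA/TTA")
  expect_equal(sf$alleles$frequency[sf$alleles$allele == "Leu"], 0.5)
  expect_equal(sf$alleles$frequency[sf$alleles$allele == "Ser"], 0.5)
  # known counts: 2 x homozygote + heterozygote over 2n
  g <- c(rep("TCA/TCA", 10), rep("TCA/TTA", 5), rep("TTT/TTT", 3), "TTA/TTT")
  sf2 <- site_frequencies(g)
  n <- length(g)
  expect_equal(sf2$alleles$frequency[sf2$alleles$allele == "Ser"],
               (2 * 10 + 5) / (2 * n))
  expect_equal(sf2$alleles$frequency[sf2$alleles$allele == "Leu"],
               (5 + 1) / (2 * n))
  expect_equal(sum(sf2$alleles$frequency), 1)
  expect_equal(sum(sf2$groups$frequency), 1)
  # fixation: a site lacking the susceptible allele entirely
  sf3 <- site_frequencies(rep("TTT/TTT", 12))
  expect_equal(sf3$alleles$frequency[sf3$alleles$allele == "Phe"], 1)
  expect_equal(sf3$alleles$frequency[sf3$alleles$allele == "Leu"], 0)
  expect_error(site_frequencies(character(0)), "empty")
})

test_that("population comparison is a Pearson test, symmetric in its arguments", {
  set.seed(14)
  ga <- draw_hwe_genotypes(c(TTA = 0.3, TCA = 0.4, TTT = 0.2, TTC = 0.1), 60)
  gb <- draw_hwe_genotypes(c(TTA = 0.1, TCA = 0.3, TTT = 0.4, TTC = 0.2), 60)
  res <- compare_populations(ga, gb, "allele")
  # equals the brute-force Pearson computation on the 2 x 3 allele table
  tab <- rbind(count_alleles(ga), count_alleles(gb))
  expect_equal(res$statistic, pearson_oracle(tab))
  expect_equal(res$df, 2L)
  # symmetry
  res_swap <- compare_populations(gb, ga, "allele")
  expect_equal(res$statistic, res_swap$statistic)
  expect_equal(res$p_value, res_swap$p_value)
  # identical samples give a statistic of (essentially) zero
  res0 <- compare_populations(ga, ga, "allele")
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  # genotype-group level uses individual counts
  resg <- compare_populations(ga, gb, "group")
  tabg <- rbind(table(genotype_group(ga)), table(genotype_group(gb)))
  expect_equal(resg$statistic, pearson_oracle(tabg))
  # a category absent from both samples is dropped with reduced df
  ga2 <- c(rep("TCA/TCA", 30), rep("TCA/TTT", 10))
  gb2 <- c(rep("TCA/TCA", 20), rep("TCA/TTT", 25))
  expect_message(res2 <- compare_populations(ga2, gb2, "allele"), "dropping")
  expect_equal(res2$dropped, "Leu")
  expect_equal(res2$df, 1L)
})

test_that("a frequency difference of 0.25 vs 0.05 is detected nearly always", {
  set.seed(23)
  reps <- 200
  rej <- 0
  fa <- c(TTA = 0.25, TCA = 0.40, TTT = 0.25, TTC = 0.10)
  fb <- c(TTA = 0.05, TCA = 0.50, TTT = 0.35, TTC = 0.10)
  for (r in seq_len(reps)) {
    ga <- draw_hwe_genotypes(fa, 200)
    gb <- draw_hwe_genotypes(fb, 200)
    p <- suppressMessages(compare_populations(ga, gb, "allele"))$p_value
    if (p < 0.05) rej <- rej + 1
  }
  expect_gt(rej / reps, 0.95)
})

test_that("Hardy-Weinberg chi-square is exact on perfect proportions", {
  g <- c(rep("TTA/TTA", 25), rep("TCA/TTA", 50), rep("TCA/TCA", 25))
  h <- hwe_test(g, method = "chi-square")
  expect_equal(h$statistic, 0, tolerance = 1e-12)
  expect_equal(h$p_value, 1)
  # expected counts sum to n
  expect_equal(sum(h$expected), h$n, tolerance = 1e-9)
  # monomorphic sample short-circuits
  hm <- hwe_test(rep("TTT/TTT", 30))
  expect_equal(hm$method, "monomorphic")
  expect_equal(hm$p_value, 1)
})

test_that("Monte-Carlo HWE p agrees with exact enumeration for small n", {
  set.seed(55)
  freqs <- list(c(TTA = 0.5, TCA = 0.3, TTT = 0.2, TTC = 0),
                c(TTA = 0.25, TCA = 0.25, TTT = 0.25, TTC = 0.25),
                c(TTA = 0.7, TCA = 0.2, TTT = 0.05, TTC = 0.05))
  for (f in freqs) {
    g <- draw_hwe_genotypes(f, 18)
    ex <- hwe_test(g, method = "exact")
    mc <- hwe_test(g, method = "monte-carlo", reps = 5000, seed = 101)
    se <- max(mc$mc_se, sqrt(ex$p_value * (1 - ex$p_value) / mc$reps))
    expect_lt(abs(mc$p_value - ex$p_value), 3 * max(se, 1e-3))
  }
})

test_that("Monte-Carlo HWE p is reproducible bit-for-bit from its seed", {
  set.seed(66)
  g <- draw_hwe_genotypes(c(TTA = 0.4, TCA = 0.3, TTT = 0.3, TTC = 0), 40)
  a <- hwe_test(g, method = "monte-carlo", reps = 2000, seed = 9)
  b <- hwe_test(g, method = "monte-carlo", reps = 2000, seed = 9)
  expect_identical(a$p_value, b$p_value)
  # codon-level testing is available behind the level flag
  g4 <- draw_hwe_genotypes(c(TTA = 0.3, TCA = 0.3, TTT = 0.2, TTC = 0.2), 200)
  h4 <- hwe_test(g4, method = "chi-square", level = "codon")
  expect_equal(h4$df, 6)  # 4 observed alleles: 10 classes - 4
  # the same sample pooled to residues has 3 alleles, df 3
  h3 <- hwe_test(g4, method = "chi-square", level = "residue")
  expect_equal(h3$df, 3)
})

test_that("HWE chi-square type-I error is near nominal under the null", {
  set.seed(88)
  reps <- 500
  rej <- 0
  f <- c(TTA = 0.2, TCA = 0.3, TTT = 0.5, TTC = 0)
  for (r in seq_len(reps)) {
    g <- draw_hwe_genotypes(f, 100)
    if (hwe_test(g, method = "chi-square")$p_value < 0.05) rej <- rej + 1
  }
  rate <- rej / reps
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / reps))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("site genotype counting respects the pooling level", {
  sp <- data.frame(
    id = 1:6,
    district = c("A", "A", "A", "B", "B", "B"),
    genotype = c("TCA/TCA", "TCA/TTA", "TTT/TTT", "TCA/TCA", "TCA/TCA", "TTA/TTA"),
    stringsAsFactors = FALSE)
  m <- site_genotype_counts(sp, by = "district")
  expect_equal(dim(m), c(2L, 6L))
  expect_equal(sum(m["A", ]), 3L)
  expect_equal(unname(m["B", "Ser/Ser"]), 2L)
})
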