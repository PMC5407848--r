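# Association statistics: Abbott gating, contingency tables, tests,
# odds ratios, proportion intervals, multiple comparisons.

fx <- bioassay_fixture()

test_that("Abbott correction follows the three-branch gating convention", {
  expect_equal(abbott_correction(43, 0),
               list(mortality_pct = 43, verdict = "uncorrected"))
  corr <- abbott_correction(50, 20)
  expect_equal(corr$mortality_pct, 100 * (50 - 20) / (100 - 20))  # 37.5
  expect_equal(corr$verdict, "corrected")
  expect_equal(abbott_correction(60, 25)$verdict, "discard")
  # with the discard gate lifted, full control mortality is undefined
  expect_error(abbott_correction(60, 100, discard_above = 100), "undefined")
  expect_error(abbott_correction(101, 0))
})

test_that("allele and genotype-group tables reproduce the fixture counts", {
  pa <- printed_allele_counts()
  pg <- printed_group_counts()
  for (ins in names(pa)) {
    at <- allele_count_table(fx, ins)
    expect_equal(at, pa[[ins]], ignore_attr = TRUE)
    gt <- genotype_group_table(fx, ins)
    expect_equal(gt, pg[[ins]], ignore_attr = TRUE)
    # allele table is exactly derivable from the genotype table:
    # 2 x homozygotes + heterozygotes per allele
    expect_equal(rowSums(at), 2 * rowSums(gt))
  }
  # Leu/* fine split for deltamethrin
  gtf <- genotype_group_table(fx, "deltamethrin", leu_split = TRUE)
  expect_equal(unname(gtf["alive", c("Leu/Leu", "Leu/Ser", "Leu/Phe")]),
               c(0L, 0L, 11L))
  # empty input gives an all-zero table
  empty <- fx[0, ]
  expect_true(all(allele_count_table(empty, "DDT") == 0))
  # ungenotyped specimens are excluded and counted
  fx2 <- fx
  fx2$genotype[1:5] <- NA
  at2 <- allele_count_table(fx2, "DDT")
  expect_equal(unname(attr(at2, "excluded")["ungenotyped"]), 5L)
  expect_equal(sum(at2), sum(allele_count_table(fx, "DDT")) - 10L)
})

test_that("Pearson chi-square matches the double-loop oracle and handles degeneracy", {
  set.seed(31)
  for (rep in 1:20) {
    tab <- matrix(rpois(8, 20) + 1, nrow = 2)
    res <- chi_square_rxc(tab)
    expect_equal(res$statistic, pearson_oracle(tab))
    expect_equal(res$df, 3L)
  }
  # proportional rows: statistic 0, p = 1
  prop_tab <- rbind(c(10, 20, 30), c(20, 40, 60))
  res0 <- chi_square_rxc(prop_tab)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # zero margin names the degenerate level
  bad <- rbind(alive = c(a = 0, b = 5), dead = c(a = 0, b = 7))
  expect_error(chi_square_rxc(bad), "a")
})

test_that("Fisher exact p agrees with hypergeometric enumeration", {
  # fixture example: Phe vs Ser alleles under DDT
  at <- allele_count_table(fx, "DDT")
  p <- fisher_exact_2x2(at[, c("Phe", "Ser")])$p_value
  expect_equal(p, 0.0013, tolerance = 0.1)
  # identical rows are completely uninformative
  expect_equal(fisher_exact_2x2(rbind(c(7, 11), c(7, 11)))$p_value, 1)
  # random small tables against the enumeration oracle
  set.seed(8)
  for (rep in 1:50) {
    cells <- as.vector(stats::rmultinom(1, sample(4:30, 1), rep(0.25, 4)))
    tab <- matrix(cells, 2)
    expect_equal(fisher_exact_2x2(tab)$p_value,
                 fisher_enum_oracle(cells[1], cells[3], cells[2], cells[4]),
                 tolerance = 1e-10)
  }
})

test_that("odds ratios use the cross-product estimator with Woolf intervals", {
  at_ddt <- allele_count_table(fx, "DDT")
  or1 <- odds_ratio(at_ddt[, c("Ser", "Leu")])
  expect_equal(or1$or, (93 * 82) / (68 * 12))
  expect_equal(round(or1$or, 2), 9.35)
  expect_equal(or1$estimator, "cross-product")
  at_d <- allele_count_table(fx, "deltamethrin")
  expect_equal(round(odds_ratio(at_d[, c("Ser", "Leu")])$or, 2), 3.47)
  # symmetric table: OR exactly 1
  expect_equal(odds_ratio(rbind(c(9, 9), c(9, 9)))$or, 1)
  # column swap inverts the OR; CI contains the point estimate
  set.seed(12)
  for (rep in 1:20) {
    tab <- matrix(rpois(4, 15) + 1, 2)
    o <- odds_ratio(tab)
    oswap <- odds_ratio(tab[, 2:1])
    expect_equal(o$or, 1 / oswap$or)
    expect_true(o$ci[1] <= o$or && o$or <= o$ci[2])
  }
  # zero cell: Haldane correction, tagged
  oz <- odds_ratio(rbind(c(13, 9), c(0, 62)))
  expect_equal(oz$estimator, "cross-product-haldane")
  expect_true(is.finite(oz$or))
  expect_error(odds_ratio(rbind(c(0, 0), c(3, 4))), "undefined")
})

test_that("continuity-corrected Wilson intervals behave at the boundaries", {
  s <- survival_proportion_ci(28, 43)
  expect_equal(s$estimate, 28 / 43, tolerance = 1e-12)
  expect_equal(round(s$estimate, 2), 0.65)
  full <- survival_proportion_ci(13, 13)
  expect_equal(full$estimate, 1)
  expect_equal(full$upper, 1)
  none <- survival_proportion_ci(0, 20)
  expect_equal(none$lower, 0)
  # interval respects [0,1] and contains the point estimate
  set.seed(4)
  for (rep in 1:30) {
    n <- sample(1:200, 1); k <- sample(0:n, 1)
    ci <- survival_proportion_ci(k, n)
    expect_true(ci$lower >= 0 && ci$upper <= 1)
    expect_true(ci$lower <= ci$estimate && ci$estimate <= ci$upper)
  }
  # monotone widening as n decreases at fixed p-hat
  w <- sapply(c(400, 100, 25), function(n) {
    ci <- survival_proportion_ci(0.6 * n, n); ci$upper - ci$lower
  })
  expect_true(all(diff(w) > 0))
  expect_error(survival_proportion_ci(1, 0))
})

test_that("Marascuilo-McSweeney comparisons reproduce the deltamethrin post-hoc", {
  # K = 5: Leu/Leu + Leu/Ser pooled, Leu/Phe, and the three kdr-only groups
  gtf <- genotype_group_table(fx, "deltamethrin", leu_split = TRUE)
  k <- c(`Leu/wt` = sum(gtf["alive", c("Leu/Leu", "Leu/Ser")]),
         `Leu/Phe` = unname(gtf["alive", "Leu/Phe"]),
         colSums(rbind(gtf["alive", c("Ser/Ser", "Ser/Phe", "Phe/Phe")])))
  n <- c(sum(colSums(gtf)[c("Leu/Leu", "Leu/Ser")]),
         colSums(gtf)[c("Leu/Phe", "Ser/Ser", "Ser/Phe", "Phe/Phe")])
  mar <- marascuilo_pairwise(unname(k), unname(n), alpha = 0.05)
  pair <- mar[mar$group_i == "group1" & mar$group_j == "group2", ]
  expect_equal(pair$p_value, 0.0014, tolerance = 0.02)
  expect_true(pair$significant)
  # all-equal proportions yield no significant pairs
  eq <- marascuilo_pairwise(c(5, 5, 5), c(20, 20, 20))
  expect_false(any(eq$significant))
  # K = 2 decision coincides with the two-proportion z-test at alpha
  set.seed(21)
  for (rep in 1:25) {
    n2 <- sample(10:80, 2, replace = TRUE)
    k2 <- c(sample(1:(n2[1] - 1), 1), sample(1:(n2[2] - 1), 1))
    m2 <- marascuilo_pairwise(k2, n2, alpha = 0.05)
    p <- k2 / n2
    z <- abs(p[1] - p[2]) / sqrt(p[1] * (1 - p[1]) / n2[1] + p[2] * (1 - p[2]) / n2[2])
    expect_equal(m2$significant, z > qnorm(0.975))
    expect_equal(m2$p_value, pchisq(z^2, 1, lower.tail = FALSE))
  }
  # degenerate boundary pair is flagged and handled conservatively
  b <- marascuilo_pairwise(c(0, 10), c(10, 10))
  expect_true(b$boundary)
  expect_true(is.finite(b$p_value))
})

test_that("Holm step-down decisions are monotone and match p.adjust", {
  expect_true(sequential_bonferroni(0.01, alpha = 0.05)$reject)
  r3 <- sequential_bonferroni(c(0.001, 0.02, 0.04), alpha = 0.05)
  expect_true(all(r3$reject))
  expect_equal(r3$threshold, c(0.05 / 3, 0.05 / 2, 0.05))
  r_stop <- sequential_bonferroni(c(0.04, 0.04, 0.04), alpha = 0.05)
  expect_false(any(r_stop$reject))
  expect_equal(nrow(sequential_bonferroni(numeric(0))), 0L)
  # agreement with the installed Holm adjustment on random inputs
  set.seed(9)
  for (rep in 1:25) {
    p <- runif(sample(1:8, 1))
    mine <- sequential_bonferroni(p, alpha = 0.05)$reject
    ref_dec <- p.adjust(p, method = "holm") <= 0.05
    expect_equal(mine, unname(ref_dec))
    # monotone in sorted order: no rejection after a retention
    o <- order(p)
    expect_false(is.unsorted(rev(mine[o])))
  }
})

test_that("phenylalanine codon homogeneity testing justifies pooling", {
  # both codons identically distributed across outcomes: p = 1
  sp <- data.frame(
    id = 1:40, insecticide = "DDT", outcome = rep(c("alive", "dead"), each = 20),
    role = "test",
    genotype = rep(c("TTT/TTT", "TTC/TTC"), 20), stringsAsFactors = FALSE)
  hom <- allele_homogeneity_test(sp)
  expect_equal(hom$per_insecticide$p_value, 1)
  expect_false(hom$pooling_warning)
  # a strong codon-outcome association triggers the pooling warning and
  # matches the enumeration oracle
  sp2 <- data.frame(
    id = 1:60, insecticide = "DDT",
    outcome = rep(c("alive", "dead"), each = 30), role = "test",
    genotype = c(rep("TTT/TTT", 27), rep("TTC/TTC", 3),
                 rep("TTT/TTT", 5), rep("TTC/TTC", 25)),
    stringsAsFactors = FALSE)
  expect_warning(hom2 <- allele_homogeneity_test(sp2), "pooling")
  expect_lt(hom2$min_p, 0.05)
  row <- hom2$per_insecticide
  expect_equal(row$p_value,
               fisher_enum_oracle(row$alive_TTT, row$alive_TTC,
                                  row$dead_TTT, row$dead_TTC),
               tolerance = 1e-10)
})

test_that("null-model chi-square calibration holds at the 5% level", {
  # equal survival across four groups: rejection rate ~ alpha
  set.seed(77)
  reps <- 400
  rej <- 0
  for (r in seq_len(reps)) {
    alive <- rbinom(4, 100, 0.5)
    tab <- rbind(alive = alive, dead = 100 - alive)
    if (chi_square_rxc(tab)$p_value < 0.05) rej <- rej + 1
  }
  expect_gt(rej / reps, 0.05 - 3 * sqrt(0.05 * 0.95 / reps))
  expect_lt(rej / reps, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})
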