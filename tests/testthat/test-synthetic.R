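# Synthetic-data generator: fixture expansion, specimen simulation,
# readout and amplicon emission.

test_that("the packaged fixture expands to the expected specimen counts", {
  fx <- bioassay_fixture()
  expect_equal(nrow(fx), 435L)  # 166 DDT + 109 deltamethrin + 160 alpha
  ddt <- fx[fx$insecticide == "DDT", ]
  expect_equal(sum(ddt$outcome == "alive"), 83L)
  expect_equal(sum(ddt$outcome == "dead"), 83L)
  expect_equal(unique(ddt$exposure_minutes), 60)
  expect_equal(unique(fx$cohort[fx$insecticide == "deltamethrin"]), "colony")
  # expansion is deterministic
  expect_identical(fx, bioassay_fixture())
})

test_that("fixture-estimated penetrance equals the group survival ratios", {
  pen <- fixture_penetrance()
  expect_equal(unname(pen$DDT["Ser/Ser"]), 28 / 43)
  expect_equal(unname(pen$DDT["Phe/Phe"]), 1)
  expect_equal(unname(pen$DDT["Leu/Leu"]), 3 / 23)
  expect_equal(unname(pen$deltamethrin["Leu/Phe"]), 11 / 29)
  expect_equal(unname(pen$`alpha-cypermethrin`["Ser/Ser"]), 13 / 28)
  # every entry is a proportion
  for (ins in names(pen)) expect_true(all(pen[[ins]] >= 0 & pen[[ins]] <= 1))
})

test_that("specimen simulation is deterministic and honours degenerate configs", {
  cfg <- synthetic_config(seed = 77)
  a <- simulate_specimens(cfg)
  b <- simulate_specimens(cfg)
  expect_identical(a, b)
  expect_error(synthetic_config(), "seed")

  # one allele at frequency 1: everyone homozygous for it
  cfg1 <- synthetic_config(
    sites = data.frame(name = "S", TTA = 0, TCA = 1, TTT = 0, TTC = 0, f = 0),
    seed = 3)
  sp1 <- simulate_specimens(cfg1)
  expect_true(all(sp1$genotype == "TCA/TCA"))

  # penetrance all 1 and control mortality 0: every test specimen alive
  pen1 <- lapply(fixture_penetrance(), function(p) {p[] <- 1; p})
  cfg2 <- synthetic_config(penetrance = pen1, control_mortality = 0, seed = 4)
  sp2 <- simulate_specimens(cfg2)
  expect_true(all(sp2$outcome[sp2$role == "test"] == "alive"))
  expect_true(all(sp2$outcome[sp2$role == "control"] == "alive"))

  # missing penetrance for an encountered group fails before sampling
  pen_bad <- fixture_penetrance()
  pen_bad$DDT <- pen_bad$DDT[-1]
  cfg3 <- synthetic_config(penetrance = pen_bad, seed = 5)
  expect_error(simulate_specimens(cfg3), "penetrance missing")
})

test_that("realised allele frequencies track the configured frequencies", {
  truth <- c(TTA = 0.2, TCA = 0.35, TTT = 0.3, TTC = 0.15)
  cfg <- synthetic_config(
    sites = data.frame(name = "S", TTA = 0.2, TCA = 0.35, TTT = 0.3, TTC = 0.15,
                       f = 0),
    penetrance = fixture_penetrance()["DDT"],
    bioassays_per_site = 100L, seed = 19)  # 2500 specimens, 5000 alleles
  sp <- simulate_specimens(cfg)
  cc <- count_alleles(sp$genotype, level = "codon")
  n_copies <- sum(cc)
  for (al in names(truth)) {
    se <- sqrt(truth[[al]] * (1 - truth[[al]]) / n_copies)
    expect_lt(abs(cc[[al]] / n_copies - truth[[al]]), 3 * se)
  }
})

test_that("inbreeding raises homozygosity as F prescribes", {
  mk <- function(f, seed) synthetic_config(
    sites = data.frame(name = "S", TTA = 0.5, TCA = 0.5, TTT = 0, TTC = 0, f = f),
    penetrance = fixture_penetrance()["DDT"],
    bioassays_per_site = 40L, seed = seed)
  sp0 <- simulate_specimens(mk(0, 11))
  sp9 <- simulate_specimens(mk(0.9, 11))
  het <- function(sp) mean(genotype_residues(sp$genotype) == "Leu/Ser")
  # expected heterozygosity 2pq(1-F): 0.5 vs 0.05
  expect_gt(het(sp0), 0.4)
  expect_lt(het(sp9), 0.15)
})

test_that("assay readout emission respects the no-call rate", {
  gs <- all_kdr_genotypes()
  # rate 0: canonical readouts recover every genotype
  ro <- simulate_assay_readouts(gs, no_call_rate = 0, seed = 1)
  called <- call_genotypes_from_readouts(ro)
  expect_equal(called$genotype, gs)
  expect_true(all(called$call_status == "ok"))
  # rate 1: everything null
  ro1 <- simulate_assay_readouts(gs, no_call_rate = 1, seed = 1)
  expect_true(all(ro1$assay1 == "null" & ro1$assay2 == "null"))
  called1 <- call_genotypes_from_readouts(ro1)
  expect_true(all(called1$call_status == "no_call"))
  # intermediate rate: among slots whose canonical readout is non-null
  # (several genotypes are legitimately null on one assay), the nulled
  # fraction tracks the rate within 3 binomial SE
  g <- sample(gs, 1000, replace = TRUE)
  ro2 <- simulate_assay_readouts(g, no_call_rate = 0.1, seed = 2)
  canon <- lapply(g, expected_readout)
  emitted <- c(ro2$assay1, ro2$assay2)
  expected_calls <- c(vapply(canon, `[[`, "", "assay1"),
                      vapply(canon, `[[`, "", "assay2"))
  informative <- expected_calls != "null"
  frac <- mean(emitted[informative] == "null")
  n_inf <- sum(informative)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / n_inf))
})

test_that("amplicon emission superposes heterozygote codons position-wise", {
  ref <- kdr_reference()
  pos <- kdrkit:::codon_genomic_positions(ref, 1014L)
  codon_at <- function(amp) unname(substr(as.character(amp), pos[1] + 1L, pos[3] + 1L))
  expect_equal(codon_at(simulate_amplicons("TCA/TCA", ref)), "TCA")
  expect_equal(codon_at(simulate_amplicons("TCA/TTA", ref)), "TYA")
  expect_equal(codon_at(simulate_amplicons("TTC/TTT", ref)), "TTY")
  expect_equal(codon_at(simulate_amplicons("TCA/TTT", ref)), "TYW")
  # primers stay embedded so the amplicon is locatable
  amp <- as.character(simulate_amplicons("TCA/TTA", ref))
  expect_equal(locate_amplicon(amp)$status, "ok")
})

test_that("simulated data recover the Ser-vs-Leu odds ratio", {
  fx <- bioassay_fixture()
  at <- allele_count_table(fx, "DDT")
  target <- odds_ratio(at[, c("Ser", "Leu")])$or
  set.seed(31)
  reps <- 120
  covered <- 0
  for (r in seq_len(reps)) {
    cfg <- synthetic_config(
      sites = data.frame(name = "S", TTA = 0.25, TCA = 0.40, TTT = 0.25,
                         TTC = 0.10, f = 0),
      penetrance = fixture_penetrance()["DDT"],
      bioassays_per_site = 20L, seed = 5000 + r)  # 500 specimens, 1000 alleles
    sp <- simulate_specimens(cfg)
    o <- odds_ratio(allele_count_table(sp, "DDT")[, c("Ser", "Leu")])
    if (o$ci[1] <= target && target <= o$ci[2]) covered <- covered + 1
  }
  expect_gte(covered / reps, 0.90)
})
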