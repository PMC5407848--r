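---
title: "Methods: kdr genotyping and bioassay association analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kdr genotyping and bioassay association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdrkit)
```

## The problem

Indoor residual spraying against the visceral leishmaniasis vector
*Phlebotomus argentipes* relies on DDT and, increasingly, on synthetic
pyrethroids. Both insecticide classes share a target site, the *para*
voltage-gated sodium channel (Vgsc), and knockdown-resistance (*kdr*)
substitutions at Vgsc codon 1014 (house-fly numbering) are the classic
target-site mechanism for resistance to both. kdrkit implements the full
analysis chain for monitoring these mutations: genotype calling from
either Sanger amplicons or a pair of allele-discrimination assays,
genotype–phenotype association statistics from WHO tube bioassays,
evaluation of the genotype as a diagnostic marker, and per-site
population frequency monitoring with Hardy–Weinberg testing. A
synthetic-data generator reproduces the statistical structure of field
collections so that every stage is testable without field material.

## The allele and genotype model

Four codon-level alleles are modelled at codon 1014: wild-type leucine
(TTA), the L1014S serine replacement (TCA), and two distinct
phenylalanine replacements, TTT and TTC (L1014F). The residue map is a
pure function of codon; any other codon — including the alternative
leucine codon TTG, which has not been observed in this system — is
rejected with an explicit "allele not in model" error rather than being
silently classed, because a novel allele is a finding, not noise.

Ten unordered codon-level genotypes follow from the four alleles; after
pooling the two phenylalanine codons (their outcome distributions show
no detectable difference; `allele_homogeneity_test()` re-checks this on
any dataset and warns if pooling looks unsafe) six residue-level
genotypes remain. For association analysis genotypes are classified into
four dominance groups — `Leu/*` (any leucine allele), `Ser/Ser`,
`Ser/Phe`, `Phe/Phe` — under the working hypothesis that each kdr allele
alone is largely recessive while alternate kdr alleles in heterozygotes
act additively. The `Leu/*` group can be split into its residue
genotypes (`leu_split = TRUE`) because leucine-carrying genotypes are
not homogeneous for every insecticide: deltamethrin survival of Leu/Phe
heterozygotes is markedly higher than that of other leucine genotypes.

## Dual-assay call combination

Two allele-discrimination assays jointly type the locus: assay 1
distinguishes the second-position alleles (TTA vs TCA), assay 2 the
third-position alleles (TTC vs TTT). We model each probe as detecting
exactly one codon, with alleles outside an assay's probe pair giving no
signal on that assay. This exact-match model is the only one under which
all ten genotypes are unambiguously callable, and it makes the
combination rule a set union: one distinct detected codon across the two
assays is a homozygote, two are a heterozygote, zero is a no-call and
three or more an inconsistency. The probe→codon map is a plain
overridable table (`probe_model()`), not hard-wired logic.

Two consequences deserve emphasis. First, a genotype such as TTA/TTT
reads *homozygous* on both assays (homo-TTA, homo-TTT) — each assay sees
only the allele its probes match — and only the union resolves the
heterozygote. Second, and a genuine limitation: a technical dropout of
one assay is indistinguishable from probe silence. A TTA/TTT specimen
whose second assay fails reads (homo-TTA, null) and is called TTA/TTA
with a clean status. With a per-assay no-call rate of 2% roughly 2% of
specimens carrying alleles on both assays will be miscalled as
homozygotes; the analysis driver quantifies this, and genotype
frequencies estimated from assay data inherit it. Sequencing a subsample
remains the appropriate control.

## Amplicon calling

Amplicons of the Vgsc domain-IIS6 fragment are expected as single Sanger
consensus sequences with IUPAC ambiguity codes at heterozygous positions
(forward primer Vssc8F `AATGTGGGATTGCATGCTGG`, reverse Vssc1bR
`CGTATCATTGTCTGCAGTTGGT`). The shipped reference annotation is a
synthetic intron-free stand-in spanning codons 1001–1030 with wild-type
residues at the watched codons (1011 Ile, 1014 Leu, 1016 Val, 1020 Phe);
the annotation format accepts a user-supplied fragment, codon anchor and
one excluded (intron) interval, so a field-derived reference replaces it
without code change.

The 1014 codon is located by best ungapped placement of a ~30-nt
reference window centred on the codon (minimum identity 80%), not by
absolute offset, so small length differences between field amplicons do
not shift the frame. A tie between equally good placements is an error,
never an arbitrary pick. Orientation is decided by anchor fit on both
strands, making calls strand-invariant. Coordinates in reports are
0-based half-open; codon numbers follow the house-fly anchor map.

IUPAC expansion at the extracted codon follows diploid logic: a
three/four-way code cannot arise from two alleles and is unresolvable; a
single two-way position expands to the two alleles directly. A codon
with *two* two-way positions (TYM, TYW) admits two codon pairs whose
superposition matches the read; the call succeeds exactly when one of
those pairs consists entirely of modelled alleles. This is what makes
the TCA/TTC and TCA/TTT heterozygotes — which differ at two codon
positions — callable from a single Sanger trace at all; it is a
deliberate strengthening of a plain "reject multi-site ambiguity" rule,
without which two of the ten genotypes would be unreachable from
sequence data. The watched-codon screen (1011/1016/1020), which has no
restricted allele universe, keeps the conservative rule, and synonymous
ambiguity there still counts as wild type.

## Association statistics

All statistics act on outcome × category count tables built from a
specimen table (one row per bioassayed fly; survivors at 24 h are
"alive" = resistant/tolerant, the rest "dead" = susceptible; control and
ungenotyped records are excluded with logged counts).

- **Abbott correction** of assay-level mortality follows the standard
  tube-bioassay gating: control mortality < 5% — no correction; 5–20% —
  `100 (T − C)/(100 − C)`; above 20% — discard the assay. The thresholds
  are arguments, since the gating convention is a choice, not part of
  the formula.
- **Chi-square tests** are plain Pearson without continuity correction
  (`stats::chisq.test` under the hood), df = (R−1)(C−1). **Fisher exact
  tests** are two-sided by the sum-of-probabilities rule (the
  `stats::fisher.test` convention). The published analysis this package
  re-implements printed Fisher p-values whose two-sided convention is
  not documented, so fixture checks on those p-values use loose
  tolerance while the test machinery itself is verified against full
  hypergeometric enumeration for every 2×2 table up to n = 30.
- **Odds ratios** use the raw cross-product `(ad)/(bc)`, which exactly
  reproduces the reference values 9.35, 2.79 and 3.47; zero cells take
  the Haldane–Anscombe +0.5 on all cells and the result is tagged. CIs
  are Woolf logit intervals. A conditional-ML estimator would give
  slightly different values (e.g. 26.3 vs 26.05 for the DDT Phe-vs-Leu
  table) and is intentionally not the default; only cross-product values
  are asserted anywhere.
- **Proportion intervals** are Wilson score with continuity correction
  (Newcombe), chosen because they reproduce the published display
  intervals (74/83 → 80–95%) and respect [0, 1] where Wald-with-cc does
  not. The correction makes them conservative — empirical coverage runs
  at or slightly above nominal — which the recovery simulations treat as
  a feature, not an error.
- **Marascuilo–McSweeney pairwise comparisons** of K survival
  proportions use the critical range
  `sqrt(chisq(1−alpha, K−1)) * sqrt(v_ij)`; because the classical
  procedure yields only significance flags, a per-pair p-value is
  attached by referring the squared standardised difference to
  chi-square with K−1 df. K is whatever set of groups enters the
  comparison and is therefore explicit in the call. A pair with zero
  pooled variance but unequal proportions (both groups on the boundary)
  is flagged and handled with the maximal admissible variance rather
  than an infinite statistic.
- **Multiple testing** uses the Holm step-down ("sequential
  Bonferroni"); decisions are cross-checked against `p.adjust(method =
  "holm")` in the test suite.

## Diagnostics

The marker's positivity rule is "kdr-only genotype" — no leucine allele,
i.e. groups Ser/Ser, Ser/Phe, Phe/Phe — with survival as the positive
condition, so TP = alive & kdr-only, TN = dead & leucine-carrying.
Sensitivity TP/(TP+FN) and specificity TN/(TN+FP) are reported as
percentages with continuity-corrected intervals. Positive/negative
predictive values are computed per genotype group at the sample's own
prevalence (PPV = alive/n within the group); a Bayes prevalence-adjusted
variant exists but is off the main path, because bioassayed F1 samples
do not estimate field prevalence anyway. The positivity rule is a
parameter so stricter cut-points (e.g. Phe carriers only) can be
compared. Empty groups report NA, never zero.

## Population monitoring and Hardy–Weinberg testing

Allele frequencies per site are counted over 2n gene copies, genotype
groups over individuals; the pooling level (village / PHC / district) is
an explicit argument. Between-population comparison is a Pearson test on
the 2 × C count table (allele level uses gene-copy counts), dropping
categories absent from both samples with a df reduction and a note.

Hardy–Weinberg testing at a multi-allelic locus is done three ways: an
asymptotic chi-square (df = A(A−1)/2 over observed alleles), exact
enumeration of all genotype tables conditional on the observed allele
counts (the conditional probability `n! 2^H Πn_a! / ((2n)! Πn_ij!)`,
p-value summing tables no more probable than the observed), and a
Monte-Carlo version that permutes the 2n gametes and re-pairs them
(Guo–Thompson style), with mandatory seed, ≥10,000 default replicates
and a reported standard error. Exact enumeration is the default up to
n = 50 (it enumerates a few thousand tables for three alleles; expect
seconds, not milliseconds, near that bound), Monte-Carlo beyond. The
default system is the 3-allele residue level, matching the pooled
analysis; `level = "codon"` tests all four alleles. No installed package
provides the multi-allelic exact test, so the enumeration and
permutation kernels are implemented here and validated against each
other (agreement within Monte-Carlo error) and against calibration
simulations (type-I error ≈ 5% under gamete sampling).

## The synthetic generator

`simulate_specimens()` is the package's model of a field bioassay
campaign, and its defaults are the study conditions the analysis
assumes: genotypes drawn from Hardy–Weinberg-with-inbreeding
probabilities (`p_i² + F p_i(1−p_i)` homozygotes, `2 p_i p_j (1−F)`
heterozygotes) at per-site allele frequencies; bioassay outcome as a
Bernoulli draw of the genotype *group's* survival probability
(penetrance); controls dying at a genotype-independent control
mortality. Genotype-level penetrance is the generative primitive because
the inference downstream is about dominance groups; allele-dose models
are expressible through the map. The default penetrance is estimated
from the packaged fixture counts (e.g. DDT: Leu/* 9/71 ≈ 0.127 overall,
Ser/Ser 28/43 ≈ 0.651, Ser/Phe 33/39 ≈ 0.846, Phe/Phe 13/13 = 1), the
default tube size is 25 females (the realistic loading of a WHO tube
assay), and control mortality defaults to 0.02 — a typical value for
well-run tubes, supplied as a stand-in since control counts are not part
of the packaged fixture. The default site frequencies sketch a
high-resistance and a mixed district.

Amplicon emission substitutes the 1014 codon of the reference with the
position-wise IUPAC superposition of the genotype's alleles (Sanger
semantics — one consensus sequence, not read pairs); readout emission
inverts the probe model and injects independent per-assay no-calls. All
generators are deterministic given their seed; the amplicon simulator's
seed drives optional minus-strand emission used to exercise strand
handling.

What the generator does *not* emulate: base-calling noise or chromatogram
quality (sequences are error-free apart from the heterozygote codes),
linkage with other loci, assay cross-reactivity (probes are exact-match),
temporal change in allele frequencies, and density or handling effects on
bioassay mortality. Tests passing on synthetic data therefore validate
the statistical machinery and the calling logic, not robustness to dirty
traces or probe chemistry artefacts.

## The packaged fixture

The packaged specimen fixture deterministically expands published
genotype-by-outcome counts (with the leucine fine split) into
pseudo-specimens — 435 rows over three insecticides. Residue-level cells
are represented at codon level with phenylalanine written as TTT; this
convention is invisible after pooling, which every downstream statistic
applies, but it does mean the fixture cannot exercise the TTT-vs-TTC
homogeneity test (synthetic data covers that). Derived outputs of the
fixture reproduce the published allele tables, group tables, confusion
counts, chi-squares (75.2, 14.9, 62.6 on 3 df), sensitivities
(89.2/76.6/87.0%), specificities (74.7/58.1/86.9%) and cross-product
odds ratios (9.35, 2.79, 3.47) exactly at display precision; the
inter-district statistics of the source study depend on supplementary
per-PHC counts that are not reprinted in its main text, so the
population-comparison operations are validated by oracle and calibration
properties instead of printed values.

## Problem sizes and numerical conventions

The test suite and drivers run at desk scale: fixture statistics are
exact recomputations (seconds); the Fisher-vs-enumeration sweep covers
all margin-distinct 2×2 tables to n = 30; calibration uses 400–2,000
null tables; penetrance recovery uses 500 replicates of 500 trials per
group; Monte-Carlo HWE uses 5,000–10,000 permutations. Probability
comparisons in the exact/Monte-Carlo HWE tests use a relative tolerance
of 1e-9 when ranking table probabilities, protecting ties against
floating-point jitter. Genotypes serialise in alphabetical codon order
("TCA/TTA"), residue pairs in Leu < Ser < Phe order ("Leu/Phe"), groups
with the `Leu/*` header used in the published tables.

## Workflow layout

The package's computation lives entirely in `R/`; the numbered scripts
under `analysis/` are thin narrative drivers (table reproduction with
verification, genotype-calling concordance, simulation recovery, and
population monitoring) that print what they find and write their tables
under `results/`. They are the command-line surface of the package;
there is deliberately no separate CLI binary, since every driver is a
two-line `Rscript` over exported functions.

## Known limitations

- The reference annotation is a synthetic stand-in; true fragment
  length and intron structure of the field amplicon should be supplied
  by the user when available.
- Assay-dropout homozygote miscalls (above) are undetectable from
  readouts alone.
- Predictive values at sample prevalence do not transfer to field
  populations with different resistance frequencies; use the adjusted
  variant with an external prevalence estimate.
- The Marascuilo per-pair p-value shares the conservative K−1-df
  reference of the familywise procedure; it is a reporting convenience,
  not an exact pairwise test.
- No dose–response modelling: the bioassays are fixed-dose, fixed-time
  by design.
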