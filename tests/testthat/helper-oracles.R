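# Independent brute-force oracles used across the suite.

# Two-sided Fisher p by complete hypergeometric enumeration: sum of the
# point probabilities of every table (with the observed margins) whose
# probability does not exceed the observed table's.
fisher_enum_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  r <- a + b
  k <- a + c
  if (n == 0) return(1)
  xs <- max(0, k - (c + d)):min(r, k)
  px <- stats::dhyper(xs, r, n - r, k)
  po <- stats::dhyper(a, r, n - r, k)
  min(1, sum(px[px <= po * (1 + 1e-7)]))
}

# Pearson statistic by the double loop over observed/expected cells.
pearson_oracle <- function(tab) {
  n <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  unname(stat)
}

# Brute sliding-window Hamming scan (exact bases only): 0-based start
# positions at <= max_mismatch mismatches.
hamming_scan_oracle <- function(subject, pattern, max_mismatch) {
  s <- strsplit(subject, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  hits <- integer(0)
  for (off in 0:(length(s) - length(p))) {
    mm <- sum(s[off + seq_along(p)] != p)
    if (mm <= max_mismatch) hits <- c(hits, off)
  }
  hits
}

# Draw n genotypes from Hardy-Weinberg proportions at given codon-allele
# frequencies (gamete sampling, so exactly HWE in expectation).
draw_hwe_genotypes <- function(freqs, n) {
  a <- sample(names(freqs), 2 * n, replace = TRUE, prob = freqs)
  kdr_genotype(a[seq_len(n)], a[n + seq_len(n)])
}

# Printed outcome x allele counts (Table-1-style rows, Leu/Ser/Phe).
printed_allele_counts <- function() {
  list(
    DDT = rbind(alive = c(Leu = 12, Ser = 93, Phe = 61),
                dead = c(Leu = 82, Ser = 68, Phe = 16)),
    deltamethrin = rbind(alive = c(Leu = 11, Ser = 40, Phe = 43),
                         dead = c(Leu = 42, Ser = 44, Phe = 38)),
    `alpha-cypermethrin` = rbind(alive = c(Leu = 3, Ser = 34, Phe = 9),
                                 dead = c(Leu = 176, Ser = 83, Phe = 15))
  )
}

# Printed outcome x genotype-group counts (Table-2-style rows).
printed_group_counts <- function() {
  g <- genotype_group_levels()
  list(
    DDT = rbind(alive = stats::setNames(c(9, 28, 33, 13), g),
                dead = stats::setNames(c(62, 15, 6, 0), g)),
    deltamethrin = rbind(alive = stats::setNames(c(11, 11, 18, 7), g),
                         dead = stats::setNames(c(36, 8, 16, 2), g)),
    `alpha-cypermethrin` = rbind(alive = stats::setNames(c(3, 13, 5, 2), g),
                                 dead = stats::setNames(c(119, 15, 2, 1), g))
  )
}
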