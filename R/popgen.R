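# Per-site allele/genotype frequency summaries, multi-allelic
# Hardy-Weinberg testing and between-population differentiation at the
# codon-1014 locus.

#' Genotype counts per site
#'
#' Tabulates genotypes by a site column of the specimen table (pooling
#' level explicit: village, PHC or district).
#'
#' @param specimens Specimen data frame with a genotype column.
#' @param by Site column name ("district", "phc" or "village").
#' @param level "residue" (6 genotype classes) or "codon" (10).
#' @return Integer matrix: one row per site, one column per genotype.
#' @export
site_genotype_counts <- function(specimens, by = "district",
                                 level = c("residue", "codon")) {
  level <- match.arg(level)
  stopifnot(by %in% names(specimens), "genotype" %in% names(specimens))
  x <- specimens[!is.na(specimens$genotype) & specimens$genotype != "", ]
  g <- if (level == "residue") genotype_residues(x$genotype) else x$genotype
  lev <- if (level == "residue") all_residue_genotypes() else all_kdr_genotypes()
  as.matrix(table(factor(x[[by]]), factor(g, levels = lev)))
}

#' Allele and genotype-group frequencies for one site sample
#'
#' Allele frequencies are computed from genotype counts over 2n gene
#' copies; genotype-group frequencies over the n individuals. Each
#' frequency carries a continuity-corrected Wilson interval.
#'
#' @param genotypes Character vector of genotypes for the site's
#'   individuals.
#' @param conf_level Confidence level for interval estimates.
#' @return List with `n`, `alleles` and `groups` data frames (frequency,
#'   lower, upper per class).
#' @export
site_frequencies <- function(genotypes, conf_level = 0.95) {
  n <- length(genotypes)
  if (n == 0) stop("empty site sample")
  ac <- count_alleles(genotypes, level = "residue")
  alleles <- do.call(rbind, lapply(names(ac), function(a) {
    ci <- survival_proportion_ci(ac[[a]], 2 * n, conf_level)
    data.frame(allele = a, count = ac[[a]], frequency = ci$estimate,
               lower = ci$lower, upper = ci$upper)
  }))
  gc <- table(genotype_group(genotypes))
  groups <- do.call(rbind, lapply(names(gc), function(g) {
    ci <- survival_proportion_ci(gc[[g]], n, conf_level)
    data.frame(group = g, count = gc[[g]], frequency = ci$estimate,
               lower = ci$lower, upper = ci$upper)
  }))
  rownames(alleles) <- rownames(groups) <- NULL
  list(n = n, alleles = alleles, groups = groups)
}

#' Chi-square comparison of two population samples
#'
#' Compares allele frequencies (counts over 2n gene copies per site;
#' 2 x 3 table for the residue-level system) or genotype-group
#' frequencies (individual counts, 2 x 4) between two samples. Categories
#' absent from both samples are dropped with a note, reducing the degrees
#' of freedom.
#'
#' @param genotypes_a,genotypes_b Genotype vectors for the two samples.
#' @param level "allele" or "group".
#' @return List: statistic, df, p_value, method, dropped (character
#'   vector of dropped categories).
#' @export
compare_populations <- function(genotypes_a, genotypes_b,
                                level = c("allele", "group")) {
  level <- match.arg(level)
  stopifnot(length(genotypes_a) > 0, length(genotypes_b) > 0)
  count_one <- function(g) {
    if (level == "allele") as.vector(count_alleles(g, level = "residue"))
    else as.vector(table(genotype_group(g)))
  }
  lev <- if (level == "allele") RESIDUE_ORDER else genotype_group_levels()
  tab <- rbind(a = count_one(genotypes_a), b = count_one(genotypes_b))
  colnames(tab) <- lev
  empty <- colSums(tab) == 0
  dropped <- colnames(tab)[empty]
  if (length(dropped)) {
    message("dropping categories absent from both samples: ",
            paste(dropped, collapse = ", "))
  }
  tab <- tab[, !empty, drop = FALSE]
  res <- chi_square_rxc(tab)
  res$method <- paste0("pearson_chi_square_", level)
  res$dropped <- dropped
  res
}

# --- Hardy-Weinberg ----------------------------------------------------

# Genotype counts as a named vector keyed "A/B" (canonical order of the
# allele names supplied) -> symmetric count matrix.
genotype_count_matrix <- function(genotypes, level = c("residue", "codon")) {
  level <- match.arg(level)
  al <- if (level == "residue") RESIDUE_ORDER else kdr_alleles()
  g <- matrix(genotype_alleles(genotypes), nrow = 2)
  x1 <- if (level == "residue") kdr_residue(g[1, ]) else g[1, ]
  x2 <- if (level == "residue") kdr_residue(g[2, ]) else g[2, ]
  m <- matrix(0L, length(al), length(al), dimnames = list(al, al))
  for (i in seq_along(x1)) {
    a <- x1[i]; b <- x2[i]
    if (match(a, al) > match(b, al)) { tmp <- a; a <- b; b <- tmp }
    m[a, b] <- m[a, b] + 1L
  }
  m
}

# log conditional probability of a genotype count table given its allele
# counts under HWE (multi-allelic exact-test kernel):
# P = n! 2^H prod(n_a!) / ((2n)! prod(n_ij!)), H = #heterozygotes.
hwe_log_prob <- function(m) {
  n <- sum(m)
  counts <- m[upper.tri(m, diag = TRUE)]
  het <- sum(m[upper.tri(m)])
  allele_counts <- hwe_allele_counts(m)
  lfactorial(n) + het * log(2) + sum(lfactorial(allele_counts)) -
    lfactorial(2 * n) - sum(lfactorial(counts))
}

# allele counts from an upper-triangular genotype count matrix: each
# homozygote cell contributes 2 copies (it appears in both the row and
# the column sum), each heterozygote one copy to each allele
hwe_allele_counts <- function(m) rowSums(m) + colSums(m)

# Enumerate all genotype count tables with the given allele counts,
# applying f(log_prob) to each. Recursive over the upper triangle.
hwe_enumerate <- function(allele_counts, f) {
  k <- length(allele_counts)
  idx <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  m <- matrix(0L, k, k)
  recurse <- function(cell, remaining) {
    if (cell > nrow(idx)) {
      if (all(remaining == 0)) f(m)
      return(invisible(NULL))
    }
    i <- idx[cell, 1]; j <- idx[cell, 2]
    # max copies this cell can take from the remaining allele budget
    cap <- if (i == j) remaining[i] %/% 2 else min(remaining[i], remaining[j])
    for (cnt in 0:cap) {
      m[i, j] <<- cnt
      rem <- remaining
      if (i == j) rem[i] <- rem[i] - 2L * cnt
      else { rem[i] <- rem[i] - cnt; rem[j] <- rem[j] - cnt }
      recurse(cell + 1L, rem)
    }
    m[i, j] <<- 0L
  }
  recurse(1L, allele_counts)
}

#' Multi-allelic Hardy-Weinberg test
#'
#' Tests genotype counts against Hardy-Weinberg proportions at the
#' codon-1014 locus (residue-level 3-allele system by default, matching
#' the analysis pooling; codon-level 4-allele via `level`). Three methods:
#' asymptotic chi-square (expected counts from allele frequencies, df =
#' A(A-1)/2), exact enumeration of all genotype tables conditional on the
#' allele counts (default for n <= 50), and a Monte-Carlo permutation of
#' the 2n gametes (Guo-Thompson style) otherwise. The exact and
#' Monte-Carlo p-values sum/count tables whose conditional probability
#' does not exceed the observed table's.
#'
#' @param genotypes Character vector of genotypes (one per individual), or
#'   a symmetric genotype count matrix as from internal counting.
#' @param method "auto", "chi-square", "exact" or "monte-carlo".
#' @param level "residue" or "codon".
#' @param reps Monte-Carlo replicates.
#' @param seed Seed for the Monte-Carlo method (required there for
#'   reproducibility).
#' @return List of class `kdr_hwe`: observed and expected counts,
#'   statistic/df (chi-square method), p_value, method, and for
#'   Monte-Carlo the replicate count, seed and standard error.
#' @export
hwe_test <- function(genotypes, method = c("auto", "chi-square", "exact", "monte-carlo"),
                     level = c("residue", "codon"), reps = 10000L, seed = NULL) {
  method <- match.arg(method)
  level <- match.arg(level)
  m <- if (is.matrix(genotypes)) genotypes else genotype_count_matrix(genotypes, level)
  n <- sum(m)
  if (n == 0) stop("empty sample")
  ac <- hwe_allele_counts(m)
  observed_alleles <- sum(ac > 0)
  p <- ac / (2 * n)
  # expected counts under HWE, upper-triangular storage
  expected <- 2 * n * outer(p, p)
  diag(expected) <- n * p^2
  expected[lower.tri(expected)] <- 0
  out <- list(observed = m, expected = expected, level = level,
              allele_freq = p, n = n)
  if (observed_alleles < 2) {
    out$p_value <- 1
    out$method <- "monomorphic"
    class(out) <- "kdr_hwe"
    return(out)
  }
  if (method == "auto") method <- if (n <= 50) "exact" else "monte-carlo"
  if (method == "chi-square") {
    A <- observed_alleles  # df counts only alleles actually present
    keep <- expected > 0
    stat <- sum((m[keep] - expected[keep])^2 / expected[keep])
    df <- A * (A - 1) / 2
    out$statistic <- stat
    out$df <- df
    out$p_value <- stats::pchisq(stat, df, lower.tail = FALSE)
    if (n < 5) out$note <- "n < 5: chi-square approximation unreliable"
    out$method <- "chi-square"
  } else if (method == "exact") {
    lp_obs <- hwe_log_prob(m)
    acc <- new.env(); acc$p <- 0
    hwe_enumerate(ac, function(tab) {
      lp <- hwe_log_prob(tab)
      if (lp <= lp_obs + 1e-9) acc$p <- acc$p + exp(lp)
    })
    out$p_value <- min(1, acc$p)
    out$method <- "exact-enumeration"
  } else {
    if (is.null(seed)) stop("Monte-Carlo method requires a seed")
    set.seed(seed)
    gametes <- rep(seq_along(ac), ac)
    lp_obs <- hwe_log_prob(m)
    k <- length(ac)
    hits <- 0L
    for (b in seq_len(reps)) {
      perm <- sample(gametes)
      i <- perm[seq(1, length(perm), by = 2)]
      j <- perm[seq(2, length(perm), by = 2)]
      lo <- pmin(i, j); hi <- pmax(i, j)
      tab <- matrix(0L, k, k)
      for (t in seq_along(lo)) tab[lo[t], hi[t]] <- tab[lo[t], hi[t]] + 1L
      if (hwe_log_prob(tab) <= lp_obs + 1e-9) hits <- hits + 1L
    }
    out$p_value <- hits / reps
    out$mc_se <- sqrt(out$p_value * (1 - out$p_value) / reps)
    out$reps <- reps
    out$seed <- seed
    out$method <- "monte-carlo"
  }
  class(out) <- "kdr_hwe"
  out
}

#' @export
print.kdr_hwe <- function(x, ...) {
  cat("Hardy-Weinberg test (", x$level, " level, n = ", x$n, ")\n", sep = "")
  cat("  method:", x$method, " p =", format(x$p_value, digits = 4), "\n")
  if (!is.null(x$statistic)) {
    cat("  chi-square =", round(x$statistic, 3), "df =", x$df, "\n")
  }
  if (!is.null(x$mc_se)) {
    cat("  MC replicates =", x$reps, "seed =", x$seed,
        "SE =", format(x$mc_se, digits = 3), "\n")
  }
  invisible(x)
}
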