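# Bioassay association statistics: outcome x allele / genotype-group
# contingency tables and the tests applied to them.

OUTCOME_LEVELS <- c("alive", "dead")

# Validate and subset a specimen table for association analysis: test-role
# genotyped specimens for one insecticide. Exclusions are counted and
# attached as an attribute so drivers can log them.
association_subset <- function(specimens, insecticide) {
  stopifnot(is.data.frame(specimens),
            all(c("insecticide", "outcome", "genotype") %in% names(specimens)))
  x <- specimens[specimens$insecticide == insecticide, , drop = FALSE]
  n0 <- nrow(x)
  if ("role" %in% names(x)) x <- x[x$role == "test", , drop = FALSE]
  n_control <- n0 - nrow(x)
  keep <- !is.na(x$genotype) & x$genotype != ""
  n_ungenotyped <- sum(!keep)
  x <- x[keep, , drop = FALSE]
  stopifnot(all(x$outcome %in% OUTCOME_LEVELS))
  attr(x, "excluded") <- c(control = n_control, ungenotyped = n_ungenotyped)
  x
}

#' Abbott correction of bioassay mortality
#'
#' Corrects test mortality for control mortality following the standard
#' tube-bioassay convention: control mortality below 5% leaves the test
#' mortality unchanged; between 5% and 20% the correction
#' 100 (T - C) / (100 - C) is applied; above 20% the assay is discarded.
#'
#' @param test_mortality_pct,control_mortality_pct Percentages in 0-100.
#' @param no_correction_below,discard_above Gating thresholds (%).
#' @return List: `mortality_pct` (corrected or unchanged; NA when the
#'   assay is discarded), `verdict` ("uncorrected", "corrected",
#'   "discard").
#' @examples
#' abbott_correction(50, 20)  # 37.5, corrected
#' @export
abbott_correction <- function(test_mortality_pct, control_mortality_pct,
                              no_correction_below = 5, discard_above = 20) {
  t <- test_mortality_pct; c <- control_mortality_pct
  stopifnot(t >= 0, t <= 100, c >= 0, c <= 100)
  if (c > discard_above) {
    return(list(mortality_pct = NA_real_, verdict = "discard"))
  }
  if (c < no_correction_below) {
    return(list(mortality_pct = t, verdict = "uncorrected"))
  }
  if (c >= 100) stop("control mortality of 100% leaves the correction undefined")
  list(mortality_pct = 100 * (t - c) / (100 - c), verdict = "corrected")
}

#' Outcome x allele contingency table
#'
#' Counts alleles carried by surviving and dead specimens for one
#' insecticide; each genotyped individual contributes two allele counts,
#' with the phenylalanine codons TTT and TTC pooled to Phe.
#'
#' @param specimens Specimen data frame (columns insecticide, outcome,
#'   genotype; optional role).
#' @param insecticide Insecticide to tabulate.
#' @return Integer matrix, rows alive/dead, columns Leu/Ser/Phe, with an
#'   `excluded` attribute counting dropped records.
#' @export
allele_count_table <- function(specimens, insecticide) {
  x <- association_subset(specimens, insecticide)
  tab <- vapply(OUTCOME_LEVELS, function(o) {
    g <- x$genotype[x$outcome == o]
    if (!length(g)) return(stats::setNames(integer(3), RESIDUE_ORDER))
    as.vector(count_alleles(g, level = "residue"))
  }, integer(3))
  out <- t(tab)
  dimnames(out) <- list(OUTCOME_LEVELS, RESIDUE_ORDER)
  attr(out, "excluded") <- attr(x, "excluded")
  out
}

#' Outcome x genotype-group contingency table
#'
#' @param specimens Specimen data frame.
#' @param insecticide Insecticide to tabulate.
#' @param leu_split If TRUE the Leu/* group is split into Leu/Leu,
#'   Leu/Ser and Leu/Phe.
#' @return Integer matrix, rows alive/dead, columns the genotype groups.
#' @export
genotype_group_table <- function(specimens, insecticide, leu_split = FALSE) {
  x <- association_subset(specimens, insecticide)
  lev <- genotype_group_levels(fine = leu_split)
  tab <- vapply(OUTCOME_LEVELS, function(o) {
    g <- x$genotype[x$outcome == o]
    if (!length(g)) return(stats::setNames(integer(length(lev)), lev))
    table(genotype_group(g, fine = leu_split))
  }, integer(length(lev)))
  out <- t(tab)
  dimnames(out) <- list(OUTCOME_LEVELS, lev)
  attr(out, "excluded") <- attr(x, "excluded")
  out
}

#' Pearson chi-square test on an R x C count table
#'
#' Pearson statistic without continuity correction, df = (R-1)(C-1),
#' upper-tail p-value. A zero row or column margin is an error naming the
#' degenerate level.
#'
#' @param table Count matrix (at least 2 x 2).
#' @return List: statistic, df, p_value, method.
#' @export
chi_square_rxc <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) >= 2, ncol(table) >= 2, all(table >= 0))
  rz <- rowSums(table) == 0; cz <- colSums(table) == 0
  if (any(rz) || any(cz)) {
    stop("zero margin for level(s): ",
         paste(c(rownames(table)[rz], colnames(table)[cz]), collapse = ", "))
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, method = "pearson_chi_square")
}

#' Fisher exact test on a 2 x 2 table
#'
#' Two-sided p-value by the sum-of-probabilities rule: all hypergeometric
#' outcomes with point probability not exceeding the observed table's are
#' summed.
#'
#' @param table 2 x 2 count matrix.
#' @return List: p_value, odds-ratio estimate is deliberately not included
#'   (see [odds_ratio()] for the cross-product estimator), df is NA,
#'   method tag.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0))
  ft <- stats::fisher.test(table)
  list(statistic = NA_real_, df = NA_integer_, p_value = ft$p.value,
       method = "fisher_exact_two_sided")
}

#' Cross-product odds ratio with Woolf confidence interval
#'
#' OR = (ad)/(bc) for a 2 x 2 table rbind(c(a, b), c(c, d)). When any cell
#' is zero, the Haldane-Anscombe correction adds 0.5 to every cell (the
#' estimator is tagged accordingly). The 95% CI is the Woolf logit
#' interval on the (corrected) cells.
#'
#' @param table 2 x 2 count matrix; rows are outcomes, columns the two
#'   compared categories; the OR is the odds of row 1 in column 1 relative
#'   to column 2.
#' @param conf_level Confidence level.
#' @return List: or, ci (length 2), estimator
#'   ("cross-product" or "cross-product-haldane"), conf_level.
#' @examples
#' odds_ratio(rbind(c(93, 12), c(68, 82)))  # Ser vs Leu survival, 9.35
#' @export
odds_ratio <- function(table, conf_level = 0.95) {
  m <- as.matrix(table)
  stopifnot(identical(dim(m), c(2L, 2L)), all(m >= 0))
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  # two zeros sharing a row or column leave the OR undefined even after
  # correction
  if ((a == 0 && b == 0) || (c == 0 && d == 0) ||
      (a == 0 && c == 0) || (b == 0 && d == 0)) {
    stop("odds ratio undefined: a full row or column of zeros")
  }
  estimator <- "cross-product"
  if (any(m == 0)) {
    m <- m + 0.5
    a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
    estimator <- "cross-product-haldane"
  }
  or <- (a * d) / (b * c)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ci <- exp(log(or) + c(-1, 1) * z * se)
  list(or = or, ci = ci, estimator = estimator, conf_level = conf_level)
}

#' Survival proportion with continuity-corrected Wilson interval
#'
#' Point estimate k/n with the Newcombe continuity-corrected Wilson score
#' interval, clipped to `[0, 1]`; k = 0 forces the lower limit to 0 and
#' k = n the upper limit to 1.
#'
#' @param k Number alive (successes).
#' @param n Group size.
#' @param conf_level Confidence level.
#' @return List: k, n, estimate, lower, upper, conf_level.
#' @examples
#' survival_proportion_ci(28, 43)  # Ser/Ser on DDT, ~0.65
#' @export
survival_proportion_ci <- function(k, n, conf_level = 0.95) {
  stopifnot(length(k) == 1, length(n) == 1, n >= 1, k >= 0, k <= n)
  p <- k / n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lower <- if (k == 0) 0 else {
    (2 * n * p + z^2 - 1 -
       z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) / (2 * (n + z^2))
  }
  upper <- if (k == n) 1 else {
    (2 * n * p + z^2 + 1 +
       z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) / (2 * (n + z^2))
  }
  list(k = k, n = n, estimate = p,
       lower = max(0, lower), upper = min(1, upper), conf_level = conf_level)
}

#' Marascuilo-McSweeney pairwise comparison of proportions
#'
#' For K groups with survival proportions p-hat_i = k_i / n_i, each pair
#' (i, j) is compared through the absolute difference against the critical
#' range sqrt(chisq(1 - alpha, K - 1)) * sqrt(p_i(1-p_i)/n_i +
#' p_j(1-p_j)/n_j). A per-pair p-value is attached by referring the
#' squared standardised difference to the chi-square distribution with
#' K - 1 degrees of freedom.
#'
#' @param k,n Integer vectors: successes and sizes per group (named
#'   vectors label the output).
#' @param alpha Familywise significance level.
#' @return Data frame, one row per pair: groups, proportions, difference,
#'   critical range, significant flag, p_value, and a boundary flag for
#'   pairs whose pooled variance term is zero.
#' @export
marascuilo_pairwise <- function(k, n, alpha = 0.05) {
  stopifnot(length(k) == length(n), length(k) >= 2, all(n >= 1),
            all(k >= 0), all(k <= n))
  K <- length(k)
  labs <- if (!is.null(names(k))) names(k) else paste0("group", seq_len(K))
  p <- k / n
  crit_chi <- stats::qchisq(1 - alpha, df = K - 1)
  pairs <- utils::combn(K, 2)
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    v <- p[i] * (1 - p[i]) / n[i] + p[j] * (1 - p[j]) / n[j]
    diff <- abs(p[i] - p[j])
    boundary <- v == 0 && diff > 0
    if (boundary) {
      # degenerate pair (both proportions on the boundary but unequal):
      # fall back on the larger admissible variance so the comparison is
      # conservative rather than infinite
      v <- 0.25 / n[i] + 0.25 / n[j]
    }
    if (v == 0) {
      crit <- 0; z2 <- 0; pval <- 1
    } else {
      crit <- sqrt(crit_chi) * sqrt(v)
      z2 <- diff^2 / v
      pval <- stats::pchisq(z2, df = K - 1, lower.tail = FALSE)
    }
    data.frame(group_i = labs[i], group_j = labs[j],
               p_i = p[i], p_j = p[j], difference = diff,
               critical_range = crit,
               significant = diff > crit & v > 0,
               p_value = pval, boundary = boundary,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "k_groups") <- K
  attr(out, "alpha") <- alpha
  out
}

#' Holm sequential Bonferroni decisions
#'
#' Step-down procedure: p-values sorted ascending are compared against
#' alpha / (m - i + 1); the first failure retains that and every larger
#' p-value, so decisions are monotone.
#'
#' @param pvalues Numeric vector of p-values.
#' @param alpha Familywise level.
#' @return Data frame in the input order: p_value, threshold (the
#'   step-down comparison level each p faced), reject.
#' @export
sequential_bonferroni <- function(pvalues, alpha = 0.05) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  m <- length(pvalues)
  if (m == 0L) {
    return(data.frame(p_value = numeric(0), threshold = numeric(0),
                      reject = logical(0)))
  }
  ord <- order(pvalues)
  thr_sorted <- alpha / (m - seq_len(m) + 1)
  rej_sorted <- logical(m)
  for (i in seq_len(m)) {
    if (pvalues[ord[i]] <= thr_sorted[i]) rej_sorted[i] <- TRUE else break
  }
  out <- data.frame(p_value = pvalues, threshold = NA_real_, reject = NA)
  out$threshold[ord] <- thr_sorted
  out$reject[ord] <- rej_sorted
  out
}

#' Test homogeneity of the two phenylalanine codons
#'
#' Fisher exact test of outcome against codon (TTC vs TTT carrier counts)
#' per insecticide, justifying (or warning against) pooling the two
#' L1014F codons. Alleles are counted per individual (two per homozygote).
#'
#' @param specimens Specimen data frame.
#' @param insecticides Insecticides to test (default: all present).
#' @return List: per-insecticide data frame (counts and p-values),
#'   minimum p, and a `pooling_warning` flag (TRUE when any p < 0.05).
#' @export
allele_homogeneity_test <- function(specimens,
                                    insecticides = unique(specimens$insecticide)) {
  rows <- lapply(insecticides, function(ins) {
    x <- association_subset(specimens, ins)
    counts <- vapply(OUTCOME_LEVELS, function(o) {
      g <- x$genotype[x$outcome == o]
      if (!length(g)) return(c(TTT = 0L, TTC = 0L))
      ct <- count_alleles(g, level = "codon")
      c(TTT = unname(ct["TTT"]), TTC = unname(ct["TTC"]))
    }, integer(2))
    tab <- t(counts)  # alive/dead x TTT/TTC
    p <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      fisher_exact_2x2(tab)$p_value
    } else NA_real_  # a codon absent entirely: no homogeneity question
    data.frame(insecticide = ins,
               alive_TTT = tab["alive", "TTT"], alive_TTC = tab["alive", "TTC"],
               dead_TTT = tab["dead", "TTT"], dead_TTC = tab["dead", "TTC"],
               p_value = p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  pmin_ <- suppressWarnings(min(tab$p_value, na.rm = TRUE))
  if (!is.finite(pmin_)) pmin_ <- NA_real_
  warn <- isTRUE(any(tab$p_value < 0.05, na.rm = TRUE))
  if (warn) warning("phenylalanine codons differ in outcome association; pooling TTT/TTC may be unsafe")
  list(per_insecticide = tab, min_p = pmin_, pooling_warning = warn)
}
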