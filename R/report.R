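# Specimen-table IO and per-insecticide report bundles mirroring the
# association and diagnostic table layouts.

SPECIMEN_COLUMNS <- c("id", "district", "phc", "village", "insecticide",
                      "exposure_minutes", "outcome", "role", "cohort",
                      "genotype")

#' Read a delimited specimen table
#'
#' Expects a UTF-8 header with at least id, insecticide, outcome and
#' genotype; the full documented schema also carries district, phc,
#' village, exposure_minutes, role and cohort. Genotypes are canonical
#' "TTA/TCA" strings (empty string or NA = not genotyped).
#'
#' @param path File path (comma- or tab-delimited by extension).
#' @return Specimen data frame.
#' @export
read_specimen_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("id", "insecticide", "outcome", "genotype")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("specimen table lacks column(s): ",
                         paste(miss, collapse = ", "))
  ok <- is.na(x$genotype) | x$genotype == ""
  if (!all(ok)) genotype_alleles(x$genotype[!ok])  # validate
  x
}

#' Write a specimen table
#' @param specimens Specimen data frame.
#' @param path Output path (.csv or .tsv).
#' @export
write_specimen_table <- function(specimens, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(specimens, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
}

# allele-level OR from an outcome x allele count table: odds of survival
# for allele a relative to allele b
allele_odds_ratio <- function(allele_table, a, b, conf_level = 0.95) {
  odds_ratio(allele_table[c("alive", "dead"), c(a, b)], conf_level)
}

#' Association report bundle for one insecticide
#'
#' Reproduces the full association analysis for one insecticide from a
#' specimen table: the outcome x allele and outcome x genotype-group
#' tables with relative percentages, the three pairwise allele odds
#' ratios with Fisher p-values, the group chi-square, per-group survival
#' proportions with continuity-corrected intervals, and the
#' Marascuilo-McSweeney pairwise comparisons over the fine-split groups.
#'
#' @param specimens Specimen data frame.
#' @param insecticide Insecticide.
#' @param alpha Significance level for the pairwise comparisons.
#' @param conf_level Confidence level for interval estimates.
#' @return List of class `kdr_association_report`; `config` embeds the
#'   effective settings so reruns are auditable.
#' @export
association_report <- function(specimens, insecticide, alpha = 0.05,
                               conf_level = 0.95) {
  at <- allele_count_table(specimens, insecticide)
  gt <- genotype_group_table(specimens, insecticide)
  gt_fine <- genotype_group_table(specimens, insecticide, leu_split = TRUE)
  pairs <- list(ser_vs_leu = c("Ser", "Leu"),
                phe_vs_leu = c("Phe", "Leu"),
                phe_vs_ser = c("Phe", "Ser"))
  ors <- lapply(pairs, function(p) {
    tab <- at[, p]
    c(allele_odds_ratio(at, p[1], p[2], conf_level),
      list(fisher_p = fisher_exact_2x2(tab)$p_value))
  })
  survival <- lapply(colnames(gt), function(g) {
    survival_proportion_ci(gt["alive", g], sum(gt[, g]), conf_level)
  })
  names(survival) <- colnames(gt)
  mar <- marascuilo_pairwise(gt_fine["alive", ], colSums(gt_fine), alpha)
  out <- list(
    insecticide = insecticide,
    allele_table = at,
    group_table = gt,
    group_table_fine = gt_fine,
    allele_pct = round(100 * prop.table(at, 1), 1),
    group_pct = round(100 * prop.table(gt, 1), 1),
    odds_ratios = ors,
    group_chisq = chi_square_rxc(gt),
    survival = survival,
    marascuilo = mar,
    excluded = attr(at, "excluded"),
    config = list(alpha = alpha, conf_level = conf_level,
                  or_estimator = "cross-product (Haldane +0.5 on zero cells)",
                  ci_method = "Wilson, continuity-corrected",
                  package_version = as.character(utils::packageVersion("kdrkit")))
  )
  class(out) <- "kdr_association_report"
  out
}

#' @export
print.kdr_association_report <- function(x, ...) {
  strip <- function(m) matrix(m, nrow(m), dimnames = dimnames(m))
  cat("kdr association report --", x$insecticide, "\n\nAllele counts:\n")
  print(strip(x$allele_table))
  cat("\nGenotype-group counts:\n")
  print(strip(x$group_table))
  cat(sprintf("\nGroup chi-square: %.1f (df %d), P = %.2g\n",
              x$group_chisq$statistic, x$group_chisq$df, x$group_chisq$p_value))
  for (nm in names(x$odds_ratios)) {
    o <- x$odds_ratios[[nm]]
    cat(sprintf("  OR %s = %.2f (%.2f-%.2f), Fisher P = %.2g\n",
                nm, o$or, o$ci[1], o$ci[2], o$fisher_p))
  }
  cat("\nSurvival proportions:\n")
  for (g in names(x$survival)) {
    s <- x$survival[[g]]
    cat(sprintf("  %-8s %d/%d = %.2f (%.2f-%.2f)\n", g, s$k, s$n,
                s$estimate, s$lower, s$upper))
  }
  invisible(x)
}

#' Verify recomputed headline values against the printed display values
#'
#' Recomputes the group chi-squares, confusion counts, sensitivities,
#' specificities and the three cross-product odds ratios from a specimen
#' table and compares each, after display rounding, with the packaged
#' printed value.
#'
#' @param specimens Specimen data frame (default: the packaged fixture).
#' @return Data frame: metric, insecticide, printed, computed (rounded to
#'   the printed precision), pass.
#' @export
verify_printed_values <- function(specimens = bioassay_fixture()) {
  pv <- printed_values()
  computed <- mapply(function(metric, ins) {
    switch(metric,
      group_chisq = chi_square_rxc(genotype_group_table(specimens, ins))$statistic,
      sensitivity_pct = sensitivity_specificity(
        confusion_counts(specimens, ins))$sensitivity$percent,
      specificity_pct = sensitivity_specificity(
        confusion_counts(specimens, ins))$specificity$percent,
      tp = confusion_counts(specimens, ins)$tp,
      fp = confusion_counts(specimens, ins)$fp,
      tn = confusion_counts(specimens, ins)$tn,
      fn = confusion_counts(specimens, ins)$fn,
      or_ser_vs_leu = allele_odds_ratio(
        allele_count_table(specimens, ins), "Ser", "Leu")$or,
      or_phe_vs_ser = allele_odds_ratio(
        allele_count_table(specimens, ins), "Phe", "Ser")$or,
      stop("unknown metric: ", metric))
  }, pv$metric, pv$insecticide)
  rounded <- round(computed, pv$digits)
  data.frame(metric = pv$metric, insecticide = pv$insecticide,
             printed = pv$value, computed = rounded,
             pass = rounded == pv$value, row.names = NULL)
}
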