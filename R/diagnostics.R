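# Evaluation of the codon-1014 genotype as a diagnostic marker for
# resistance (DDT) / tolerance (pyrethroids): confusion counts,
# sensitivity/specificity, and per-group predictive values.

#' Confusion counts for the kdr diagnostic
#'
#' Positive test = kdr-only genotype (no leucine allele, i.e. groups
#' Ser/Ser, Ser/Phe, Phe/Phe); positive condition = alive after the
#' bioassay. So TP = alive & kdr-only, FP = dead & kdr-only, TN = dead &
#' leucine-carrying, FN = alive & leucine-carrying. The positivity rule is
#' a parameter so alternative cut-points (e.g. only Phe carriers) can be
#' assessed.
#'
#' @param specimens Specimen data frame.
#' @param insecticide Insecticide to evaluate.
#' @param positive_groups Genotype groups counted as test-positive.
#' @return List: tp, fp, tn, fn, n (their sum).
#' @export
confusion_counts <- function(specimens, insecticide,
                             positive_groups = c("Ser/Ser", "Ser/Phe", "Phe/Phe")) {
  tab <- genotype_group_table(specimens, insecticide)
  stopifnot(all(positive_groups %in% colnames(tab)))
  pos <- colnames(tab) %in% positive_groups
  list(tp = sum(tab["alive", pos]), fp = sum(tab["dead", pos]),
       tn = sum(tab["dead", !pos]), fn = sum(tab["alive", !pos]),
       n = sum(tab))
}

#' Sensitivity and specificity with confidence intervals
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), as percentages with
#' continuity-corrected Wilson intervals.
#'
#' @param counts List with tp, fp, tn, fn (as from [confusion_counts()]).
#' @param conf_level Confidence level.
#' @return List with `sensitivity` and `specificity`, each a list:
#'   percent, lower_pct, upper_pct, k, n.
#' @export
sensitivity_specificity <- function(counts, conf_level = 0.95) {
  with(counts, {
    if (tp + fn == 0) stop("sensitivity undefined: no condition-positive specimens")
    if (tn + fp == 0) stop("specificity undefined: no condition-negative specimens")
    as_pct <- function(k, n) {
      ci <- survival_proportion_ci(k, n, conf_level)
      list(percent = 100 * ci$estimate, lower_pct = 100 * ci$lower,
           upper_pct = 100 * ci$upper, k = k, n = n)
    }
    list(sensitivity = as_pct(tp, tp + fn),
         specificity = as_pct(tn, tn + fp))
  })
}

#' Per-group predictive values for resistance/tolerance
#'
#' For each genotype group g, the positive predictive value is the
#' probability of surviving the bioassay given the group, PPV =
#' alive_g / n_g, and the negative predictive value its complement NPV =
#' dead_g / n_g, each with a continuity-corrected Wilson interval.
#' Computed at the sample's own prevalence. A group with no specimens is
#' reported as unavailable (NA), never as zero.
#'
#' @param specimens Specimen data frame.
#' @param insecticide Insecticide to evaluate.
#' @param leu_split Split the Leu/* group into its residue genotypes.
#' @param conf_level Confidence level.
#' @return Data frame: group, n, alive, ppv, ppv_lower, ppv_upper, npv,
#'   npv_lower, npv_upper.
#' @export
predictive_values <- function(specimens, insecticide, leu_split = FALSE,
                              conf_level = 0.95) {
  tab <- genotype_group_table(specimens, insecticide, leu_split = leu_split)
  rows <- lapply(colnames(tab), function(g) {
    alive <- tab["alive", g]; n <- sum(tab[, g])
    if (n == 0) {
      return(data.frame(group = g, n = 0L, alive = 0L,
                        ppv = NA_real_, ppv_lower = NA_real_, ppv_upper = NA_real_,
                        npv = NA_real_, npv_lower = NA_real_, npv_upper = NA_real_))
    }
    p <- survival_proportion_ci(alive, n, conf_level)
    q <- survival_proportion_ci(n - alive, n, conf_level)
    data.frame(group = g, n = n, alive = alive,
               ppv = p$estimate, ppv_lower = p$lower, ppv_upper = p$upper,
               npv = q$estimate, npv_lower = q$lower, npv_upper = q$upper)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Prevalence-adjusted predictive values
#'
#' Bayes re-weighting of a group's predictive value to a supplied
#' resistance prevalence, using the sample's group-conditional outcome
#' rates. Off the main path: the default analysis reports predictive
#' values at the sample's own prevalence.
#'
#' @param sens,spec Sensitivity and specificity as proportions in 0-1.
#' @param prevalence Assumed condition (resistance/tolerance) prevalence.
#' @return List: ppv, npv at the assumed prevalence.
#' @export
adjusted_predictive_values <- function(sens, spec, prevalence) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1,
            prevalence > 0, prevalence < 1)
  ppv <- sens * prevalence / (sens * prevalence + (1 - spec) * (1 - prevalence))
  npv <- spec * (1 - prevalence) / ((1 - sens) * prevalence + spec * (1 - prevalence))
  list(ppv = ppv, npv = npv)
}

#' Diagnostic report for one insecticide
#'
#' Bundles confusion counts, sensitivity/specificity and per-group
#' predictive values in one structure mirroring the diagnostic summary
#' table layout.
#'
#' @param specimens Specimen data frame.
#' @param insecticide Insecticide.
#' @param conf_level Confidence level.
#' @return List of class `kdr_diagnostic_report`.
#' @export
diagnostic_report <- function(specimens, insecticide, conf_level = 0.95) {
  cc <- confusion_counts(specimens, insecticide)
  ss <- sensitivity_specificity(cc, conf_level)
  pv <- predictive_values(specimens, insecticide, conf_level = conf_level)
  out <- list(insecticide = insecticide, counts = cc,
              sensitivity = ss$sensitivity, specificity = ss$specificity,
              predictive_values = pv, conf_level = conf_level)
  class(out) <- "kdr_diagnostic_report"
  out
}

#' @export
print.kdr_diagnostic_report <- function(x, ...) {
  cat("kdr diagnostic report --", x$insecticide, "\n")
  with(x$counts, cat(sprintf("  TP %d  FP %d  TN %d  FN %d (n = %d)\n",
                             tp, fp, tn, fn, n)))
  cat(sprintf("  sensitivity %.1f%% (%.0f-%.0f)\n", x$sensitivity$percent,
              x$sensitivity$lower_pct, x$sensitivity$upper_pct))
  cat(sprintf("  specificity %.1f%% (%.0f-%.0f)\n", x$specificity$percent,
              x$specificity$lower_pct, x$specificity$upper_pct))
  invisible(x)
}
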