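# Dual allele-discrimination assay model.
#
# Two fluorescent-probe assays jointly genotype codon 1014: assay 1
# differentiates the 2nd-position alleles (TTA vs TCA), assay 2 the
# 3rd-position alleles (TTC vs TTT). Each probe is modelled as detecting
# exactly one codon; alleles not matching either of an assay's probes give
# no signal on that assay. Under this exact-match model every allele is
# detected by exactly one probe across the pair of assays, which is the
# only model under which all 10 genotypes are unambiguously callable.

#' Default probe model for the dual codon-1014 assays
#'
#' @return Named list: for each assay, the character vector of codons its
#'   probes detect. Override to explore alternative probe chemistries.
#' @export
probe_model <- function() {
  list(assay1 = c("TTA", "TCA"), assay2 = c("TTC", "TTT"))
}

# Valid discrete calls for an assay over a probe codon pair c(x, y):
# "null", homozygous in either probe, or the two-probe heterozygote.
assay_call_levels <- function(probes) {
  p <- sort(probes)
  c("null", paste0("homo_", p), paste0("het_", p[1], "_", p[2]))
}

#' Codons detected by one assay call
#'
#' @param call A discrete assay call such as "homo_TCA", "het_TTC_TTT" or
#'   "null" (NA is treated as "null").
#' @return Character vector of detected codons (length 0, 1 or 2).
#' @export
assay_call_codons <- function(call) {
  if (is.na(call) || call == "null") return(character(0))
  if (startsWith(call, "homo_")) return(substring(call, 6))
  if (startsWith(call, "het_")) {
    return(strsplit(substring(call, 5), "_", fixed = TRUE)[[1]])
  }
  stop("unrecognised assay call: ", call)
}

#' Combine the two assay calls into a codon-1014 genotype
#'
#' The detected codon sets of the two assays are unioned: one distinct
#' codon is called homozygous, two distinct codons heterozygous. Both
#' assays null is a no-call; three or more detected codons contradict a
#' diploid genotype and are flagged inconsistent.
#'
#' @param assay1,assay2 Discrete calls for the two assays.
#' @param model Probe model (see [probe_model()]), used to validate that
#'   each call only involves codons that assay's probes can detect.
#' @return List with `genotype` (canonical string or NA) and `status`
#'   ("ok", "no_call" or "inconsistent").
#' @examples
#' combine_assay_calls("het_TTA_TCA", "null")      # TTA/TCA
#' combine_assay_calls("homo_TCA", "homo_TTT")     # TCA/TTT
#' @export
combine_assay_calls <- function(assay1, assay2, model = probe_model()) {
  c1 <- assay_call_codons(assay1)
  c2 <- assay_call_codons(assay2)
  if (!all(c1 %in% model$assay1)) {
    stop("assay 1 call involves codons outside its probe set: ", assay1)
  }
  if (!all(c2 %in% model$assay2)) {
    stop("assay 2 call involves codons outside its probe set: ", assay2)
  }
  detected <- union(c1, c2)
  if (length(detected) == 0L) {
    return(list(genotype = NA_character_, status = "no_call"))
  }
  if (length(detected) > 2L) {
    return(list(genotype = NA_character_, status = "inconsistent"))
  }
  g <- if (length(detected) == 1L) {
    kdr_genotype(detected, detected)
  } else {
    kdr_genotype(detected[1], detected[2])
  }
  list(genotype = g, status = "ok")
}

#' Expected assay readout of a genotype
#'
#' Inverse of [combine_assay_calls()] under the exact-match probe model:
#' for each assay, the alleles of the genotype matching that assay's
#' probes determine its call (none -> "null", one -> homozygous call, two
#' -> heterozygous call). Note a single detected codon yields a homozygous
#' call even when the individual carries only one copy (the other allele
#' is silent on that assay), e.g. TTA/TTT reads (homo_TTA, homo_TTT).
#'
#' @param genotype Canonical genotype string.
#' @param model Probe model.
#' @return List with `assay1` and `assay2` call strings.
#' @export
expected_readout <- function(genotype, model = probe_model()) {
  al <- genotype_alleles(genotype)
  one <- function(probes) {
    det <- sort(unique(al[al %in% probes]))
    if (length(det) == 0L) return("null")
    if (length(det) == 1L) return(paste0("homo_", det))
    paste0("het_", det[1], "_", det[2])
  }
  list(assay1 = one(model$assay1), assay2 = one(model$assay2))
}

#' Call genotypes for a table of assay readouts
#'
#' Vectorised wrapper over [combine_assay_calls()] for a data frame of
#' per-specimen readouts.
#'
#' @param readouts Data frame with columns `assay1` and `assay2` (discrete
#'   calls; NA treated as null), plus any identifier columns, which are
#'   carried through.
#' @param model Probe model.
#' @return The input data frame with `genotype` and `call_status` columns
#'   appended.
#' @export
call_genotypes_from_readouts <- function(readouts, model = probe_model()) {
  stopifnot(all(c("assay1", "assay2") %in% names(readouts)))
  res <- Map(combine_assay_calls, readouts$assay1, readouts$assay2,
             MoreArgs = list(model = model))
  readouts$genotype <- vapply(res, `[[`, NA_character_, "genotype")
  readouts$call_status <- vapply(res, `[[`, "", "status")
  readouts
}
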