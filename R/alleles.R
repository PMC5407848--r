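# Codon-level allele model at Vgsc codon 1014 (house-fly numbering).
# Only the four alleles observed in P. argentipes are modelled; the
# alternative leucine codon TTG is deliberately absent so that sequence
# input carrying it raises a "novel allele" error instead of being
# silently classed as wild type.
KDR_CODON_RESIDUE <- c(TTA = "Leu", TCA = "Ser", TTT = "Phe", TTC = "Phe")

#' Modelled kdr alleles at Vgsc codon 1014
#'
#' The four codon-level alleles observed at codon 1014: wild-type leucine
#' (TTA), the L1014S serine replacement (TCA) and the two L1014F
#' phenylalanine replacements (TTT, TTC).
#'
#' @return Character vector of the four modelled codons.
#' @export
kdr_alleles <- function() names(KDR_CODON_RESIDUE)

#' Residue class of a codon-1014 allele
#'
#' Maps a modelled codon to its amino-acid class: TTA -> Leu, TCA -> Ser,
#' TTT/TTC -> Phe. Any other codon -- including the unobserved alternative
#' leucine codon TTG -- is rejected.
#'
#' @param codon Character vector of uppercase 3-letter codons.
#' @return Character vector of residue classes ("Leu", "Ser", "Phe").
#' @examples
#' kdr_residue(c("TCA", "TTC"))
#' @export
kdr_residue <- function(codon) {
  stopifnot(is.character(codon))
  res <- KDR_CODON_RESIDUE[codon]
  if (anyNA(res)) {
    bad <- unique(codon[is.na(res)])
    stop("allele not in model: ", paste(bad, collapse = ", "),
         " (modelled codons: ", paste(kdr_alleles(), collapse = ", "), ")")
  }
  unname(res)
}

# Residues ordered wild-type first, then by observed effect; used to
# canonicalise residue pairs ("Leu/Phe", never "Phe/Leu").
RESIDUE_ORDER <- c("Leu", "Ser", "Phe")

#' Construct a codon-level genotype
#'
#' A genotype is an unordered pair of modelled alleles, serialised in
#' alphabetical codon order as e.g. "TTA/TCA". Both arguments are
#' vectorised and recycled.
#'
#' @param a1,a2 Codon strings (modelled alleles).
#' @return Character vector of canonical genotype strings.
#' @examples
#' kdr_genotype("TCA", "TTA")   # "TTA/TCA"
#' @export
kdr_genotype <- function(a1, a2) {
  kdr_residue(a1); kdr_residue(a2)  # validate
  ifelse(a1 <= a2, paste(a1, a2, sep = "/"), paste(a2, a1, sep = "/"))
}

#' All expressible codon-level genotypes
#'
#' The 10 unordered pairs (with replacement) of the four modelled alleles.
#'
#' @return Character vector of 10 canonical genotype strings.
#' @export
all_kdr_genotypes <- function() {
  al <- sort(kdr_alleles())
  idx <- which(upper.tri(diag(4), diag = TRUE), arr.ind = TRUE)
  sort(paste(al[idx[, "row"]], al[idx[, "col"]], sep = "/"))
}

#' Alleles of a genotype
#' @param genotype Canonical genotype string(s), e.g. "TTA/TCA".
#' @return For one genotype, a length-2 character vector; for several, a
#'   2-row matrix (one column per genotype).
#' @export
genotype_alleles <- function(genotype) {
  parts <- strsplit(genotype, "/", fixed = TRUE)
  ok <- vapply(parts, length, 1L) == 2L
  if (!all(ok)) stop("malformed genotype: ", paste(genotype[!ok], collapse = ", "))
  m <- vapply(parts, identity, character(2))
  kdr_residue(as.vector(m))  # validate
  if (length(genotype) == 1L) m[, 1] else m
}

#' Residue-level genotype after codon pooling
#'
#' Collapses a codon genotype to its residue pair, ordered Leu < Ser < Phe
#' (so TTC/TTA renders as "Leu/Phe"). The two phenylalanine codons TTT and
#' TTC pool to the same residue genotype.
#'
#' @param genotype Canonical genotype string(s).
#' @return Character vector like "Leu/Phe".
#' @export
genotype_residues <- function(genotype) {
  m <- matrix(genotype_alleles(genotype), nrow = 2)
  r1 <- kdr_residue(m[1, ]); r2 <- kdr_residue(m[2, ])
  swap <- match(r1, RESIDUE_ORDER) > match(r2, RESIDUE_ORDER)
  paste(ifelse(swap, r2, r1), ifelse(swap, r1, r2), sep = "/")
}

#' The six residue-level genotypes
#' @return Character vector, ordered wild-type first.
#' @export
all_residue_genotypes <- function() {
  c("Leu/Leu", "Leu/Ser", "Leu/Phe", "Ser/Ser", "Ser/Phe", "Phe/Phe")
}

# Group labels as printed in association tables.
GROUP_LEVELS <- c("Leu/*", "Ser/Ser", "Ser/Phe", "Phe/Phe")
LEU_FINE_LEVELS <- c("Leu/Leu", "Leu/Ser", "Leu/Phe")
GROUP_FINE_LEVELS <- c(LEU_FINE_LEVELS, GROUP_LEVELS[-1])

#' Dominance-group classification of a genotype
#'
#' Under a null hypothesis of recessivity of each kdr allele alone (with
#' possible additivity of alternate kdr alleles), genotypes fall into four
#' groups: any genotype carrying a wild-type leucine allele ("Leu/*"), and
#' the three kdr-only residue genotypes "Ser/Ser", "Ser/Phe" and "Phe/Phe".
#'
#' @param genotype Canonical genotype string(s).
#' @param fine If TRUE, the Leu/* group is split into its three residue
#'   genotypes Leu/Leu, Leu/Ser and Leu/Phe (needed to expose survival
#'   heterogeneity among leucine-carrying genotypes).
#' @return Factor with levels in table display order.
#' @examples
#' genotype_group(c("TCA/TTT", "TTA/TTC"))
#' @export
genotype_group <- function(genotype, fine = FALSE) {
  res <- genotype_residues(genotype)
  has_leu <- startsWith(res, "Leu")
  lab <- ifelse(has_leu & !fine, "Leu/*", res)
  factor(lab, levels = if (fine) GROUP_FINE_LEVELS else GROUP_LEVELS)
}

#' Group labels
#' @param fine If TRUE, return the six fine labels (Leu/* split).
#' @return Character vector of group labels in display order.
#' @export
genotype_group_levels <- function(fine = FALSE) {
  if (fine) GROUP_FINE_LEVELS else GROUP_LEVELS
}

#' Count alleles carried by a set of genotypes
#'
#' Each individual contributes two allele counts. Counting is at residue
#' level by default (TTT and TTC pooled to Phe) or at codon level.
#'
#' @param genotype Character vector of canonical genotype strings.
#' @param level "residue" (default) or "codon".
#' @return Named integer vector over all alleles at that level.
#' @export
count_alleles <- function(genotype, level = c("residue", "codon")) {
  level <- match.arg(level)
  al <- as.vector(matrix(genotype_alleles(genotype), nrow = 2))
  if (level == "residue") {
    table(factor(kdr_residue(al), levels = RESIDUE_ORDER))
  } else {
    table(factor(al, levels = kdr_alleles()))
  }
}
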