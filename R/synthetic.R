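# Synthetic-data generator: specimen tables, assay readouts and amplicon
# sequences carrying the statistical structure the analysis assumes, plus
# the packaged bioassay fixture.

# Bioassay design constants: exposure minutes and rearing cohort per
# insecticide (standard 60-min exposure for DDT; deliberately shortened
# pyrethroid exposures to generate survivors; deltamethrin assays used
# colony rather than F1 females).
INSECTICIDE_EXPOSURE <- c(DDT = 60, deltamethrin = 20, `alpha-cypermethrin` = 30)
INSECTICIDE_COHORT <- c(DDT = "F1", deltamethrin = "colony",
                        `alpha-cypermethrin` = "F1")

#' Packaged bioassay fixture
#'
#' Deterministically expands the packaged genotype-by-outcome counts per
#' insecticide (with the Leu/* fine split) into one row per pseudo
#' specimen. Residue-level table cells are represented at codon level with
#' phenylalanine encoded as TTT; allele counts after TTT/TTC pooling, the
#' genotype-group tables and the confusion counts derived from this table
#' reproduce the source counts exactly.
#'
#' @return Specimen data frame: id, district, phc, village, insecticide,
#'   exposure_minutes, outcome, role, cohort, genotype.
#' @export
bioassay_fixture <- function() {
  path <- system.file("extdata", "vgsc1014_bioassay_counts.csv",
                      package = "kdrkit", mustWork = TRUE)
  counts <- utils::read.csv(path, stringsAsFactors = FALSE)
  rows <- counts[rep(seq_len(nrow(counts)), counts$count), ]
  data.frame(
    id = sprintf("%s_%s_%03d", abbreviate(rows$insecticide, 5), rows$outcome,
                 stats::ave(seq_len(nrow(rows)),
                            paste(rows$insecticide, rows$outcome),
                            FUN = seq_along)),
    district = NA_character_, phc = NA_character_, village = NA_character_,
    insecticide = rows$insecticide,
    exposure_minutes = unname(INSECTICIDE_EXPOSURE[rows$insecticide]),
    outcome = rows$outcome,
    role = "test",
    cohort = unname(INSECTICIDE_COHORT[rows$insecticide]),
    genotype = rows$genotype,
    stringsAsFactors = FALSE
  )
}

#' Printed display values packaged with the fixture
#'
#' The headline association and diagnostic values as displayed in the
#' source tables (rounded for display), for the reproduction drivers'
#' verification mode.
#'
#' @return Data frame: metric, insecticide, value, digits.
#' @export
printed_values <- function() {
  path <- system.file("extdata", "vgsc1014_printed_values.csv",
                      package = "kdrkit", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Penetrance map estimated from the packaged fixture
#'
#' Genotype-group-specific survival probabilities (penetrance), computed
#' as alive / (alive + dead) per fine group and insecticide from the
#' fixture counts; the generative default of [synthetic_config()].
#'
#' @return Named list: per insecticide, a named numeric vector of survival
#'   probabilities over the six fine genotype groups.
#' @export
fixture_penetrance <- function() {
  fx <- bioassay_fixture()
  out <- lapply(names(INSECTICIDE_EXPOSURE), function(ins) {
    tab <- genotype_group_table(fx, ins, leu_split = TRUE)
    stats::setNames(as.numeric(tab["alive", ] / colSums(tab)), colnames(tab))
  })
  stats::setNames(out, names(INSECTICIDE_EXPOSURE))
}

#' Configuration for the synthetic specimen generator
#'
#' @param sites Data frame with columns name, TTA, TCA, TTT, TTC (allele
#'   frequencies, summing to 1 per row) and f (inbreeding coefficient).
#' @param penetrance Map insecticide -> named survival-probability vector
#'   over fine genotype groups (default: fixture-estimated penetrance).
#' @param control_mortality Control-tube mortality probability.
#' @param specimens_per_bioassay Females per tube.
#' @param bioassays_per_site Test tubes per site and insecticide.
#' @param no_call_rate Per-assay probability of a null readout.
#' @param seed Random seed (mandatory).
#' @return List of class `kdr_synth_config`.
#' @export
synthetic_config <- function(sites = data.frame(
                               name = c("Vaishali", "Patna"),
                               TTA = c(0.10, 0.30), TCA = c(0.35, 0.40),
                               TTT = c(0.45, 0.20), TTC = c(0.10, 0.10),
                               f = c(0, 0)),
                             penetrance = fixture_penetrance(),
                             control_mortality = 0.02,
                             specimens_per_bioassay = 25L,
                             bioassays_per_site = 4L,
                             no_call_rate = 0.02,
                             seed) {
  if (missing(seed)) stop("a seed is mandatory for synthetic data")
  freqs <- as.matrix(sites[, kdr_alleles()])
  stopifnot(all(abs(rowSums(freqs) - 1) < 1e-8),
            all(freqs >= 0),
            all(sites$f >= 0 & sites$f <= 1),
            control_mortality >= 0, control_mortality <= 1,
            no_call_rate >= 0, no_call_rate <= 1)
  for (ins in names(penetrance)) {
    stopifnot(all(penetrance[[ins]] >= 0 & penetrance[[ins]] <= 1))
  }
  out <- list(sites = sites, penetrance = penetrance,
              control_mortality = control_mortality,
              specimens_per_bioassay = as.integer(specimens_per_bioassay),
              bioassays_per_site = as.integer(bioassays_per_site),
              no_call_rate = no_call_rate, seed = as.integer(seed))
  class(out) <- "kdr_synth_config"
  out
}

# genotype probabilities under HWE perturbed by inbreeding coefficient f:
# P(ii) = p_i^2 + f p_i (1 - p_i); P(ij) = 2 p_i p_j (1 - f)
genotype_probs <- function(freqs, f = 0) {
  al <- names(freqs)
  gs <- all_kdr_genotypes()
  pr <- vapply(gs, function(g) {
    a <- genotype_alleles(g)
    if (a[1] == a[2]) freqs[[a[1]]]^2 + f * freqs[[a[1]]] * (1 - freqs[[a[1]]])
    else 2 * freqs[[a[1]]] * freqs[[a[2]]] * (1 - f)
  }, numeric(1))
  pr / sum(pr)
}

#' Simulate bioassayed specimens
#'
#' For each site and insecticide draws genotypes from
#' Hardy-Weinberg-with-inbreeding genotype probabilities, then bioassay
#' outcomes as Bernoulli trials of the genotype group's penetrance; one
#' control tube per site and insecticide dies at the control mortality
#' rate independently of genotype. Fully reproducible from the config
#' seed.
#'
#' @param config A [synthetic_config()].
#' @return Specimen data frame in the same schema as
#'   [bioassay_fixture()], controls included (role = "control").
#' @export
simulate_specimens <- function(config) {
  stopifnot(inherits(config, "kdr_synth_config"))
  set.seed(config$seed)
  gs <- all_kdr_genotypes()
  rows <- list()
  for (s in seq_len(nrow(config$sites))) {
    site <- config$sites[s, ]
    freqs <- stats::setNames(as.numeric(site[kdr_alleles()]), kdr_alleles())
    gp <- genotype_probs(freqs, site$f)
    for (ins in names(config$penetrance)) {
      pen <- config$penetrance[[ins]]
      n_test <- config$specimens_per_bioassay * config$bioassays_per_site
      n_ctrl <- config$specimens_per_bioassay
      geno <- sample(gs, n_test + n_ctrl, replace = TRUE, prob = gp)
      grp <- as.character(genotype_group(geno, fine = TRUE))
      if (any(is.na(pen[grp[seq_len(n_test)]]))) {
        stop("penetrance missing for group(s): ",
             paste(unique(grp[seq_len(n_test)][is.na(pen[grp[seq_len(n_test)]])]),
                   collapse = ", "))
      }
      alive_test <- stats::runif(n_test) < pen[grp[seq_len(n_test)]]
      dead_ctrl <- stats::runif(n_ctrl) < config$control_mortality
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("%s_%s_%04d", site$name, abbreviate(ins, 5),
                     seq_len(n_test + n_ctrl)),
        district = site$name, phc = NA_character_, village = NA_character_,
        insecticide = ins,
        exposure_minutes = unname(INSECTICIDE_EXPOSURE[ins]),
        outcome = c(ifelse(alive_test, "alive", "dead"),
                    ifelse(dead_ctrl, "dead", "alive")),
        role = rep(c("test", "control"), c(n_test, n_ctrl)),
        cohort = unname(INSECTICIDE_COHORT[ins]),
        genotype = geno,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Simulate dual-assay readouts for known genotypes
#'
#' Emits the canonical probe-model readout of each genotype, replacing
#' each assay's call with "null" independently at the no-call rate.
#'
#' @param genotypes Character vector of genotypes.
#' @param no_call_rate Per-assay null probability.
#' @param seed Random seed.
#' @param model Probe model.
#' @return Data frame: id, true_genotype, assay1, assay2.
#' @export
simulate_assay_readouts <- function(genotypes, no_call_rate = 0, seed,
                                    model = probe_model()) {
  stopifnot(no_call_rate >= 0, no_call_rate <= 1)
  set.seed(seed)
  ro <- lapply(genotypes, expected_readout, model = model)
  a1 <- vapply(ro, `[[`, "", "assay1")
  a2 <- vapply(ro, `[[`, "", "assay2")
  n <- length(genotypes)
  a1[stats::runif(n) < no_call_rate] <- "null"
  a2[stats::runif(n) < no_call_rate] <- "null"
  data.frame(id = sprintf("ro%04d", seq_len(n)), true_genotype = genotypes,
             assay1 = a1, assay2 = a2, stringsAsFactors = FALSE)
}

#' Simulate Sanger-style amplicon sequences for known genotypes
#'
#' Substitutes the codon-1014 positions of the reference fragment with the
#' position-wise IUPAC superposition of the genotype's two allele codons
#' (single-sequence heterozygote encoding); primers stay embedded so
#' [locate_amplicon()] succeeds. Optionally emits a fraction of records
#' reverse-complemented to exercise strand handling.
#'
#' @param genotypes Character vector of genotypes.
#' @param ref Reference annotation.
#' @param revcomp_fraction Fraction of records emitted on the minus
#'   strand.
#' @param seed Seed (used only when `revcomp_fraction > 0`).
#' @return `Biostrings::DNAStringSet`, one record per genotype, named by
#'   index and genotype.
#' @export
simulate_amplicons <- function(genotypes, ref = kdr_reference(),
                               revcomp_fraction = 0, seed = NULL) {
  pos <- codon_genomic_positions(ref, 1014L)
  stopifnot(identical(pos, pos[1] + 0:2))  # codon uninterrupted by intron
  seqs <- vapply(genotypes, function(g) {
    al <- genotype_alleles(g)
    c1 <- strsplit(al[1], "")[[1]]; c2 <- strsplit(al[2], "")[[1]]
    iupac <- vapply(1:3, function(i) iupac_code_for(c(c1[i], c2[i])), "")
    s <- strsplit(ref$sequence, "")[[1]]
    s[pos + 1L] <- iupac
    paste(s, collapse = "")
  }, character(1))
  if (revcomp_fraction > 0) {
    if (is.null(seed)) stop("minus-strand emission requires a seed")
    set.seed(seed)
    flip <- stats::runif(length(seqs)) < revcomp_fraction
    seqs[flip] <- vapply(seqs[flip], revcomp, character(1))
  }
  out <- Biostrings::DNAStringSet(unname(seqs))
  names(out) <- sprintf("amp%04d_%s", seq_along(genotypes),
                        gsub("/", "-", genotypes))
  out
}
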