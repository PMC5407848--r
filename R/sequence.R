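# Amplicon-based calling of Vgsc codon 1014 (and a screen of codons
# 1011/1016/1020) from Sanger-style sequences, anchored to a reference
# fragment with house-fly para codon numbering. Heterozygotes are expected
# as single sequences carrying IUPAC ambiguity codes.

# --- IUPAC utilities ---------------------------------------------------

.iupac_cache <- new.env(parent = emptyenv())

iupac_sets <- function() {
  if (is.null(.iupac_cache$sets)) {
    m <- Biostrings::IUPAC_CODE_MAP
    .iupac_cache$sets <- lapply(m, function(x) strsplit(x, "")[[1]])
  }
  .iupac_cache$sets
}

# letter x letter compatibility (base sets intersect), cached
iupac_compat_matrix <- function() {
  if (is.null(.iupac_cache$compat)) {
    sets <- iupac_sets()
    .iupac_cache$compat <- outer(
      names(sets), names(sets),
      Vectorize(function(a, b) length(intersect(sets[[a]], sets[[b]])) > 0))
    dimnames(.iupac_cache$compat) <- list(names(sets), names(sets))
  }
  .iupac_cache$compat
}

# TRUE where the base sets of two IUPAC letters intersect.
iupac_compatible <- function(a, b) {
  sets <- iupac_sets()
  sa <- sets[strsplit(a, "")[[1]]]
  sb <- sets[strsplit(b, "")[[1]]]
  if (any(vapply(c(sa, sb), is.null, TRUE))) stop("non-IUPAC letter in sequence")
  mapply(function(x, y) length(intersect(x, y)) > 0, sa, sb)
}

#' Minimal IUPAC code covering a set of bases
#' @param bases Character vector of A/C/G/T bases.
#' @return Single IUPAC letter whose base set equals the union.
#' @export
iupac_code_for <- function(bases) {
  want <- sort(unique(bases))
  sets <- iupac_sets()
  hit <- names(sets)[vapply(sets, function(s) identical(sort(s), want), TRUE)]
  if (length(hit) != 1L) stop("no IUPAC code for base set: ", paste(want, collapse = ""))
  hit
}

#' Expand an IUPAC-ambiguous codon into concrete codons
#' @param codon 3-letter string, possibly with ambiguity codes.
#' @return Character vector of all concrete ACGT codons it covers.
#' @export
expand_iupac_codon <- function(codon) {
  stopifnot(nchar(codon) == 3L)
  sets <- iupac_sets()
  pos <- sets[strsplit(codon, "")[[1]]]
  if (any(vapply(pos, is.null, TRUE))) stop("non-IUPAC letter in codon: ", codon)
  grid <- expand.grid(pos[[1]], pos[[2]], pos[[3]], stringsAsFactors = FALSE)
  sort(paste0(grid[[1]], grid[[2]], grid[[3]]))
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# --- primers and reference --------------------------------------------

#' Conserved Vgsc domain-IIS6 amplification primers
#'
#' The primer pair used to amplify the domain II segment 6 fragment of the
#' voltage-gated sodium channel gene spanning codons 1011-1020.
#'
#' @return List with `forward` (Vssc8F) and `reverse` (Vssc1bR) sequences.
#' @export
vssc_primers <- function() {
  list(forward = "AATGTGGGATTGCATGCTGG", reverse = "CGTATCATTGTCTGCAGTTGGT")
}

# Synthetic stand-in coding region, codons 1001-1030 under house-fly
# numbering. Watched codons carry the wild-type residues (1011 Ile,
# 1014 Leu [TTA], 1016 Val, 1020 Phe); the remainder are invented
# hydrophobic-leaning codons chosen so every 30-nt anchor window is unique
# within the fragment. Replaceable by a field-derived annotation.
REF_CODONS <- c(
  "GGA", "TGT", "GTC", "ATC", "TGC", "CTG", "ACC", "GTG", "TTC", "CGT",
  "ATT", "ATG", "GGT", "TTA", "AAC", "GTA", "CCG", "ATG", "CAA", "TTT",
  "CTC", "GGC", "TGG", "AAC", "ATC", "TTC", "GAC", "TTC", "ATG", "GTC"
)

#' Reference annotation for the domain-IIS6 amplicon
#'
#' Builds the annotation object used to anchor amplicons: the fragment
#' sequence (forward primer + coding region + reverse-primer site), the
#' coding frame, the house-fly codon numbering anchor, the watched codons
#' with their wild-type residues, and an optional excluded (intron)
#' interval. The default ships an intron-free synthetic fragment spanning
#' codons 1001-1030; field-derived references can be supplied in the same
#' shape.
#'
#' @param codons Character vector of in-frame reference codons.
#' @param codon_start House-fly codon number of the first codon.
#' @param primers Primer pair embedded at the fragment ends.
#' @param intron Optional 0-based half-open genomic interval (relative to
#'   the fragment) excluded from the coding frame, or NULL.
#' @param watched Named character vector: wild-type residue (3-letter) per
#'   watched codon number.
#' @return Object of class `kdr_reference`.
#' @export
kdr_reference <- function(codons = REF_CODONS, codon_start = 1001L,
                          primers = vssc_primers(), intron = NULL,
                          watched = c(`1011` = "Ile", `1014` = "Leu",
                                      `1016` = "Val", `1020` = "Phe")) {
  cds <- paste(codons, collapse = "")
  fwd <- primers$forward
  rev_site <- revcomp(primers$reverse)
  genomic <- if (is.null(intron)) cds else {
    # intron coordinates are relative to the final fragment; insert a
    # spacer so the stated interval is non-coding
    stop_if <- function(ok, msg) if (!ok) stop(msg)
    stop_if(length(intron) == 2 && intron[1] < intron[2], "bad intron interval")
    off <- nchar(fwd)
    cut <- intron[1] - off
    stop_if(cut > 0 && cut < nchar(cds), "intron must lie inside the coding span")
    paste0(substr(cds, 1, cut), strrep("N", intron[2] - intron[1]),
           substr(cds, cut + 1, nchar(cds)))
  }
  seq <- paste0(fwd, genomic, rev_site)
  obj <- list(
    sequence = seq,
    cds_offset = nchar(fwd),
    cds_end = nchar(seq) - nchar(rev_site),
    codon_start = as.integer(codon_start),
    intron = intron,
    watched = watched,
    primers = primers
  )
  class(obj) <- "kdr_reference"
  obj
}

# 0-based genomic positions of the coding bases, intron excluded.
coding_positions <- function(ref) {
  pos <- seq.int(ref$cds_offset, ref$cds_end - 1L)
  if (!is.null(ref$intron)) {
    pos <- pos[pos < ref$intron[1] | pos >= ref$intron[2]]
  }
  pos
}

# 0-based genomic positions of a codon's three bases.
codon_genomic_positions <- function(ref, codon_number) {
  cp <- coding_positions(ref)
  i <- (as.integer(codon_number) - ref$codon_start) * 3L
  if (i < 0L || i + 3L > length(cp)) {
    stop("codon ", codon_number, " outside the annotated fragment")
  }
  cp[i + 1:3]
}

#' Codon string at a house-fly codon number in the reference
#' @param ref A `kdr_reference`.
#' @param codon_number House-fly codon number.
#' @return 3-letter codon string.
#' @export
reference_codon <- function(ref, codon_number) {
  p <- codon_genomic_positions(ref, codon_number)
  paste(strsplit(ref$sequence, "")[[1]][p + 1L], collapse = "")
}

# --- primer scan -------------------------------------------------------

# Brute Hamming scan of a short pattern (IUPAC allowed on both sides)
# against every ungapped offset of the subject. Returns mismatch count per
# 0-based start position.
hamming_profile <- function(subject, pattern) {
  sl <- nchar(subject); pl <- nchar(pattern)
  if (pl > sl) return(integer(0))
  s <- strsplit(subject, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  compat <- iupac_compat_matrix()
  if (!all(s %in% rownames(compat)) || !all(p %in% rownames(compat))) {
    stop("non-IUPAC letter in sequence")
  }
  vapply(0:(sl - pl), function(off) {
    sum(!compat[cbind(s[off + seq_len(pl)], p)])
  }, integer(1))
}

#' Locate the amplicon between the two primer sites
#'
#' Scans for the forward primer and the reverse complement of the reverse
#' primer with at most `max_mismatch` mismatches each (ungapped, IUPAC
#' aware), on both strands; if the minus strand matches better the input
#' is reported as minus-strand and returned reverse-complemented.
#'
#' @param seq DNA sequence (character).
#' @param primers Primer pair, as from [vssc_primers()].
#' @param max_mismatch Maximum mismatches tolerated per primer.
#' @return List: `status` ("ok", "not_found", "ambiguous"), and when ok
#'   `start`/`end` (0-based half-open interval of the insert between the
#'   primers on the oriented sequence), `strand` ("+"/"-"), `mismatches`
#'   (named, per primer), and `sequence` (the plus-oriented sequence).
#' @export
locate_amplicon <- function(seq, primers = vssc_primers(), max_mismatch = 1L) {
  stopifnot(max_mismatch >= 0L)
  scan_one <- function(s) {
    pf <- hamming_profile(s, primers$forward)
    pr <- hamming_profile(s, revcomp(primers$reverse))
    if (!length(pf) || !length(pr)) return(list(ok = FALSE))
    bf <- min(pf); br <- min(pr)
    if (bf > max_mismatch || br > max_mismatch) return(list(ok = FALSE, score = bf + br))
    f_at <- which(pf == bf) - 1L
    r_at <- which(pr == br) - 1L
    list(ok = TRUE, score = bf + br, f_at = f_at, r_at = r_at, bf = bf, br = br)
  }
  plus <- scan_one(seq)
  rc <- revcomp(seq)
  minus <- scan_one(rc)
  pick <- if (plus$ok && (!minus$ok || plus$score <= minus$score)) "+"
          else if (minus$ok) "-" else NA
  if (is.na(pick)) return(list(status = "not_found"))
  hit <- if (pick == "+") plus else minus
  oriented <- if (pick == "+") seq else rc
  if (length(hit$f_at) > 1L || length(hit$r_at) > 1L) {
    return(list(status = "ambiguous", strand = pick))
  }
  ins_start <- hit$f_at + nchar(primers$forward)
  ins_end <- hit$r_at
  if (ins_end < ins_start) return(list(status = "not_found"))
  list(status = "ok", start = ins_start, end = ins_end, strand = pick,
       mismatches = c(forward = hit$bf, reverse = hit$br),
       sequence = oriented)
}

# --- anchored codon extraction ----------------------------------------

# Anchor window around a codon: the genomic reference slice from 13 nt
# before the codon's first base to 13 nt after its last, clipped to the
# fragment. Returns window string plus the codon's offsets within it.
anchor_window <- function(ref, codon_number) {
  pos <- codon_genomic_positions(ref, codon_number)
  len <- nchar(ref$sequence)
  start <- max(0L, pos[1] - 13L)
  end <- min(len, pos[3] + 14L)
  list(window = substr(ref$sequence, start + 1L, end),
       codon_rel = pos - start)
}

# Best ungapped placement of the anchor window on the query (already
# oriented). min_identity applies to the window length.
match_anchor <- function(query, ref, codon_number, min_identity = 0.8) {
  aw <- anchor_window(ref, codon_number)
  prof <- hamming_profile(query, aw$window)
  if (!length(prof)) return(list(status = "anchor_not_found"))
  best <- min(prof)
  wl <- nchar(aw$window)
  if ((wl - best) / wl < min_identity) return(list(status = "anchor_not_found"))
  at <- which(prof == best) - 1L
  if (length(at) > 1L) return(list(status = "ambiguous_anchor"))
  q <- strsplit(query, "")[[1]]
  codon <- paste(q[at + aw$codon_rel + 1L], collapse = "")
  list(status = "ok", at = at, mismatches = best, codon = codon)
}

# Decide orientation by anchor fit at codon 1014; returns oriented query.
orient_query <- function(seq, ref, min_identity = 0.8) {
  sc <- function(s) {
    aw <- anchor_window(ref, 1014L)
    prof <- hamming_profile(s, aw$window)
    if (!length(prof)) Inf else min(prof)
  }
  rc <- revcomp(seq)
  if (sc(seq) <= sc(rc)) list(sequence = seq, strand = "+")
  else list(sequence = rc, strand = "-")
}

# position-wise IUPAC superposition of two concrete codons
codon_superposition <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  paste(vapply(1:3, function(i) iupac_code_for(c(ca[i], cb[i])), ""),
        collapse = "")
}

# Expand an extracted codon into allele calls. Returns list(status,
# alleles) where status is ok / unresolvable / novel_allele.
#
# A diploid Sanger read superposes two codons, so any position with a
# 3/4-way code is unresolvable outright. A single 2-way position expands
# to the two alleles directly. Two 2-way positions (e.g. TYM from a
# TCA/TTC heterozygote) admit two codon pairs whose superposition matches
# the read; when an allele model is supplied the call succeeds iff
# exactly one of those pairs consists entirely of modelled alleles --
# the restricted allele universe is what makes such double-site
# heterozygotes callable at all. Without a model (the watched-codon
# screen) multi-site ambiguity stays unresolvable.
codon_to_alleles <- function(codon, valid = kdr_alleles()) {
  sets <- iupac_sets()
  letters3 <- strsplit(codon, "")[[1]]
  if (!all(letters3 %in% names(sets))) {
    return(list(status = "unresolvable", alleles = character(0),
                note = paste0("non-IUPAC codon ", codon)))
  }
  widths <- lengths(sets[letters3])
  if (any(widths > 2L)) {
    return(list(status = "unresolvable", alleles = character(0),
                note = paste0("3/4-way ambiguity in ", codon)))
  }
  n_amb <- sum(widths > 1L)
  exp <- expand_iupac_codon(codon)
  if (n_amb == 0L) {
    if (!is.null(valid) && !(exp %in% valid)) {
      return(list(status = "novel_allele", alleles = exp,
                  note = paste0("codon ", codon, " is not a modelled allele")))
    }
    return(list(status = "ok", alleles = exp, note = ""))
  }
  if (n_amb == 1L) {
    if (!is.null(valid) && !all(exp %in% valid)) {
      return(list(status = "novel_allele", alleles = exp,
                  note = paste0("codon ", codon, " expands to unmodelled allele(s): ",
                                paste(setdiff(exp, valid), collapse = ", "))))
    }
    return(list(status = "ok", alleles = exp, note = ""))
  }
  if (is.null(valid)) {
    return(list(status = "unresolvable", alleles = character(0),
                note = paste0("multi-site ambiguity in ", codon,
                              " without an allele model")))
  }
  pairs <- utils::combn(exp, 2)
  match_pair <- apply(pairs, 2, function(p) codon_superposition(p[1], p[2]) == codon)
  modelled <- apply(pairs, 2, function(p) all(p %in% valid))
  hit <- which(match_pair & modelled)
  if (length(hit) == 1L) {
    return(list(status = "ok", alleles = pairs[, hit], note = ""))
  }
  if (length(hit) == 0L && any(match_pair)) {
    return(list(status = "novel_allele", alleles = character(0),
                note = paste0("codon ", codon,
                              " only explained by unmodelled allele pair(s)")))
  }
  list(status = "unresolvable", alleles = character(0),
       note = paste0("multi-site ambiguity in ", codon,
                     " matches multiple modelled allele pairs"))
}

#' Call the codon-1014 genotype from an amplicon sequence
#'
#' Orients the sequence, anchors the 1014 codon by best ungapped placement
#' of a reference window centred on the codon (minimum 80% identity; a tie
#' between placements is an error, never an arbitrary pick), expands any
#' IUPAC ambiguity into at most two alleles, and returns the genotype.
#'
#' @param seq Amplicon DNA sequence (character; IUPAC codes allowed).
#' @param ref Reference annotation ([kdr_reference()]).
#' @param min_identity Minimum anchor-window identity.
#' @return List: `genotype` (canonical string or NA), `status` ("ok",
#'   "novel_allele", "unresolvable", "anchor_not_found",
#'   "ambiguous_anchor"), `codon` (as read), `strand`, `note`.
#' @examples
#' ref <- kdr_reference()
#' call_codon_1014(ref$sequence)$genotype            # "TTA/TTA"
#' @export
call_codon_1014 <- function(seq, ref = kdr_reference(), min_identity = 0.8) {
  ori <- orient_query(seq, ref, min_identity)
  m <- match_anchor(ori$sequence, ref, 1014L, min_identity)
  if (m$status != "ok") {
    return(list(genotype = NA_character_, status = m$status,
                codon = NA_character_, strand = ori$strand, note = m$status))
  }
  ex <- codon_to_alleles(m$codon)
  if (ex$status != "ok") {
    return(list(genotype = NA_character_, status = ex$status,
                codon = m$codon, strand = ori$strand, note = ex$note))
  }
  g <- if (length(ex$alleles) == 1L) kdr_genotype(ex$alleles, ex$alleles)
       else kdr_genotype(ex$alleles[1], ex$alleles[2])
  list(genotype = g, status = "ok", codon = m$codon, strand = ori$strand,
       note = "")
}

# One-letter -> three-letter residue, via the standard code.
translate_codon3 <- function(codon) {
  aa1 <- as.character(Biostrings::translate(Biostrings::DNAString(codon)))
  unname(Biostrings::AMINO_ACID_CODE[aa1])
}

#' Screen the watched resistance codons of an amplicon
#'
#' Reports, for each watched codon (by default 1011, 1014, 1016, 1020),
#' the residue genotype read from the amplicon and whether it is wild
#' type. Synonymous ambiguity (all expansions translating to the wild-type
#' residue) keeps the wild-type flag TRUE.
#'
#' @param seq Amplicon DNA sequence.
#' @param ref Reference annotation.
#' @param min_identity Minimum anchor-window identity.
#' @return Data frame: codon number, codon read, residue genotype,
#'   wild-type residue, `wildtype` flag (NA when unreadable), status.
#' @export
screen_watched_codons <- function(seq, ref = kdr_reference(), min_identity = 0.8) {
  ori <- orient_query(seq, ref, min_identity)
  rows <- lapply(names(ref$watched), function(cn) {
    wt <- ref$watched[[cn]]
    m <- match_anchor(ori$sequence, ref, as.integer(cn), min_identity)
    if (m$status != "ok") {
      return(data.frame(codon_number = as.integer(cn), codon = NA,
                        residues = NA, wildtype_residue = wt,
                        wildtype = NA, status = m$status))
    }
    ex <- codon_to_alleles(m$codon, valid = NULL)
    if (ex$status != "ok") {
      return(data.frame(codon_number = as.integer(cn), codon = m$codon,
                        residues = NA, wildtype_residue = wt,
                        wildtype = NA, status = ex$status))
    }
    res <- vapply(ex$alleles, translate_codon3, "")
    u <- sort(unique(res))
    data.frame(codon_number = as.integer(cn), codon = m$codon,
               residues = paste(rep(u, length.out = max(2, length(u)))[1:2],
                                collapse = "/"),
               wildtype_residue = wt,
               wildtype = all(res == wt), status = "ok")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call genotypes for a set of amplicon records
#'
#' Batch driver: reads a FASTA file (or takes a named character vector /
#' `DNAStringSet`), trims each record to the primer-bounded insert where
#' locatable, calls the 1014 genotype, classifies the dominance group and
#' screens the watched codons.
#'
#' @param x Path to a FASTA file, a named character vector of sequences,
#'   or a `Biostrings::DNAStringSet`.
#' @param ref Reference annotation.
#' @param max_mismatch Primer mismatch tolerance for trimming.
#' @return Data frame, one row per record: id, genotype, residue genotype,
#'   group, call status, strand, watched-codon wild-type flags and a QC
#'   note.
#' @export
call_amplicons <- function(x, ref = kdr_reference(), max_mismatch = 1L) {
  seqs <- if (is.character(x) && length(x) == 1L && file.exists(x)) {
    s <- Biostrings::readDNAStringSet(x)
    stats::setNames(as.character(s), names(s))
  } else if (methods::is(x, "DNAStringSet")) {
    stats::setNames(as.character(x), names(x))
  } else if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    x
  } else stop("unsupported input: need FASTA path, character vector or DNAStringSet")
  if (!length(seqs)) {
    warning("no amplicon records in input")
  }
  rows <- lapply(seq_along(seqs), function(i) {
    s <- toupper(seqs[[i]])
    loc <- locate_amplicon(s, ref$primers, max_mismatch)
    call <- call_codon_1014(s, ref)
    watched <- screen_watched_codons(s, ref)
    wt_ok <- watched$wildtype[watched$codon_number != 1014L]
    data.frame(
      id = names(seqs)[i],
      genotype = call$genotype,
      residues = if (is.na(call$genotype)) NA_character_
                 else genotype_residues(call$genotype),
      group = if (is.na(call$genotype)) NA_character_
              else as.character(genotype_group(call$genotype)),
      call_status = call$status,
      strand = call$strand,
      primer_trim = loc$status,
      watched_wildtype = all(wt_ok %in% TRUE),
      qc_note = call$note,
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), genotype = character(0), residues = character(0),
               group = character(0), call_status = character(0), strand = character(0),
               primer_trim = character(0), watched_wildtype = logical(0),
               qc_note = character(0))
  rownames(out) <- NULL
  out
}
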