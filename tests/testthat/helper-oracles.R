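# Independent oracles, deliberately written as literal per-sequence
# summations / full scans, separate from the package's vectorized paths.

# Literal unified nearest-neighbor table lookup: walk the sequence one
# dinucleotide at a time, add initiation terms, apply the two-state
# formula. dH kcal/mol, dS cal/(mol K).
oracle_tm <- function(seq, na_molar = 1.0, formamide_pct = 0,
                      probe_conc_m = 5e-9, formamide_coef = 0.65) {
  tab <- list(
    AA = c(-7.9, -22.2), TT = c(-7.9, -22.2),
    AT = c(-7.2, -20.4), TA = c(-7.2, -21.3),
    CA = c(-8.5, -22.7), TG = c(-8.5, -22.7),
    GT = c(-8.4, -22.4), AC = c(-8.4, -22.4),
    CT = c(-7.8, -21.0), AG = c(-7.8, -21.0),
    GA = c(-8.2, -22.2), TC = c(-8.2, -22.2),
    CG = c(-10.6, -27.2), GC = c(-9.8, -24.4),
    GG = c(-8.0, -19.9), CC = c(-8.0, -19.9)
  )
  init <- list(A = c(2.3, 4.1), T = c(2.3, 4.1),
               G = c(0.1, -2.8), C = c(0.1, -2.8))
  dh <- 0; ds <- 0
  for (i in 1:(nchar(seq) - 1)) {
    step <- substr(seq, i, i + 1)
    dh <- dh + tab[[step]][1]
    ds <- ds + tab[[step]][2]
  }
  first <- substr(seq, 1, 1)
  last <- substr(seq, nchar(seq), nchar(seq))
  dh <- dh + init[[first]][1] + init[[last]][1]
  ds <- ds + init[[first]][2] + init[[last]][2]
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]),
              collapse = "")
  if (identical(seq, rc)) ds <- ds - 1.4
  r_ln <- 1.9872 * log(probe_conc_m)
  tm_raw <- dh * 1000 / (ds + r_ln) - 273.15
  ds_na <- ds + 0.368 * (nchar(seq) - 1) * log(na_molar)
  tm_salt <- dh * 1000 / (ds_na + r_ln) - 273.15
  list(tm_raw = tm_raw,
       tm_corrected = tm_salt - formamide_coef * formamide_pct)
}

# Brute-force both-strand full scan of a reference FASTA: every start of
# every contig, both orientations, substitution-bounded. Independent
# engine: Biostrings C matching, not the package's seed index.
oracle_loci <- function(probe, reference_fasta, max_mismatches) {
  ref <- Biostrings::readDNAStringSet(reference_fasta)
  names(ref) <- sub("\\s.*$", "", names(ref))
  n <- 0L
  for (i in seq_along(ref)) {
    for (q in c(probe, as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(probe))))) {
      m <- Biostrings::matchPattern(q, ref[[i]],
                                    max.mismatch = max_mismatches,
                                    with.indels = FALSE)
      # only alignments fully inside the contig are loci (matchPattern
      # also reports out-of-bounds matches, overhang counted as mismatch)
      inside <- Biostrings::start(m) >= 1 &
        Biostrings::end(m) <= length(ref[[i]])
      n <- n + sum(inside)
    }
  }
  n
}

# Literal re-evaluation of the three thermodynamic screening predicates.
oracle_screen_pass <- function(seq, conditions, params) {
  gc <- sum(strsplit(seq, "")[[1]] %in% c("G", "C")) / nchar(seq)
  tm <- oracle_tm(seq, na_molar = conditions$na_molar,
                  formamide_pct = conditions$formamide_pct,
                  probe_conc_m = params$probe_conc_m,
                  formamide_coef = params$formamide_coef)$tm_corrected
  runs <- rle(strsplit(seq, "")[[1]])$lengths
  gc >= params$gc_min && gc <= params$gc_max &&
    tm >= conditions$temperature_c + params$tm_margin_c &&
    max(runs) <= params$max_homopolymer
}

random_seq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}
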