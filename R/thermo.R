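# Unified nearest-neighbor duplex parameters (two-state model, 1 M NaCl
# reference). dH in kcal/mol, dS in cal/(mol K). The 16 stacked
# dinucleotides collapse to 10 unique values by strand complementarity.
NN_DH <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
NN_DS <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)
# Duplex initiation, keyed by terminal base pair.
NN_INIT_DH <- c(G = 0.1, C = 0.1, A = 2.3, T = 2.3)
NN_INIT_DS <- c(G = -2.8, C = -2.8, A = 4.1, T = 4.1)
GAS_CONSTANT <- 1.9872  # cal/(mol K)

#' GC content of DNA sequences
#'
#' @param seq Character vector of DNA sequences over `{A,C,G,T}`.
#' @return Numeric vector of GC fractions in `[0, 1]`.
#' @examples
#' gc_content(c("ATGC", "GGCC"))
#' @export
gc_content <- function(seq) {
  if (any(!nzchar(seq)) || length(seq) == 0) {
    abort("`seq` must be non-empty sequences.")
  }
  seq <- toupper(seq)
  if (any(grepl("[^ACGT]", seq))) {
    abort("`seq` must contain only A, C, G, T.")
  }
  vapply(seq, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    sum(b == "G" | b == "C") / length(b)
  }, numeric(1), USE.NAMES = FALSE)
}

# Sum of stacked-dinucleotide and initiation terms for one sequence.
nn_sums <- function(s) {
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(b)
  steps <- paste0(b[-n], b[-1])
  dh <- sum(NN_DH[steps]) + NN_INIT_DH[[b[1]]] + NN_INIT_DH[[b[n]]]
  ds <- sum(NN_DS[steps]) + NN_INIT_DS[[b[1]]] + NN_INIT_DS[[b[n]]]
  c(dh = dh, ds = ds)
}

is_self_complementary <- function(seq) {
  seq == reverse_complement(seq)
}

#' Nearest-neighbor melting temperature with salt and formamide corrections
#'
#' Computes the two-state duplex melting temperature from unified
#' nearest-neighbor enthalpy/entropy parameters,
#' `Tm = dH / (dS + R ln(C_T / x)) - 273.15`,
#' at probe concentration `params$probe_conc_m` with the probe in excess
#' over its target (`x = 1`; self-complementary sequences additionally
#' receive the symmetry entropy term of -1.4 cal/(mol K)). `tm_raw_c` is
#' the 1 M Na+ reference value. `tm_corrected_c` applies the selected
#' monovalent-salt correction (`salt_method`) at `conditions$na_molar`,
#' then subtracts the linear formamide penalty
#' `formamide_coef * formamide_pct`.
#'
#' @param seq Character vector of DNA sequences (length >= 8, no `N`).
#' @param conditions An [hcr_conditions()] object.
#' @param params A [design_params()] object (supplies the probe
#'   concentration, salt-correction method and formamide coefficient).
#' @return A tibble with columns `seq`, `tm_raw_c`, `tm_corrected_c`.
#' @examples
#' melting_temperature("ACGTGCTAGCTAGGCTAGGCTAGGA", hcr_conditions())
#' @export
melting_temperature <- function(seq, conditions = hcr_conditions(),
                                params = design_params()) {
  stopifnot(inherits(conditions, "hcr_conditions"),
            inherits(params, "design_params"))
  seq <- toupper(seq)
  if (any(grepl("[^ACGT]", seq))) {
    abort("`seq` must contain only A, C, G, T (no N) for Tm computation.")
  }
  if (any(nchar(seq) < 6)) abort("Tm requires sequences of length >= 6.")
  sums <- vapply(seq, nn_sums, c(dh = 0, ds = 0), USE.NAMES = FALSE)
  dh <- sums[1L, ]
  ds <- sums[2L, ]
  selfc <- is_self_complementary(seq)
  ds[selfc] <- ds[selfc] - 1.4
  rln <- GAS_CONSTANT * log(params$probe_conc_m)
  tm_raw_k <- dh * 1000 / (ds + rln)
  n <- nchar(seq)
  tm_salt_k <- switch(
    params$salt_method,
    santalucia = {
      ds_na <- ds + 0.368 * (n - 1) * log(conditions$na_molar)
      dh * 1000 / (ds_na + rln)
    },
    owczarzy = {
      fgc <- gc_content(seq)
      lna <- log(conditions$na_molar)
      1 / (1 / tm_raw_k + (4.29 * fgc - 3.95) * 1e-5 * lna +
             9.40e-6 * lna^2)
    }
  )
  tibble(
    seq = seq,
    tm_raw_c = tm_raw_k - 273.15,
    tm_corrected_c = tm_salt_k - 273.15 -
      params$formamide_coef * conditions$formamide_pct
  )
}

#' Enumerate candidate probe windows on transcripts
#'
#' Emits one candidate per start position `0 ... length - probe_len` of
#' each transcript, in 0-based half-open transcript coordinates. Windows
#' containing `N` are excluded (their melting temperature is undefined).
#' A transcript shorter than `probe_len` contributes no windows and raises
#' a warning.
#'
#' @param transcripts Transcript tibble from [read_transcripts()] or
#'   [transcript_tbl()].
#' @param params A [design_params()] object (supplies `probe_len`).
#' @return A tibble of candidates: `transcript_id`, `start`, `end`
#'   (half-open window), `target_seq` (the transcript subsequence) and
#'   `binding_seq` (its reverse complement, the probe's binding region).
#' @examples
#' tx <- transcript_tbl("t1", strrep("ACGT", 20))
#' enumerate_windows(tx)
#' @export
enumerate_windows <- function(transcripts, params = design_params()) {
  stopifnot(inherits(params, "design_params"))
  validate_transcripts(transcripts)
  k <- params$probe_len
  per_tx <- lapply(seq_len(nrow(transcripts)), function(i) {
    s <- transcripts$sequence[i]
    len <- nchar(s)
    if (len < k) {
      warn(paste0("Transcript '", transcripts$id[i], "' (", len,
                  " nt) is shorter than probe_len = ", k,
                  "; no candidate windows."))
      return(NULL)
    }
    starts <- 0:(len - k)
    target <- substring(s, starts + 1L, starts + k)
    keep <- !grepl("N", target, fixed = TRUE)
    tibble(
      transcript_id = transcripts$id[i],
      start = as.integer(starts[keep]),
      end = as.integer(starts[keep] + k),
      target_seq = target[keep]
    )
  })
  out <- bind_rows(per_tx)
  if (nrow(out) == 0) {
    return(tibble(transcript_id = character(), start = integer(),
                  end = integer(), target_seq = character(),
                  binding_seq = character()))
  }
  out$binding_seq <- reverse_complement(out$target_seq)
  out
}

longest_homopolymer <- function(seq) {
  vapply(seq, function(s) {
    max(rle(strsplit(s, "", fixed = TRUE)[[1]])$lengths)
  }, integer(1), USE.NAMES = FALSE)
}

#' Screen candidate windows against hybridization conditions
#'
#' Annotates every candidate with its GC fraction, raw and corrected
#' melting temperatures, and the thermodynamic verdict. A candidate passes
#' when its GC lies in `[gc_min, gc_max]`, its corrected Tm is at least
#' `temperature_c + tm_margin_c`, and its longest homopolymer run is at
#' most `max_homopolymer`. All candidates are retained with verdicts; no
#' silent dropping. The verdict depends only on the candidate's own
#' sequence and the parameters.
#'
#' @param candidates Candidate tibble from [enumerate_windows()].
#' @param conditions An [hcr_conditions()] object.
#' @param params A [design_params()] object.
#' @return The candidate tibble with added columns `gc`, `tm_raw_c`,
#'   `tm_corrected_c`, `homopolymer`, `passed_thermo`.
#' @export
screen_candidates <- function(candidates, conditions = hcr_conditions(),
                              params = design_params()) {
  stopifnot(inherits(conditions, "hcr_conditions"),
            inherits(params, "design_params"))
  if (nrow(candidates) == 0) {
    return(mutate(candidates, gc = numeric(0), tm_raw_c = numeric(0),
                  tm_corrected_c = numeric(0), homopolymer = integer(0),
                  passed_thermo = logical(0)))
  }
  tm <- melting_temperature(candidates$target_seq, conditions, params)
  candidates |>
    mutate(
      gc = gc_content(.data$target_seq),
      tm_raw_c = tm$tm_raw_c,
      tm_corrected_c = tm$tm_corrected_c,
      homopolymer = longest_homopolymer(.data$target_seq),
      passed_thermo = .data$gc >= params$gc_min &
        .data$gc <= params$gc_max &
        .data$tm_corrected_c >= conditions$temperature_c + params$tm_margin_c &
        .data$homopolymer <= params$max_homopolymer
    )
}
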