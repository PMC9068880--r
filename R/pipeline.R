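# End-to-end design: enumerate -> thermodynamic screen -> uniqueness ->
# pair -> region designation -> selection -> oligo assembly -> outputs.

#' Design an HCR v3 probe set for each transcript
#'
#' Runs the full pipeline on a transcript tibble: enumerate candidate
#' windows, screen them against the hybridization conditions, drop
#' multi-mapping candidates against the reference (built-in k-mer matcher
#' or imported SAM hits), pair adjacent survivors with the 2-nt spacer,
#' designate regions, select up to `max_pairs` non-overlapping pairs with
#' ORF > 3' UTR > 5' UTR priority, and append the amplifier's
#' split-initiator arms. Each transcript is designed independently; the
#' pair cap applies per transcript.
#'
#' @param transcripts Transcript tibble from [read_transcripts()].
#' @param reference Path to a reference FASTA, or a prebuilt
#'   `reference_index`, used by the built-in specificity matcher. May be
#'   `NULL` when `sam` is given, or when both are `NULL` the uniqueness
#'   stage is skipped with a warning (every candidate treated as unique).
#' @param sam Optional path to a SAM file of candidate alignments from an
#'   external aligner (see [import_sam_hits()]); overrides `reference`.
#' @param amp Amplifier name (resolved against `amplifiers`) or an
#'   [amplifier()] object.
#' @param amplifiers Named amplifier list, default the shipped B1-B5 set.
#' @param conditions An [hcr_conditions()] object.
#' @param params A [design_params()] object.
#' @return A `probe_set` whose `report` element is the design-funnel
#'   tibble (one row per transcript) and which carries all intermediate
#'   verdicts in `candidates`.
#' @examples
#' fx <- generate_fixture(seed = 1, length = 800, gc = 0.55,
#'                        cds = c(100, 700), n_duplications = 0,
#'                        dir = tempdir())
#' ps <- design_probes(fx$transcript, reference = fx$genome_path)
#' glance(ps)
#' @export
design_probes <- function(transcripts, reference = NULL, sam = NULL,
                          amp = "B1", amplifiers = load_amplifiers(),
                          conditions = hcr_conditions(),
                          params = design_params()) {
  validate_transcripts(transcripts)
  amp <- get_amplifier(amp, amplifiers)
  candidates <- enumerate_windows(transcripts, params)
  candidates <- screen_candidates(candidates, conditions, params)

  if (!is.null(sam)) {
    hits <- import_sam_hits(sam)
    candidates <- apply_uniqueness(candidates, params = params, hits = hits)
  } else if (!is.null(reference)) {
    index <- if (inherits(reference, "reference_index")) reference
             else build_index(reference)
    candidates <- apply_uniqueness(candidates, index, params)
  } else {
    warn("No reference or SAM given; skipping the uniqueness filter.")
    candidates$n_loci <- NA_integer_
    candidates$unique <- candidates$passed_thermo
  }

  pairs <- pair_candidates(candidates, params)
  pairs <- designate_region(pairs, transcripts, params)
  ps <- select_pairs(pairs, params, transcripts = transcripts)
  if (nrow(ps$pairs) > 0) {
    ps$pairs <- attach_initiators(ps$pairs, amp, amplifiers)
  }
  ps$candidates <- candidates
  ps$conditions <- conditions
  ps$report <- design_report(transcripts, candidates, pairs, ps, params)
  ps
}

# One funnel row per transcript; invariants n_windows >= n_pass_thermo >=
# n_unique and n_pairs_selected <= min(n_pairs_candidate, max_pairs).
design_report <- function(transcripts, candidates, pairs, ps, params) {
  per_tx <- function(id) {
    cx <- candidates[candidates$transcript_id == id, , drop = FALSE]
    px <- pairs[pairs$transcript_id == id, , drop = FALSE]
    sx <- ps$pairs[ps$pairs$transcript_id == id, , drop = FALSE]
    reg <- table(factor(sx$region,
                        levels = c("UTR5", "ORF", "UTR3", "UNANNOTATED")))
    tibble(
      transcript_id = id,
      n_windows = nrow(cx),
      n_pass_thermo = sum(cx$passed_thermo),
      n_unique = sum(cx$unique %in% TRUE),
      n_pairs_candidate = nrow(px),
      n_pairs_selected = nrow(sx),
      n_utr5 = as.integer(reg[["UTR5"]]),
      n_orf = as.integer(reg[["ORF"]]),
      n_utr3 = as.integer(reg[["UTR3"]]),
      n_unannotated = as.integer(reg[["UNANNOTATED"]])
    )
  }
  rep <- bind_rows(lapply(transcripts$id, per_tx))
  attr(rep, "parameters_echo") <- unclass(params)
  attr(rep, "tool_version") <-
    as.character(utils::packageVersion("hcrprobes"))
  rep
}

#' Write the order-ready output files of a probe set
#'
#' Writes four files under `out_prefix`:
#' * `<prefix>_order.tsv` — order sheet with columns `oligo_name`,
#'   `well` (A1..H12 column-major, overflowing to further plates) and
#'   `sequence`;
#' * `<prefix>_probes.bed` — binding footprints in transcript
#'   coordinates, 0-based half-open, one line per probe, name encoding
#'   pair index and P1/P2;
#' * `<prefix>_oligos.fasta` — the final oligo sequences;
#' * `<prefix>_report.json` — the design report (funnel counts, per-region
#'   counts, parameter echo, tool version, timestamp).
#'
#' @param probe_set A non-empty `probe_set` from [design_probes()].
#' @param out_prefix Output path prefix (directories are created).
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_probe_outputs <- function(probe_set, out_prefix) {
  stopifnot(inherits(probe_set, "probe_set"))
  pairs <- probe_set$pairs
  if (nrow(pairs) == 0) {
    abort("Probe set is empty; nothing to write.")
  }
  if (!all(c("oligo1", "oligo2") %in% names(pairs))) {
    abort("Probe set lacks assembled oligos; run attach_initiators().")
  }
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)

  oligos <- tibble(
    oligo_name = as.vector(rbind(pairs$oligo1_name, pairs$oligo2_name)),
    sequence = as.vector(rbind(pairs$oligo1, pairs$oligo2))
  )
  oligos$well <- plate_wells(nrow(oligos))

  tsv <- paste0(out_prefix, "_order.tsv")
  readr::write_tsv(oligos[, c("oligo_name", "well", "sequence")], tsv)

  bed <- paste0(out_prefix, "_probes.bed")
  bed_tbl <- tibble(
    chrom = rep(pairs$transcript_id, each = 2),
    start = as.vector(rbind(pairs$p1_start, pairs$p2_start)),
    end = as.vector(rbind(pairs$p1_end, pairs$p2_end)),
    name = as.vector(rbind(sprintf("pair%03d_P1", pairs$index),
                           sprintf("pair%03d_P2", pairs$index)))
  )
  readr::write_tsv(bed_tbl, bed, col_names = FALSE)

  fa <- paste0(out_prefix, "_oligos.fasta")
  xs <- Biostrings::DNAStringSet(stats::setNames(oligos$sequence,
                                                 oligos$oligo_name))
  Biostrings::writeXStringSet(xs, fa)

  js <- paste0(out_prefix, "_report.json")
  write_design_report(probe_set, js)

  invisible(c(order_sheet = tsv, bed = bed, fasta = fa, report = js))
}

# A1..H12 column-major, then plate 2, 3, ...
plate_wells <- function(n) {
  rows <- LETTERS[1:8]
  one_plate <- paste0(rep(rows, times = 12), rep(1:12, each = 8))
  plate <- (seq_len(n) - 1) %/% 96 + 1
  well <- one_plate[(seq_len(n) - 1) %% 96 + 1]
  ifelse(plate == 1, well, paste0("P", plate, "_", well))
}

write_design_report <- function(probe_set, path) {
  rep <- probe_set$report
  payload <- list(
    tool = "hcrprobes",
    tool_version = attr(rep, "tool_version") %||%
      as.character(utils::packageVersion("hcrprobes")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    conditions = unclass(probe_set$conditions),
    parameters_echo = attr(rep, "parameters_echo") %||%
      unclass(probe_set$params),
    per_region_counts = as.list(probe_set$per_region_counts),
    transcripts = rep
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the design pipeline from file inputs
#'
#' File-level wrapper used by the command-line interface: reads the
#' transcripts and CDS annotation, runs [design_probes()], and writes the
#' output files when `out_prefix` is given. A run that yields zero pairs
#' is a warning, not an error (the report is still written).
#'
#' @param fasta Path to the transcript FASTA.
#' @param cds CDS annotation (see [read_transcripts()]).
#' @param genome Path to a reference FASTA for the built-in specificity
#'   filter.
#' @param sam Path to SAM alignments of candidates (alternative to
#'   `genome`).
#' @param amp Amplifier name, e.g. `"B1"`.
#' @param amplifier_config Optional YAML overriding the shipped
#'   amplifiers.
#' @param conditions,params See [hcr_conditions()], [design_params()].
#' @param out_prefix Optional output prefix for [write_probe_outputs()];
#'   the JSON report is written even for an empty set.
#' @return The `probe_set`, invisibly.
#' @export
run_design <- function(fasta, cds = NULL, genome = NULL, sam = NULL,
                       amp = "B1", amplifier_config = NULL,
                       conditions = hcr_conditions(),
                       params = design_params(), out_prefix = NULL) {
  amplifiers <- if (is.null(amplifier_config)) load_amplifiers()
                else load_amplifiers(amplifier_config)
  transcripts <- read_transcripts(fasta, cds)
  ps <- design_probes(transcripts, reference = genome, sam = sam,
                      amp = amp, amplifiers = amplifiers,
                      conditions = conditions, params = params)
  if (!is.null(out_prefix)) {
    dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
    if (nrow(ps$pairs) > 0) {
      write_probe_outputs(ps, out_prefix)
    } else {
      write_design_report(ps, paste0(out_prefix, "_report.json"))
    }
  }
  invisible(ps)
}
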