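# HCR v3 split-initiator probe pairs: two adjacent 25-mer binding regions
# separated by a 2-nt spacer on the transcript; each oligo carries half of
# the amplifier's initiator so the hairpin cascade only triggers when both
# probes bind side by side.

#' Load amplifier definitions
#'
#' Reads split-initiator amplifier definitions (name, upstream and
#' downstream initiator arms, arm linkers) from a YAML config. The
#' package ships a default set, the five published HCR v3.0 amplifiers
#' B1-B5 with their 36-nt initiators split into 18-nt halves; verify
#' against your amplifier lot and override via config if your definitions
#' differ (the arms are data, not code).
#'
#' @param path YAML file with an `amplifiers:` list; defaults to the
#'   shipped set.
#' @return A named list of `amplifier` objects.
#' @examples
#' names(load_amplifiers())
#' @export
load_amplifiers <- function(path = system.file("extdata", "amplifiers.yaml",
                                               package = "hcrprobes")) {
  if (!file.exists(path)) abort(paste0("Amplifier config not found: ", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$amplifiers) || length(cfg$amplifiers) == 0) {
    abort("Amplifier config must contain a non-empty `amplifiers:` list.")
  }
  amps <- lapply(cfg$amplifiers, function(a) {
    amplifier(name = a$name, initiator_up = a$initiator_up,
              initiator_down = a$initiator_down,
              arm_spacer_up = a$arm_spacer_up %||% "AA",
              arm_spacer_down = a$arm_spacer_down %||% "AA")
  })
  nm <- vapply(amps, `[[`, character(1), "name")
  if (anyDuplicated(nm)) abort("Amplifier names must be unique.")
  stats::setNames(amps, nm)
}

#' Define a split-initiator amplifier
#'
#' @param name Amplifier name (e.g. `"B1"`).
#' @param initiator_up Arm prepended to the upstream (5'-ward) probe.
#' @param initiator_down Arm appended to the downstream (3'-ward) probe.
#' @param arm_spacer_up,arm_spacer_down Short DNA linkers placed between
#'   arm and binding region (may be empty strings).
#' @return An `amplifier` object.
#' @export
amplifier <- function(name, initiator_up, initiator_down,
                      arm_spacer_up = "AA", arm_spacer_down = "AA") {
  initiator_up <- toupper(initiator_up)
  initiator_down <- toupper(initiator_down)
  arm_spacer_up <- toupper(arm_spacer_up %||% "")
  arm_spacer_down <- toupper(arm_spacer_down %||% "")
  if (!nzchar(initiator_up) || !nzchar(initiator_down)) {
    abort("Both initiator arms must be non-empty.")
  }
  for (s in c(initiator_up, initiator_down, arm_spacer_up, arm_spacer_down)) {
    if (grepl("[^ACGT]", s)) {
      abort(paste0("Amplifier '", name, "' contains non-ACGT characters."))
    }
  }
  structure(list(name = as.character(name), initiator_up = initiator_up,
                 initiator_down = initiator_down,
                 arm_spacer_up = arm_spacer_up,
                 arm_spacer_down = arm_spacer_down),
            class = "amplifier")
}

get_amplifier <- function(name, amplifiers = load_amplifiers()) {
  if (inherits(name, "amplifier")) return(name)
  if (!name %in% names(amplifiers)) {
    abort(paste0("Unknown amplifier '", name, "'. Available: ",
                 paste(names(amplifiers), collapse = ", "), "."))
  }
  amplifiers[[name]]
}

#' Pair adjacent passing candidates into probe pairs
#'
#' Emits a pair for every pair of candidate windows `(i, i + probe_len +
#' spacer_len)` on the same transcript where both windows passed every
#' upstream filter (thermodynamics, and uniqueness when computed). The
#' two binding footprints are therefore separated by exactly `spacer_len`
#' nt of transcript. Pairs are ordered by the upstream window's start;
#' overlapping pairs are permitted at this stage — deduplication happens
#' at selection.
#'
#' @param candidates Candidate tibble carrying `passed_thermo` (and
#'   optionally `unique`) verdicts.
#' @param params A [design_params()] object.
#' @return A tibble of pairs: window coordinates of both members
#'   (`p1_*` = 5'-ward, `p2_*` = 3'-ward), their binding sequences, and
#'   the overall `footprint_start`/`footprint_end`.
#' @export
pair_candidates <- function(candidates, params = design_params()) {
  stopifnot(inherits(params, "design_params"))
  step <- params$probe_len + params$spacer_len
  ok <- candidates$passed_thermo %||% rep(TRUE, nrow(candidates))
  if ("unique" %in% names(candidates)) {
    ok <- ok & !is.na(candidates$unique) & candidates$unique
  }
  eligible <- candidates[which(ok), , drop = FALSE]
  empty <- tibble(
    transcript_id = character(), p1_start = integer(), p1_end = integer(),
    p2_start = integer(), p2_end = integer(),
    p1_binding = character(), p2_binding = character(),
    footprint_start = integer(), footprint_end = integer()
  )
  if (nrow(eligible) == 0) return(empty)
  per_tx <- lapply(split(eligible, eligible$transcript_id), function(e) {
    i1 <- match(e$start + step, e$start)
    keep <- which(!is.na(i1))
    if (length(keep) == 0) return(NULL)
    tibble(
      transcript_id = e$transcript_id[keep],
      p1_start = e$start[keep], p1_end = e$end[keep],
      p2_start = e$start[i1[keep]], p2_end = e$end[i1[keep]],
      p1_binding = e$binding_seq[keep],
      p2_binding = e$binding_seq[i1[keep]],
      footprint_start = e$start[keep],
      footprint_end = e$end[i1[keep]]
    )
  })
  out <- bind_rows(per_tx)
  if (nrow(out) == 0) return(empty)
  arrange(out, .data$transcript_id, .data$p1_start)
}

#' Append split-initiator arms to probe pairs
#'
#' Assembles the order-ready oligos by exact concatenation, 5' to 3':
#' `oligo1 = initiator_up + arm_spacer_up + p1_binding` for the 5'-ward
#' probe and `oligo2 = p2_binding + arm_spacer_down + initiator_down` for
#' the 3'-ward probe. No other edits are made, so each oligo contains its
#' binding region verbatim. Oligo names encode transcript, pair index and
#' P1/P2 (e.g. `geneX_B1_pair001_P1`).
#'
#' @param pairs Pair tibble from [pair_candidates()] or [select_pairs()];
#'   rows lacking an `index` column are numbered in order.
#' @param amp An `amplifier` object, or an amplifier name resolved
#'   against `amplifiers`.
#' @param amplifiers Named amplifier list used when `amp` is a name.
#' @return `pairs` with added columns `amplifier`, `oligo1_name`,
#'   `oligo1`, `oligo2_name`, `oligo2`.
#' @export
attach_initiators <- function(pairs, amp, amplifiers = load_amplifiers()) {
  amp <- get_amplifier(amp, amplifiers)
  if (!"index" %in% names(pairs)) {
    pairs$index <- seq_len(nrow(pairs))
  }
  pairs |>
    mutate(
      amplifier = amp$name,
      oligo1_name = sprintf("%s_%s_pair%03d_P1", .data$transcript_id,
                            amp$name, .data$index),
      oligo1 = paste0(amp$initiator_up, amp$arm_spacer_up,
                      .data$p1_binding),
      oligo2_name = sprintf("%s_%s_pair%03d_P2", .data$transcript_id,
                            amp$name, .data$index),
      oligo2 = paste0(.data$p2_binding, amp$arm_spacer_down,
                      amp$initiator_down)
    )
}
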