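# Off-target screening against a reference, mirroring the genome-alignment
# step of the design pipeline at desk scale: an exact k-mer seed index plus
# substitution-bounded verification, with a SAM import path for users who
# run an external aligner (e.g. Bowtie2) at genome scale.

#' Build a k-mer seed index over a reference
#'
#' Indexes every k-mer of the forward strand of each contig (k-mers
#' containing `N` are skipped, so contigs are indexed around their `N`s).
#' Queries are run in both orientations — the probe sequence and its
#' reverse complement — which covers both reference strands exactly.
#'
#' The default seed length is chosen by the pigeonhole principle: with a
#' substitution budget of `m`, a matching window of length `L` must contain
#' at least one exact seed among `m + 1` disjoint seeds of length
#' `floor(L / (m + 1))`, so seed lookup plus verification finds every
#' match the brute-force scan finds.
#'
#' @param reference_fasta Path to the reference FASTA.
#' @param k Seed length; must lie in `[4, probe_len]`. Default 8
#'   (= `floor(25 / 3)`, exact for 25-mers at <= 2 substitutions).
#' @return A `reference_index` object (contig sequences plus a k-mer hash).
#' @export
build_index <- function(reference_fasta, k = 8L) {
  k <- as.integer(k)
  if (k < 4L) abort("`k` must be >= 4.")
  if (!file.exists(reference_fasta)) {
    abort(paste0("Reference FASTA not found: ", reference_fasta))
  }
  seqs <- Biostrings::readDNAStringSet(reference_fasta)
  if (length(seqs) == 0 || sum(Biostrings::width(seqs)) == 0) {
    abort("Reference FASTA is empty.")
  }
  contigs <- stats::setNames(toupper(as.character(seqs)),
                             sub("\\s.*$", "", names(seqs)))
  ht <- new.env(hash = TRUE, parent = emptyenv(), size = 4 * sum(nchar(contigs)))
  for (ci in seq_along(contigs)) {
    s <- contigs[[ci]]
    len <- nchar(s)
    if (len < k) next
    starts <- 0:(len - k)
    kmers <- substring(s, starts + 1L, starts + k)
    ok <- !grepl("N", kmers, fixed = TRUE)
    kmers <- kmers[ok]
    pos <- starts[ok]
    for (j in seq_along(kmers)) {
      key <- kmers[j]
      ht[[key]] <- c(ht[[key]], ci * 2^24 + pos[j])  # packed (contig, pos)
    }
  }
  structure(
    list(source = reference_fasta, k = k, contigs = contigs, hash = ht),
    class = "reference_index"
  )
}

#' @export
print.reference_index <- function(x, ...) {
  cat(sprintf("k-mer reference index: %d contig(s), %s bp total, k = %d\n",
              length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ","), x$k))
  invisible(x)
}

hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

# All (contig, start, strand) loci where `q` (with reverse complement
# `qrc`) matches the reference with <= max_mismatches substitutions.
# Seed offsets are the disjoint pigeonhole positions 0, k, 2k, ...
# Returns parallel vectors, sorted; kept tibble-free for speed.
match_loci_one <- function(q, qrc, index, max_mismatches) {
  L <- nchar(q)
  k <- index$k
  n_seeds <- L %/% k
  if (n_seeds < max_mismatches + 1L) {
    warn(paste0("Seed length ", k, " gives only ", n_seeds,
                " disjoint seeds for a ", L, "-mer; matches with up to ",
                max_mismatches, " mismatches may be missed."))
  }
  offsets <- (seq_len(n_seeds) - 1L) * k
  seen <- character(0)
  h_ci <- integer(0); h_pos <- integer(0); h_strand <- character(0)
  for (orient in c("+", "-")) {
    qq <- if (orient == "+") q else qrc
    qraw <- charToRaw(qq)
    for (o in offsets) {
      seed <- substr(qq, o + 1L, o + k)
      packed <- index$hash[[seed]]
      if (is.null(packed)) next
      ci <- packed %/% 2^24
      cand_start <- packed %% 2^24 - o
      for (j in seq_along(packed)) {
        st <- cand_start[j]
        contig <- index$contigs[[ci[j]]]
        if (st < 0 || st + L > nchar(contig)) next
        key <- paste0(ci[j], ":", st, orient)
        if (key %in% seen) next
        seen <- c(seen, key)
        ref <- substr(contig, st + 1L, st + L)
        if (sum(charToRaw(ref) != qraw) <= max_mismatches) {
          h_ci <- c(h_ci, ci[j])
          h_pos <- c(h_pos, as.integer(st))
          h_strand <- c(h_strand, orient)
        }
      }
    }
  }
  ord <- order(h_ci, h_pos, h_strand)
  list(contig = names(index$contigs)[h_ci[ord]], position = h_pos[ord],
       strand = h_strand[ord])
}

#' Count reference loci matched by candidate probes
#'
#' For each candidate window, finds every reference locus where the
#' 25-mer (in either orientation) matches with at most `max_mismatches`
#' substitutions, by seed lookup plus full-window verification. Seed
#' extensions that reach the same alignment are collapsed, so each locus
#' is a distinct `(contig, position, strand)` triple.
#'
#' @param candidates Candidate tibble (needs a `target_seq` column), or a
#'   character vector of sequences.
#' @param index A `reference_index` from [build_index()].
#' @param max_mismatches Substitution budget (default from
#'   [design_params()]).
#' @return A tibble with one row per candidate: `candidate_id`, `n_loci`,
#'   and a `loci` list-column of per-locus tibbles.
#' @export
count_hits <- function(candidates, index, max_mismatches = 2L) {
  stopifnot(inherits(index, "reference_index"))
  if (is.character(candidates)) {
    candidates <- tibble(transcript_id = "query",
                         start = seq_along(candidates) - 1L,
                         target_seq = candidates)
  }
  ids <- candidate_ids(candidates)
  qrc <- if ("binding_seq" %in% names(candidates)) candidates$binding_seq
         else reverse_complement(candidates$target_seq)
  loci <- Map(match_loci_one, candidates$target_seq, qrc,
              MoreArgs = list(index = index,
                              max_mismatches = as.integer(max_mismatches)))
  loci <- unname(loci)
  tibble(
    candidate_id = ids,
    n_loci = vapply(loci, function(l) length(l$position), integer(1)),
    loci = lapply(loci, function(l) {
      tibble::new_tibble(l, nrow = length(l$position))
    })
  )
}

candidate_ids <- function(candidates) {
  paste0(candidates$transcript_id, ":", candidates$start, "-",
         candidates$start + nchar(candidates$target_seq))
}

#' Mark candidates that map uniquely to the reference
#'
#' Sets the `unique` verdict: a candidate is unique when its number of
#' matched reference loci is at most `params$max_hits`. Candidates with
#' zero hits are dropped by default (a probe absent from the design
#' reference cannot be vetted); set `keep_unmapped = TRUE` in
#' [design_params()] to keep them. Hits are computed only for candidates
#' that passed the thermodynamic screen (others keep `NA` verdicts); pass
#' a precomputed `hits` table (e.g. from [import_sam_hits()]) to skip the
#' built-in matcher.
#'
#' @param candidates Screened candidate tibble (from
#'   [screen_candidates()]; a bare [enumerate_windows()] tibble is
#'   treated as all-passing).
#' @param index A `reference_index`, or `NULL` when `hits` is given.
#' @param params A [design_params()] object.
#' @param hits Optional tibble `candidate_id`, `n_loci` replacing the
#'   built-in matcher (candidates absent from it count as unmapped).
#' @return `candidates` with added columns `n_loci` and `unique`.
#' @export
apply_uniqueness <- function(candidates, index = NULL,
                             params = design_params(), hits = NULL) {
  stopifnot(inherits(params, "design_params"))
  if (!"passed_thermo" %in% names(candidates)) {
    candidates$passed_thermo <- TRUE
  }
  candidates$n_loci <- NA_integer_
  candidates$unique <- NA
  todo <- which(candidates$passed_thermo)
  if (length(todo) > 0) {
    if (!is.null(hits)) {
      ids <- candidate_ids(candidates[todo, ])
      m <- match(ids, hits$candidate_id)
      n_loci <- ifelse(is.na(m), 0L, hits$n_loci[m])
    } else {
      if (is.null(index)) abort("Provide either `index` or `hits`.")
      n_loci <- count_hits(candidates[todo, ], index,
                           params$max_mismatches)$n_loci
    }
    candidates$n_loci[todo] <- as.integer(n_loci)
    candidates$unique[todo] <- n_loci <= params$max_hits &
      (n_loci > 0L | params$keep_unmapped)
  }
  candidates
}

#' Import alignment hit counts from a SAM file
#'
#' Adapter for external aligners: reads a SAM file whose query names are
#' candidate ids (`"<transcript>:<start>-<end>"`, as produced by the
#' pipeline's candidate FASTA export) and counts, per candidate, the
#' distinct reported alignments. Primary and secondary (flag 0x100)
#' alignments count; supplementary records (flag 0x800) are parts of an
#' already-counted alignment and do not; unmapped records (flag 0x4) give
#' zero loci. Alignments below `min_score` (the `AS` tag, when present)
#' are ignored.
#'
#' @param sam_path Path to a SAM file with header (`@SQ` lines required).
#' @param min_score Alignment-score floor applied to the `AS` tag;
#'   default `-Inf` keeps every reported alignment.
#' @return A tibble `candidate_id`, `n_loci`.
#' @export
import_sam_hits <- function(sam_path, min_score = -Inf) {
  if (!file.exists(sam_path)) abort(paste0("SAM file not found: ", sam_path))
  bam <- tryCatch(
    Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE),
    error = function(e) abort(paste0("Failed to parse SAM file ", sam_path,
                                     ": ", conditionMessage(e)))
  )
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag"), tag = "AS")
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  qname <- rec$qname
  flag <- rec$flag
  score <- rec$tag$AS
  if (is.null(score)) score <- rep(NA_real_, length(qname))
  unmapped <- bitwAnd(flag, 0x4L) > 0L
  supplementary <- bitwAnd(flag, 0x800L) > 0L
  pass_score <- is.na(score) | score >= min_score
  counted <- !unmapped & !supplementary & pass_score
  tab <- table(factor(qname[counted], levels = unique(qname)))
  tibble(candidate_id = names(tab), n_loci = as.integer(tab))
}
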