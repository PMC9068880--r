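# Synthetic fixtures: a random transcript with a defined CDS, embedded in
# a synthetic genome whose planted duplicated segments trigger the
# multi-mapping filter. Emulates, at desk scale, a transcript designed
# against a large reference genome; it does not emulate transcriptome
# redundancy (paralogs, isoforms) or biased base composition beyond the
# target GC.

random_dna <- function(n, gc) {
  n_gc <- round(gc * n)
  base <- sample(c("A", "T"), n, replace = TRUE)
  gc_pos <- sample.int(n, n_gc)
  base[gc_pos] <- sample(c("G", "C"), n_gc, replace = TRUE)
  paste(base, collapse = "")
}

#' Generate a reproducible design fixture
#'
#' Builds a random transcript of the requested length and GC composition
#' with a defined CDS, plus a synthetic single-contig genome consisting
#' of the transcript embedded in random flanks followed by
#' `n_duplications` segments copied from the transcript — exact second
#' copies that the multi-mapping filter must catch. The realized
#' transcript GC equals `round(gc * length) / length` by construction
#' (exact-count composition, shuffled), so it is always within 2% of the
#' target. Identical seeds give byte-identical FASTA output.
#'
#' @param seed Integer RNG seed, recorded in the manifest.
#' @param length Transcript length in nt, >= 200.
#' @param gc Target GC fraction.
#' @param cds Integer 0-based half-open CDS interval `c(start, end)`
#'   within the transcript, or `NULL` for an unannotated transcript.
#' @param n_duplications Number of transcript segments planted a second
#'   time in the genome.
#' @param dir Directory to write `transcript.fasta` and `genome.fasta`.
#' @param dup_len Length of each duplicated segment (nt).
#' @param flank Length of each random genomic flank (nt).
#' @param probe_len Probe length used to enumerate the ground-truth
#'   dropped windows.
#' @return A `fixture_manifest` list: `seed`, `transcript` (tibble),
#'   `transcript_path`, `genome_path`, `transcript_offset` (0-based start
#'   of the transcript in the genome contig), `planted_duplications`
#'   (tibble of transcript intervals copied elsewhere) and
#'   `expected_dropped_windows` (starts of every window fully inside a
#'   planted duplication).
#' @examples
#' fx <- generate_fixture(seed = 7, length = 400, gc = 0.5,
#'                        cds = c(50, 350), n_duplications = 1,
#'                        dir = tempdir())
#' fx$planted_duplications
#' @export
generate_fixture <- function(seed, length, gc = 0.55, cds = NULL,
                             n_duplications = 0, dir = tempdir(),
                             dup_len = 150L, flank = 500L,
                             probe_len = 25L) {
  len <- as.integer(length)
  rm(length)  # unshadow base::length
  if (len < 200L) abort("`length` must be >= 200.")
  if (!is.null(cds)) {
    cds <- as.integer(cds)
    if (length(cds) != 2L || cds[1] < 0L || cds[2] <= cds[1] ||
        cds[2] > len) {
      abort("`cds` must be a 0-based half-open interval within the transcript.")
    }
  }
  n_duplications <- as.integer(n_duplications)
  dup_len <- min(as.integer(dup_len), len)
  withr::local_seed(seed)

  tx_seq <- random_dna(len, gc)
  dups <- tibble(start = integer(), end = integer())
  if (n_duplications > 0) {
    starts <- integer(0)
    tries <- 0L
    while (length(starts) < n_duplications && tries < 10000L) {
      s <- sample.int(len - dup_len + 1L, 1L) - 1L
      if (all(s + dup_len <= starts | s >= starts + dup_len)) {
        starts <- c(starts, s)
      }
      tries <- tries + 1L
    }
    if (length(starts) < n_duplications) {
      abort("Could not place the requested non-overlapping duplications.")
    }
    dups <- tibble(start = sort(starts), end = sort(starts) + dup_len)
  }

  copies <- vapply(seq_len(nrow(dups)), function(i) {
    paste0(random_dna(100L, gc),
           substr(tx_seq, dups$start[i] + 1L, dups$end[i]))
  }, character(1))
  genome_seq <- paste0(random_dna(flank, gc), tx_seq, random_dna(flank, gc),
                       paste(copies, collapse = ""))

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  transcript_path <- file.path(dir, "transcript.fasta")
  genome_path <- file.path(dir, "genome.fasta")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(transcript_fixture = tx_seq)),
    transcript_path)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(chr_fixture = genome_seq)), genome_path)

  dropped <- sort(unique(unlist(lapply(seq_len(nrow(dups)), function(i) {
    if (dups$end[i] - dups$start[i] < probe_len) return(integer(0))
    dups$start[i]:(dups$end[i] - probe_len)
  }))))

  structure(
    list(
      seed = seed,
      transcript = transcript_tbl(
        "transcript_fixture", tx_seq,
        cds_start = if (is.null(cds)) NA_integer_ else cds[1],
        cds_end = if (is.null(cds)) NA_integer_ else cds[2]),
      transcript_path = transcript_path,
      genome_path = genome_path,
      transcript_offset = as.integer(flank),
      planted_duplications = dups,
      expected_dropped_windows = as.integer(dropped)
    ),
    class = "fixture_manifest"
  )
}

#' @export
print.fixture_manifest <- function(x, ...) {
  cat(sprintf(
    "Design fixture (seed %s): %d-nt transcript, %d planted duplication(s), %d ground-truth dropped window(s)\n",
    format(x$seed), x$transcript$length, nrow(x$planted_duplications),
    length(x$expected_dropped_windows)))
  invisible(x)
}
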