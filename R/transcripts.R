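#' Read transcripts from FASTA with optional CDS annotation
#'
#' Reads one record per FASTA entry, uppercases the sequence, converts U to
#' T, and attaches coding-sequence (CDS) coordinates by record id. CDS
#' input follows the human convention (1-based, inclusive, as in
#' GenBank-style annotations) and is converted on ingestion to the 0-based
#' half-open interval used everywhere else in the package and in BED
#' output.
#'
#' @param fasta_path Path to a FASTA file of sense-strand mRNA sequences.
#' @param cds CDS annotation, one of:
#'   * `NULL` — no CDS; regions are reported as `UNANNOTATED`;
#'   * a string `"START-END"` (1-based inclusive) applied to every record;
#'   * a data frame with columns `id` and either `start`/`end` (1-based
#'     inclusive) or a single `cds` column of `"START-END"` strings;
#'   * a path to a two-column tab-separated file (`id`, `START-END`),
#'     without a header.
#'
#' @return A tibble with one row per record: `id`, `sequence` (uppercase
#'   DNA), `length`, and 0-based half-open `cds_start`/`cds_end` (`NA` when
#'   unannotated).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">geneX", strrep("ACGT", 30)), fa)
#' read_transcripts(fa, cds = "21-80")
#' @export
read_transcripts <- function(fasta_path, cds = NULL) {
  if (!file.exists(fasta_path)) {
    abort(paste0("FASTA file not found: ", fasta_path))
  }
  seqs <- tryCatch(
    Biostrings::readBStringSet(fasta_path),
    error = function(e) abort(paste0("Malformed FASTA in ", fasta_path, ": ",
                                     conditionMessage(e)))
  )
  if (length(seqs) == 0) abort(paste0("No FASTA records in ", fasta_path))
  ids <- sub("\\s.*$", "", names(seqs))
  sequences <- chartr("u", "t", toupper(as.character(seqs)))
  sequences <- chartr("U", "T", sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    abort(paste0("Record '", ids[which(bad)[1]],
                 "' contains characters outside {A,C,G,T,N,U}."))
  }
  out <- tibble(
    id = unname(ids),
    sequence = unname(sequences),
    length = unname(nchar(sequences)),
    cds_start = NA_integer_,
    cds_end = NA_integer_
  )
  ann <- normalize_cds_annotation(cds, out$id)
  if (!is.null(ann)) {
    idx <- match(ann$id, out$id)
    if (anyNA(idx)) {
      abort(paste0("CDS annotation names unknown record(s): ",
                   paste(ann$id[is.na(idx)], collapse = ", ")))
    }
    out$cds_start[idx] <- ann$cds_start
    out$cds_end[idx] <- ann$cds_end
  }
  validate_transcripts(out)
  out
}

# CDS spec (see read_transcripts) -> tibble(id, cds_start, cds_end), 0-based half-open
normalize_cds_annotation <- function(cds, record_ids) {
  if (is.null(cds)) return(NULL)
  if (is.character(cds) && length(cds) == 1 && !file.exists(cds)) {
    iv <- parse_cds_string(cds)
    return(tibble(id = record_ids, cds_start = iv[1] - 1L, cds_end = iv[2]))
  }
  if (is.character(cds) && length(cds) == 1) {
    tab <- utils::read.table(cds, sep = "\t", header = FALSE,
                             col.names = c("id", "cds"),
                             colClasses = "character")
    cds <- tab
  }
  if (!is.data.frame(cds)) abort("Unsupported `cds` annotation format.")
  if ("cds" %in% names(cds)) {
    ivs <- lapply(cds$cds, parse_cds_string)
    tibble(id = as.character(cds$id),
           cds_start = vapply(ivs, `[`, integer(1), 1L) - 1L,
           cds_end = vapply(ivs, `[`, integer(1), 2L))
  } else if (all(c("start", "end") %in% names(cds))) {
    tibble(id = as.character(cds$id),
           cds_start = as.integer(cds$start) - 1L,
           cds_end = as.integer(cds$end))
  } else {
    abort("CDS data frame needs columns `id` and `start`/`end` (or `cds`).")
  }
}

parse_cds_string <- function(x) {
  m <- regmatches(x, regexec("^\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", x))[[1]]
  if (length(m) != 3) {
    abort(paste0("CDS must be 'START-END' (1-based inclusive), got: ", x))
  }
  iv <- as.integer(m[2:3])
  if (iv[1] < 1L || iv[2] < iv[1]) {
    abort(paste0("Invalid CDS interval (must be 1-based inclusive): ", x))
  }
  iv
}

validate_transcripts <- function(transcripts) {
  stopifnot(is.data.frame(transcripts),
            all(c("id", "sequence", "cds_start", "cds_end") %in%
                  names(transcripts)))
  len <- nchar(transcripts$sequence)
  has_cds <- !is.na(transcripts$cds_start)
  bad <- has_cds & (transcripts$cds_start < 0L |
                      transcripts$cds_start >= transcripts$cds_end |
                      transcripts$cds_end > len)
  if (any(bad)) {
    abort(paste0("CDS interval outside sequence for record '",
                 transcripts$id[which(bad)[1]], "' (length ",
                 len[which(bad)[1]], ")."))
  }
  invisible(transcripts)
}

#' Reverse complement of DNA sequences
#'
#' Standard Watson-Crick reverse complement; `N` maps to `N`. Vectorized.
#'
#' @param seq Character vector of DNA sequences over `{A,C,G,T,N}`
#'   (lowercase accepted and uppercased).
#' @return Character vector of the same length.
#' @examples
#' reverse_complement("ATGC")
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  if (any(grepl("[^ACGTN]", seq))) {
    abort("`seq` must contain only A, C, G, T, N.")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Build a transcript tibble from in-memory sequences
#'
#' Convenience constructor used by the fixture generator and tests; applies
#' the same normalization and validation as [read_transcripts()]. CDS
#' coordinates here are 0-based half-open (the package-internal
#' convention).
#'
#' @param id Record id(s).
#' @param sequence DNA string(s).
#' @param cds_start,cds_end Optional 0-based half-open CDS interval(s).
#' @return A transcript tibble (see [read_transcripts()]).
#' @export
transcript_tbl <- function(id, sequence, cds_start = NA_integer_,
                           cds_end = NA_integer_) {
  sequence <- chartr("U", "T", toupper(sequence))
  if (any(grepl("[^ACGTN]", sequence))) {
    abort("`sequence` must contain only A, C, G, T, N, U.")
  }
  out <- tibble(id = as.character(id), sequence = sequence,
                length = nchar(sequence),
                cds_start = as.integer(cds_start),
                cds_end = as.integer(cds_end))
  validate_transcripts(out)
  out
}
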