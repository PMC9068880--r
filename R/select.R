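# Region designation and final selection: each pair's footprint is
# assigned to the 5' UTR, ORF or 3' UTR of its transcript, then up to
# max_pairs non-overlapping pairs are taken greedily in region-priority
# order (ORF first, then 3' UTR, then 5' UTR, by default).

#' Designate the transcript region of each probe pair
#'
#' Assigns each pair the region (`UTR5`, `ORF`, `UTR3`) containing its
#' full binding footprint (both windows plus the spacer). A footprint
#' straddling a region boundary takes the region containing the majority
#' of its bases; an exact tie resolves to whichever tied region comes
#' first in `params$region_priority`. Pairs on transcripts without a CDS
#' are `UNANNOTATED`.
#'
#' @param pairs Pair tibble from [pair_candidates()].
#' @param transcripts Transcript tibble (provides CDS intervals).
#' @param params A [design_params()] object (tie-break order).
#' @return `pairs` with an added `region` column.
#' @export
designate_region <- function(pairs, transcripts, params = design_params()) {
  stopifnot(inherits(params, "design_params"))
  validate_transcripts(transcripts)
  m <- match(pairs$transcript_id, transcripts$id)
  if (anyNA(m)) {
    abort(paste0("Pairs reference unknown transcript(s): ",
                 paste(unique(pairs$transcript_id[is.na(m)]), collapse = ", ")))
  }
  cs <- transcripts$cds_start[m]
  ce <- transcripts$cds_end[m]
  len <- transcripts$length[m]
  s <- pairs$footprint_start
  e <- pairs$footprint_end
  ov <- function(a1, a2) pmax(0L, pmin(e, a2) - pmax(s, a1))
  overlaps <- cbind(
    UTR5 = ov(0L, ifelse(is.na(cs), 0L, cs)),
    ORF = ov(ifelse(is.na(cs), 0L, cs), ifelse(is.na(ce), 0L, ce)),
    UTR3 = ov(ifelse(is.na(ce), len, ce), len)
  )
  # tie-break: evaluate regions in priority order, keep the first maximum
  ord <- match(params$region_priority, colnames(overlaps))
  region <- params$region_priority[apply(overlaps[, ord, drop = FALSE], 1,
                                         which.max)]
  region[is.na(cs)] <- "UNANNOTATED"
  pairs$region <- factor(region,
                         levels = c("UTR5", "ORF", "UTR3", "UNANNOTATED"))
  pairs
}

#' Select the final probe set
#'
#' Greedy selection of up to `max_pairs` pairs per transcript: regions
#' are visited in `params$region_priority` order; within a region, pairs
#' are swept left to right (5' to 3') and a pair is kept when its
#' footprint is disjoint from every already-kept pair on that transcript
#' (across regions). Selection stops at `max_pairs`. `UNANNOTATED` pairs
#' (no CDS) are swept purely left to right. The procedure is
#' deterministic for fixed input.
#'
#' @param pairs Pair tibble carrying `region` (from [designate_region()]).
#' @param params A [design_params()] object.
#' @param transcripts Optional transcript tibble, stored for plotting.
#' @return A `probe_set` object: the selected pairs (sorted by footprint
#'   start, indexed from 1 per transcript), per-region counts, and the
#'   parameters used. Zero surviving pairs yields an empty set with a
#'   warning, not an error.
#' @export
select_pairs <- function(pairs, params = design_params(),
                         transcripts = NULL) {
  stopifnot(inherits(params, "design_params"))
  if (!"region" %in% names(pairs)) {
    abort("`pairs` must carry a `region` column; run designate_region().")
  }
  if (nrow(pairs) == 0) {
    warn("No surviving probe pairs; returning an empty probe set.")
    sel <- pairs
    sel$index <- integer(0)
  } else {
    sel <- bind_rows(lapply(split(pairs, pairs$transcript_id),
                            select_pairs_one_tx, params = params))
    if (nrow(sel) == 0) {
      warn("No surviving probe pairs; returning an empty probe set.")
    }
  }
  per_region <- table(factor(sel$region,
                             levels = c("UTR5", "ORF", "UTR3", "UNANNOTATED")))
  structure(
    list(pairs = as_tibble(sel),
         per_region_counts = per_region,
         params = params,
         transcripts = transcripts),
    class = "probe_set"
  )
}

select_pairs_one_tx <- function(px, params) {
  order_regions <- c(params$region_priority, "UNANNOTATED")
  kept <- integer(0)
  kept_s <- integer(0)
  kept_e <- integer(0)
  for (reg in order_regions) {
    idx <- which(as.character(px$region) == reg)
    idx <- idx[order(px$footprint_start[idx])]
    for (i in idx) {
      if (length(kept) >= params$max_pairs) break
      s <- px$footprint_start[i]
      e <- px$footprint_end[i]
      if (all(e <= kept_s | s >= kept_e)) {
        kept <- c(kept, i)
        kept_s <- c(kept_s, s)
        kept_e <- c(kept_e, e)
      }
    }
    if (length(kept) >= params$max_pairs) break
  }
  out <- px[kept[order(px$footprint_start[kept])], , drop = FALSE]
  out$index <- seq_len(nrow(out))
  out
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("HCR probe set: %d pair(s) across %d transcript(s)\n",
              nrow(x$pairs), length(unique(x$pairs$transcript_id))))
  pr <- x$per_region_counts
  cat("  per region:", paste(names(pr), pr, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$report)) {
    print(x$report)
  }
  invisible(x)
}

#' @describeIn select_pairs Tidy the selected pairs into a tibble
#'   (one row per pair).
#' @param x A `probe_set`.
#' @param ... Unused.
#' @method tidy probe_set
#' @export
tidy.probe_set <- function(x, ...) {
  as_tibble(x$pairs)
}

#' @describeIn select_pairs One-row-per-transcript summary of the design
#'   funnel (window, thermo, uniqueness, pairing and selection counts).
#' @method glance probe_set
#' @export
glance.probe_set <- function(x, ...) {
  if (!is.null(x$report)) return(as_tibble(x$report))
  x$pairs |>
    dplyr::count(.data$transcript_id, name = "n_pairs_selected")
}
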