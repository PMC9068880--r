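# Pairs are built synthetically here: region designation and selection
# depend only on coordinates and regions.
synthetic_pairs <- function(footprint_starts, region = NULL,
                            transcript_id = "tx", probe_len = 25,
                            spacer = 2) {
  fp <- as.integer(footprint_starts)
  p <- tibble::tibble(
    transcript_id = transcript_id,
    p1_start = fp, p1_end = fp + probe_len,
    p2_start = fp + probe_len + spacer,
    p2_end = fp + 2 * probe_len + spacer,
    p1_binding = strrep("A", probe_len), p2_binding = strrep("C", probe_len),
    footprint_start = fp, footprint_end = fp + 2 * probe_len + spacer
  )
  if (!is.null(region)) {
    p$region <- factor(region,
                       levels = c("UTR5", "ORF", "UTR3", "UNANNOTATED"))
  }
  p
}

test_that("region designation follows containment, majority, and the
           documented tie-break", {
  tx <- transcript_tbl("tx", random_seq(2000), cds_start = 100L,
                       cds_end = 1300L)
  set.seed(1)
  p <- designate_region(synthetic_pairs(c(150, 1310, 90, 20)), tx)
  expect_equal(as.character(p$region), c("ORF", "UTR3", "ORF", "UTR5"))
  # footprint [90,142): 10 bases UTR5, 42 ORF -> majority ORF (row 3)

  # exact 26/26 tie at the CDS start resolves to ORF (priority order)
  tie <- designate_region(synthetic_pairs(100 - 26), tx)
  expect_equal(as.character(tie$region), "ORF")

  # no CDS -> UNANNOTATED
  tx0 <- transcript_tbl("tx", random_seq(2000))
  p0 <- designate_region(synthetic_pairs(c(10, 500)), tx0)
  expect_equal(as.character(p0$region), c("UNANNOTATED", "UNANNOTATED"))
})

test_that("selection caps at max_pairs with all-ORF surplus", {
  # 100 disjoint-capable ORF pairs
  p <- synthetic_pairs(seq(0, by = 52, length.out = 100), region = "ORF")
  ps <- select_pairs(p)
  expect_equal(nrow(ps$pairs), 36)
  expect_true(all(ps$pairs$region == "ORF"))
})

test_that("selection fills the cap across regions in priority order", {
  p <- dplyr::bind_rows(
    synthetic_pairs(seq(0, by = 52, length.out = 10), region = "ORF"),
    synthetic_pairs(seq(1000, by = 52, length.out = 50), region = "UTR3"),
    synthetic_pairs(seq(6000, by = 52, length.out = 50), region = "UTR5")
  )
  ps <- select_pairs(p)
  expect_equal(nrow(ps$pairs), 36)
  expect_equal(sum(ps$pairs$region == "ORF"), 10)
  expect_equal(sum(ps$pairs$region == "UTR3"), 26)
  expect_equal(sum(ps$pairs$region == "UTR5"), 0)

  # with all ORF pairs invalidated, selection falls back to UTR3 then UTR5
  ps2 <- select_pairs(dplyr::filter(p, region != "ORF"))
  expect_equal(sum(ps2$pairs$region == "UTR3"), 36)
})

test_that("selected footprints are pairwise disjoint and sorted, and no
           further pair could be added under the sweep", {
  set.seed(19)
  # dense overlapping candidates
  p <- designate_region(
    synthetic_pairs(sort(sample(0:1900, 300, replace = TRUE))),
    transcript_tbl("tx", random_seq(2000), cds_start = 100L,
                   cds_end = 1300L))
  ps <- select_pairs(p, design_params(max_pairs = 12))
  sel <- ps$pairs
  expect_lte(nrow(sel), 12)
  expect_equal(sel$footprint_start, sort(sel$footprint_start))
  ok <- TRUE
  for (i in seq_len(nrow(sel))) {
    for (j in seq_len(nrow(sel))) {
      if (i != j && sel$footprint_start[i] < sel$footprint_end[j] &&
          sel$footprint_end[i] > sel$footprint_start[j]) ok <- FALSE
    }
  }
  expect_true(ok)

  # exhaustive post-hoc check: if under the cap, no unselected pair fits
  if (nrow(sel) < 12) {
    for (i in seq_len(nrow(p))) {
      fits <- all(p$footprint_end[i] <= sel$footprint_start |
                    p$footprint_start[i] >= sel$footprint_end)
      expect_false(fits)
    }
  }
})

test_that("selection is deterministic and stable at the margin", {
  set.seed(23)
  p <- designate_region(
    synthetic_pairs(sort(sample(0:3000, 200, replace = TRUE))),
    transcript_tbl("tx", random_seq(3100), cds_start = 200L,
                   cds_end = 2500L))
  ps1 <- select_pairs(p)
  ps2 <- select_pairs(p)
  expect_identical(ps1$pairs, ps2$pairs)

  # removing one selected pair never loses more than that pair
  n0 <- nrow(ps1$pairs)
  drop_fp <- ps1$pairs$footprint_start[ceiling(n0 / 2)]
  p_less <- dplyr::filter(p, footprint_start != drop_fp)
  expect_gte(nrow(select_pairs(p_less)$pairs), n0 - 1)
})

test_that("zero surviving pairs yields an empty set with a warning", {
  p <- synthetic_pairs(integer(0), region = character(0))
  expect_warning(ps <- select_pairs(p), "empty probe set")
  expect_equal(nrow(ps$pairs), 0)
  expect_error(write_probe_outputs(ps, tempfile()), "empty")
})

test_that("tidy and glance return tabular views", {
  p <- synthetic_pairs(seq(0, by = 52, length.out = 5), region = "ORF")
  ps <- select_pairs(p)
  expect_s3_class(tidy(ps), "tbl_df")
  expect_equal(nrow(tidy(ps)), 5)
  g <- glance(ps)
  expect_true("n_pairs_selected" %in% names(g) || "transcript_id" %in% names(g))
})
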