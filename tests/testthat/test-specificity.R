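test_that("index construction bounds and self-matching hold", {
  fx <- fixture_2kb()
  idx <- build_index(fx$genome_path, k = 15)
  genome_len <- sum(nchar(idx$contigs))
  expect_lte(length(ls(idx$hash)), genome_len - 15 + 1)

  # reference = the transcript itself: every window matches at least once
  cand <- enumerate_windows(fx$transcript)[seq(1, 1976, by = 97), ]
  h <- count_hits(cand, build_index(fx$transcript_path))
  expect_true(all(h$n_loci >= 1))
})

test_that("hit counts equal the brute-force both-strand full scan", {
  fx <- generate_fixture(seed = 33, length = 600, gc = 0.5,
                         cds = c(100, 500), n_duplications = 1,
                         dir = file.path(tempdir(), "fx_spec"),
                         dup_len = 100, flank = 300)
  idx <- build_index(fx$genome_path)
  cand <- enumerate_windows(fx$transcript)
  got <- count_hits(cand, idx, max_mismatches = 2)
  idxes <- seq(1, nrow(cand), by = 7)
  want <- vapply(cand$target_seq[idxes], oracle_loci, integer(1),
                 reference_fasta = fx$genome_path, max_mismatches = 2)
  expect_equal(got$n_loci[idxes], unname(want))
})

test_that("windows inside a planted duplication report two loci and are
           dropped; unique windows are kept", {
  fx <- fixture_2kb()
  idx <- build_index(fx$genome_path)
  cand <- screen_candidates(enumerate_windows(fx$transcript))
  cand <- apply_uniqueness(cand, idx)

  dup_windows <- intersect(fx$expected_dropped_windows,
                           cand$start[cand$passed_thermo])
  expect_gt(length(dup_windows), 50)
  inside <- cand[cand$start %in% dup_windows, ]
  expect_true(all(inside$n_loci >= 2))
  expect_true(all(!inside$unique))

  single <- cand$passed_thermo & !is.na(cand$n_loci) & cand$n_loci == 1
  expect_true(any(single))
  expect_true(all(cand$unique[single]))
})

test_that("a pair survives only when both members are unique", {
  cand <- tibble::tibble(
    transcript_id = "tx", start = c(0L, 27L), end = c(25L, 52L),
    target_seq = c(strrep("ACGTG", 5), strrep("TGCAT", 5)),
    binding_seq = reverse_complement(c(strrep("ACGTG", 5),
                                       strrep("TGCAT", 5))),
    passed_thermo = TRUE, n_loci = c(1L, 2L), unique = c(TRUE, FALSE))
  expect_equal(nrow(pair_candidates(cand)), 0)
  cand$unique <- c(TRUE, TRUE)
  expect_equal(nrow(pair_candidates(cand)), 1)
})

test_that("increasing the mismatch budget never decreases hit counts, and
           planting a copy of a kept probe's locus flips it to dropped", {
  fx <- fixture_2kb()
  idx <- build_index(fx$genome_path)
  cand <- enumerate_windows(fx$transcript)[seq(1, 1900, by = 250), ]
  n0 <- count_hits(cand, idx, max_mismatches = 0)$n_loci
  n1 <- count_hits(cand, idx, max_mismatches = 1)$n_loci
  n2 <- count_hits(cand, idx, max_mismatches = 2)$n_loci
  expect_true(all(n1 >= n0))
  expect_true(all(n2 >= n1))

  # plant an exact copy of the first kept probe's window elsewhere
  probe <- cand$target_seq[1]
  genome <- Biostrings::readDNAStringSet(fx$genome_path)
  doctored <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(genome, Biostrings::DNAStringSet(
      c(planted_contig = probe)))), doctored)
  cand1 <- apply_uniqueness(mutate(cand, passed_thermo = TRUE),
                            build_index(doctored))
  expect_false(cand1$unique[1])
})

test_that("SAM import counts primary plus secondary alignments and zero
           for unmapped, and those verdicts drive uniqueness", {
  sam <- write_test_sam(c(
    # one primary alignment only -> 1 locus
    "tx:0-25\t0\tchr_fixture\t100\t42\t25M\t*\t0\t0\tACGTACGTACGTACGTACGTACGTA\t*\tAS:i:0",
    # primary + one secondary -> 2 loci
    "tx:27-52\t0\tchr_fixture\t200\t42\t25M\t*\t0\t0\tACGTACGTACGTACGTACGTACGTA\t*\tAS:i:0",
    "tx:27-52\t256\tchr_fixture\t900\t0\t25M\t*\t0\t0\tACGTACGTACGTACGTACGTACGTA\t*\tAS:i:-2",
    # supplementary records do not add loci
    "tx:54-79\t0\tchr_fixture\t300\t42\t25M\t*\t0\t0\tACGTACGTACGTACGTACGTACGTA\t*\tAS:i:0",
    "tx:54-79\t2048\tchr_fixture\t950\t0\t25M\t*\t0\t0\tACGTACGTACGTACGTACGTACGTA\t*\tAS:i:0",
    # unmapped -> 0 loci
    "tx:81-106\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGTACGTACGTACGTACGTA\t*"
  ), tempfile(fileext = ".sam"))
  hits <- import_sam_hits(sam)
  expect_equal(hits$n_loci[match(c("tx:0-25", "tx:27-52", "tx:54-79"),
                                 hits$candidate_id)],
               c(1L, 2L, 1L))
  expect_true(hits$n_loci[hits$candidate_id == "tx:81-106"] == 0 ||
                !"tx:81-106" %in% hits$candidate_id)

  # score floor removes the low-scoring secondary
  hits_floor <- import_sam_hits(sam, min_score = -1)
  expect_equal(hits_floor$n_loci[hits_floor$candidate_id == "tx:27-52"], 1L)

  cand <- tibble::tibble(
    transcript_id = "tx", start = c(0L, 27L, 54L, 81L),
    end = c(25L, 52L, 79L, 106L),
    target_seq = rep("ACGTACGTACGTACGTACGTACGTA", 4),
    binding_seq = rep(reverse_complement("ACGTACGTACGTACGTACGTACGTA"), 4),
    passed_thermo = TRUE)
  v <- apply_uniqueness(cand, hits = hits)
  expect_equal(v$unique, c(TRUE, FALSE, TRUE, FALSE))
  # --keep-unmapped reverses the zero-hit rule
  v2 <- apply_uniqueness(cand, hits = hits,
                         params = design_params(keep_unmapped = TRUE))
  expect_equal(v2$unique, c(TRUE, FALSE, TRUE, TRUE))
})
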