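test_that("window enumeration covers every start and excludes N windows", {
  tx <- transcript_tbl("t2000", fixture_2kb()$transcript$sequence)
  w <- enumerate_windows(tx)
  expect_equal(nrow(w), 2000 - 25 + 1)
  expect_equal(w$start, 0:1975)
  expect_equal(w$end - w$start, rep(25L, nrow(w)))
  expect_equal(w$target_seq[1], substr(tx$sequence, 1, 25))
  expect_equal(w$binding_seq, reverse_complement(w$target_seq))

  # exactly one window on a 25-nt transcript (validation minimum relaxed
  # by constructing the tibble directly)
  tx25 <- tibble::tibble(id = "t25", sequence = strrep("ACGTG", 5),
                         length = 25L, cds_start = NA_integer_,
                         cds_end = NA_integer_)
  w25 <- enumerate_windows(tx25)
  expect_equal(nrow(w25), 1)
  expect_equal(c(w25$start, w25$end), c(0L, 25L))

  # a 30-nt transcript with N at position 10 (0-based): all 6 windows
  # cover it, so none survive
  s <- strrep("ACGTG", 6)
  substr(s, 11, 11) <- "N"
  wN <- enumerate_windows(transcript_tbl("tN", s))
  expect_equal(nrow(wN), 0)

  expect_warning(
    enumerate_windows(tibble::tibble(id = "tiny", sequence = "ACGTACGTAC",
                                     length = 10L, cds_start = NA_integer_,
                                     cds_end = NA_integer_)),
    "shorter than probe_len")
})

test_that("gc_content matches direct base counting", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_error(gc_content(""), "non-empty")
})

test_that("nearest-neighbor Tm matches the literal table-summation oracle", {
  cond <- hcr_conditions()
  par <- design_params()
  # the hexamer duplex checked by hand summation
  hex <- melting_temperature("CGTTGA", cond, par)
  expect_equal(hex$tm_raw_c, oracle_tm("CGTTGA")$tm_raw, tolerance = 1e-6)

  set.seed(7)
  for (i in 1:50) {
    s <- random_seq(sample(8:30, 1))
    got <- melting_temperature(s, cond, par)
    want <- oracle_tm(s, na_molar = cond$na_molar,
                      formamide_pct = cond$formamide_pct)
    expect_lt(abs(got$tm_raw_c - want$tm_raw), 0.01)
    expect_lt(abs(got$tm_corrected_c - want$tm_corrected), 0.01)
  }
})

test_that("corrections are identity at 1 M Na+ / 0% formamide and the
           formamide penalty is exactly linear", {
  par <- design_params()
  s <- random_seq(25)
  ref <- melting_temperature(s, hcr_conditions(formamide_pct = 0), par)
  expect_equal(ref$tm_corrected_c, ref$tm_raw_c)

  at30 <- melting_temperature(s, hcr_conditions(formamide_pct = 30), par)
  expect_equal(at30$tm_corrected_c, at30$tm_raw_c - 30 * par$formamide_coef)
})

test_that("Tm is strand-symmetric and monotone in formamide and salt", {
  par <- design_params()
  set.seed(11)
  for (i in 1:10) {
    s <- random_seq(sample(10:30, 1))
    expect_equal(
      melting_temperature(s, hcr_conditions(), par)$tm_raw_c,
      melting_temperature(reverse_complement(s), hcr_conditions(),
                          par)$tm_raw_c)
  }
  s <- random_seq(25)
  fa <- vapply(c(0, 10, 20, 30, 40), function(f) {
    melting_temperature(s, hcr_conditions(formamide_pct = f), par)$tm_corrected_c
  }, numeric(1))
  expect_true(all(diff(fa) < 0))
  na <- vapply(c(0.01, 0.05, 0.1, 0.3, 1), function(m) {
    melting_temperature(s, hcr_conditions(na_molar = m), par)$tm_corrected_c
  }, numeric(1))
  expect_true(all(diff(na) > 0))
  # the alternative salt model obeys the same monotonicity
  par_ow <- design_params(salt_method = "owczarzy")
  na_ow <- vapply(c(0.01, 0.05, 0.1, 0.3, 1), function(m) {
    melting_temperature(s, hcr_conditions(na_molar = m),
                        par_ow)$tm_corrected_c
  }, numeric(1))
  expect_true(all(diff(na_ow) > 0))
})

test_that("screening equals brute-force predicate evaluation and is a
           pure, order-independent filter", {
  fx <- fixture_2kb()
  cond <- hcr_conditions()
  par <- design_params()
  cand <- screen_candidates(enumerate_windows(fx$transcript), cond, par)
  expect_equal(nrow(cand), 2000 - 25 + 1)  # no silent dropping

  idx <- seq(1, nrow(cand), by = 13)  # spot-check a spread of windows
  want <- vapply(cand$target_seq[idx], oracle_screen_pass, logical(1),
                 conditions = cond, params = par)
  expect_equal(unname(cand$passed_thermo[idx]), unname(want))

  # permutation of input permutes output verdicts identically
  set.seed(3)
  perm <- sample(nrow(cand))
  cand_perm <- screen_candidates(enumerate_windows(fx$transcript)[perm, ],
                                 cond, par)
  expect_equal(cand_perm$passed_thermo,
               cand$passed_thermo[perm])
})

test_that("screening thresholds act on GC and homopolymer runs", {
  cond <- hcr_conditions()
  par <- design_params()
  low_gc <- paste0("G", strrep("ATAT", 6))  # gc = 0.04
  homop <- strrep("A", 25)
  tx <- tibble::tibble(transcript_id = "x", start = c(0L, 0L),
                       end = c(25L, 25L),
                       target_seq = c(low_gc, homop),
                       binding_seq = reverse_complement(c(low_gc, homop)))
  got <- screen_candidates(tx, cond, par)
  expect_false(any(got$passed_thermo))
  expect_equal(got$homopolymer[2], 25L)
})
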