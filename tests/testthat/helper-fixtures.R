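# Shared test fixtures, built in code.

# Synthetic placeholder amplifier: no shipped arm sequence is
# load-bearing in the tests.
test_amplifier <- function(up = "GGATTCGGATTCGGATTC",
                           down = "CCTAAGCCTAAGCCTAAG",
                           linker = "AA") {
  amplifier("TESTAMP", up, down, arm_spacer_up = linker,
            arm_spacer_down = linker)
}

# One cached 2-kb fixture (transcript + genome with one planted
# duplication) reused across tests.
fixture_2kb <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_fixture(seed = 101, length = 2000, gc = 0.55,
                                 cds = c(100, 1300), n_duplications = 1,
                                 dir = file.path(tempdir(), "fx2kb"))
    }
    cache
  }
})

# Write a minimal SAM file for the import adapter tests.
write_test_sam <- function(records, path,
                           sq = "@SQ\tSN:chr_fixture\tLN:5000") {
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", sq, records), path)
  path
}
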