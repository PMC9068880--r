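#' Hybridization conditions
#'
#' Bundles the buffer conditions a probe set is designed against. The
#' defaults are the standard HCR v3 hybridization buffer: 37 degrees C,
#' 1 M monovalent sodium, 30% (v/v) formamide.
#'
#' @param temperature_c Hybridization temperature in degrees Celsius,
#'   strictly between 0 and 100.
#' @param na_molar Monovalent cation (Na+) concentration in mol/L, > 0.
#' @param formamide_pct Formamide percentage (v/v), between 0 and 50.
#'
#' @return An object of class `hcr_conditions` (a named list).
#' @examples
#' hcr_conditions()
#' hcr_conditions(temperature_c = 45, formamide_pct = 0)
#' @export
hcr_conditions <- function(temperature_c = 37, na_molar = 1.0,
                           formamide_pct = 30) {
  stopifnot(is.numeric(temperature_c), length(temperature_c) == 1,
            is.numeric(na_molar), length(na_molar) == 1,
            is.numeric(formamide_pct), length(formamide_pct) == 1)
  if (temperature_c <= 0 || temperature_c >= 100) {
    abort("`temperature_c` must be in (0, 100).")
  }
  if (na_molar <= 0) abort("`na_molar` must be > 0.")
  if (formamide_pct < 0 || formamide_pct > 50) {
    abort("`formamide_pct` must be in [0, 50].")
  }
  structure(
    list(temperature_c = temperature_c, na_molar = na_molar,
         formamide_pct = formamide_pct),
    class = "hcr_conditions"
  )
}

#' @export
print.hcr_conditions <- function(x, ...) {
  cat(sprintf("HCR hybridization conditions: %g degC, %g M Na+, %g%% formamide\n",
              x$temperature_c, x$na_molar, x$formamide_pct))
  invisible(x)
}

#' Probe-design parameters
#'
#' Tunable parameters of the design pipeline. Defaults reproduce the HCR v3
#' design rules: 25-nt probes, 2-nt spacer between the members of a pair,
#' at most 36 pairs per transcript, selection priority ORF, then 3' UTR,
#' then 5' UTR, and exclusion of probes matching more than one reference
#' locus.
#'
#' @param probe_len Probe (binding region) length in nt, >= 10.
#' @param spacer_len Gap between the two binding footprints of a pair, in
#'   nt, >= 0.
#' @param max_pairs Maximum number of pairs selected per transcript, >= 1.
#' @param region_priority Character vector, a permutation of
#'   `c("ORF", "UTR3", "UTR5")`, in decreasing selection priority.
#' @param gc_min,gc_max GC-fraction bounds a candidate must satisfy.
#' @param tm_margin_c Required excess of the corrected melting temperature
#'   over the hybridization temperature, in degrees C. A candidate passes
#'   only if `tm_corrected_c >= temperature_c + tm_margin_c`.
#' @param max_homopolymer Longest tolerated single-base run, in nt.
#' @param max_hits Maximum number of reference loci a candidate may match
#'   and still be considered unique (1 = the probe's own site only).
#' @param max_mismatches Substitution budget of the built-in reference
#'   matcher.
#' @param formamide_coef Linear melting-temperature depression per percent
#'   formamide, in degrees C (0.65 is the standard value for DNA duplexes).
#' @param salt_method Monovalent-salt correction: `"santalucia"` (entropy
#'   adjustment) or `"owczarzy"` (GC-dependent reciprocal-temperature
#'   correction).
#' @param probe_conc_m Probe strand concentration (mol/L) used in the
#'   two-state melting formula; the probe is assumed in excess over target.
#' @param keep_unmapped If `TRUE`, candidates with zero reference hits are
#'   kept rather than dropped (by default a probe absent from the design
#'   reference cannot be vetted and is removed).
#'
#' @return An object of class `design_params` (a named list).
#' @examples
#' design_params()
#' design_params(max_pairs = 5, region_priority = c("UTR3", "ORF", "UTR5"))
#' @export
design_params <- function(probe_len = 25L, spacer_len = 2L, max_pairs = 36L,
                          region_priority = c("ORF", "UTR3", "UTR5"),
                          gc_min = 0.25, gc_max = 0.75,
                          tm_margin_c = 5,
                          max_homopolymer = 4L,
                          max_hits = 1L,
                          max_mismatches = 2L,
                          formamide_coef = 0.65,
                          salt_method = c("santalucia", "owczarzy"),
                          probe_conc_m = 5e-9,
                          keep_unmapped = FALSE) {
  salt_method <- match.arg(salt_method)
  probe_len <- as.integer(probe_len)
  spacer_len <- as.integer(spacer_len)
  max_pairs <- as.integer(max_pairs)
  if (probe_len < 10L) abort("`probe_len` must be >= 10.")
  if (spacer_len < 0L) abort("`spacer_len` must be >= 0.")
  if (max_pairs < 1L) abort("`max_pairs` must be >= 1.")
  if (!setequal(region_priority, c("ORF", "UTR3", "UTR5")) ||
      length(region_priority) != 3L) {
    abort("`region_priority` must be a permutation of ORF, UTR3, UTR5.")
  }
  if (gc_min < 0 || gc_max > 1 || gc_min > gc_max) {
    abort("GC bounds must satisfy 0 <= gc_min <= gc_max <= 1.")
  }
  if (probe_conc_m <= 0) abort("`probe_conc_m` must be > 0.")
  structure(
    list(probe_len = probe_len, spacer_len = spacer_len,
         max_pairs = max_pairs, region_priority = region_priority,
         gc_min = gc_min, gc_max = gc_max, tm_margin_c = tm_margin_c,
         max_homopolymer = as.integer(max_homopolymer),
         max_hits = as.integer(max_hits),
         max_mismatches = as.integer(max_mismatches),
         formamide_coef = formamide_coef, salt_method = salt_method,
         probe_conc_m = probe_conc_m, keep_unmapped = isTRUE(keep_unmapped)),
    class = "design_params"
  )
}

#' @export
print.design_params <- function(x, ...) {
  cat("HCR probe-design parameters\n")
  cat(sprintf("  probe_len: %d nt, spacer_len: %d nt, max_pairs: %d\n",
              x$probe_len, x$spacer_len, x$max_pairs))
  cat(sprintf("  region priority: %s\n", paste(x$region_priority, collapse = " > ")))
  cat(sprintf("  GC in [%.2f, %.2f], Tm margin %g degC, homopolymer <= %d\n",
              x$gc_min, x$gc_max, x$tm_margin_c, x$max_homopolymer))
  cat(sprintf("  specificity: <= %d loci at <= %d mismatches\n",
              x$max_hits, x$max_mismatches))
  invisible(x)
}

#' Load design configuration from a YAML or JSON file
#'
#' Reads thresholds and thermodynamic settings from a config file and
#' returns the corresponding [design_params()] and [hcr_conditions()]
#' objects. Keys mirror the argument names of those constructors, grouped
#' under `parameters:` and `conditions:`; missing keys fall back to the
#' built-in defaults. A committed default file ships with the package
#' (`system.file("extdata", "default_config.yaml", package = "hcrprobes")`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A list with elements `params` and `conditions`.
#' @export
read_design_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  pa <- cfg$parameters %||% list()
  co <- cfg$conditions %||% list()
  list(
    params = do.call(design_params, pa),
    conditions = do.call(hcr_conditions, co)
  )
}
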