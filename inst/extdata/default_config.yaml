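# Default design configuration. Keys mirror the arguments of
# design_params() and hcr_conditions(); anything omitted falls back to
# the built-in defaults shown here.
conditions:
  temperature_c: 37      # hybridization temperature, degC
  na_molar: 1.0          # monovalent Na+, mol/L
  formamide_pct: 30      # formamide, % v/v
parameters:
  probe_len: 25          # binding-region length, nt
  spacer_len: 2          # gap between the two footprints of a pair, nt
  max_pairs: 36          # selection cap per transcript
  region_priority: [ORF, UTR3, UTR5]
  gc_min: 0.25
  gc_max: 0.75
  tm_margin_c: 5         # required corrected-Tm excess over temperature_c
  max_homopolymer: 4
  max_hits: 1            # loci a unique probe may match
  max_mismatches: 2      # substitution budget of the built-in matcher
  formamide_coef: 0.65   # degC Tm depression per % formamide
  salt_method: santalucia  # or: owczarzy
  probe_conc_m: 5.0e-9   # probe strand concentration, mol/L
  keep_unmapped: false
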