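---
title: "HCR v3 probe design: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HCR v3 probe design: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcrprobes)
```

## The design problem

Third-generation hybridization chain reaction (HCR v3) FISH reads out an
mRNA through *split-initiator probe pairs*: two 25-nt DNA probes that bind
adjacent sites on the transcript, separated by a 2-nt spacer. Each probe
carries one half of an amplifier's initiator; fluorescent hairpin
polymerization triggers only when both halves are juxtaposed, which is
what gives v3 its specificity. A probe set for one gene is up to 36 such
pairs tiled along the transcript, preferring the open reading frame, then
the 3′ UTR, then the 5′ UTR.

`hcrprobes` turns a transcript sequence plus CDS annotation into that
probe set. The pipeline is a funnel of deterministic stages — window
enumeration, thermodynamic screening, specificity filtering, pairing,
region designation, selection, oligo assembly — and every stage returns a
tibble carrying its verdicts, so nothing is silently dropped and the
whole funnel is auditable (`glance()` on the result).

## Thermodynamic model

Candidate windows are screened with the two-state nearest-neighbor model:

$$T_m = \frac{\Delta H^\circ}{\Delta S^\circ + R \ln C_T} - 273.15$$

with the unified SantaLucia (1998) stacked-dinucleotide
$\Delta H^\circ/\Delta S^\circ$ parameters and terminal initiation terms.
Choices the model leaves open, and what this package does:

* **Strand concentration.** $C_T$ = 5 nM with the probe in excess over
  target ($x = 1$), the regime of in situ hybridization where probe vastly
  outnumbers transcript. Override via `design_params(probe_conc_m = )`.
  Self-complementary sequences receive the symmetry entropy term
  (−1.4 cal mol⁻¹ K⁻¹); at the 25-nt odd probe length this never arises in
  practice.
* **Salt correction.** Default is the SantaLucia (1998) entropy
  adjustment $\Delta S^\circ[\mathrm{Na^+}] = \Delta S^\circ[1\,\mathrm M]
  + 0.368\,(N-1)\ln[\mathrm{Na^+}]$, which is exactly identity at the
  1 M NaCl of the HCR buffer. The Owczarzy (2004) GC-dependent
  reciprocal-temperature correction is selectable
  (`salt_method = "owczarzy"`) for users working at lower ionic strength.
* **Formamide.** A linear depression of 0.65 °C per percent (v/v), the
  standard coefficient for long DNA duplexes; at the default 30%
  formamide this subtracts 19.5 °C. Config-overridable
  (`formamide_coef`).
* **Pass rule.** A window passes when its corrected $T_m$ is at least
  `tm_margin_c` (default 5 °C) above the hybridization temperature
  (default 37 °C): the probe must remain stably duplexed *in the buffer at
  the hybridization temperature*, with a safety margin. GC bounds
  \[0.25, 0.75\] and a homopolymer cap of 4 nt are conventional
  probe-mining defaults that remove composition outliers the $T_m$ model
  handles poorly.

The implementation is vectorized over windows; the test suite pins it,
window by window, to an independent literal table-summation oracle
(agreement within 0.01 °C), and checks strand symmetry and the
monotonicity of both corrections.

## Specificity filtering

A probe that matches more than one genomic locus produces off-target
signal, so candidates are aligned against a reference and any candidate
matching more than `max_hits` (default 1) loci is removed; a *pair*
survives only if both members do. Two routes are provided:

* **Built-in matcher** (desk scale, ≲ tens of Mb): an exact k-mer index
  over the reference, queried in both orientations, with full-window
  verification allowing up to `max_mismatches` (default 2) substitutions.
  The seed length is derived by the pigeonhole principle — with budget
  $m$, one of $m+1$ disjoint seeds of length
  $\lfloor 25/(m+1) \rfloor = 8$ must be exact — so the seed search finds
  *every* substitution-bounded match; the tests verify exact agreement
  with a brute-force both-strand full scan on kilobase fixtures. Longer
  seeds (e.g. the 11+ typical of alignment tools) would be faster but can
  miss two-mismatch matches, which would break that guarantee. Indels are
  deliberately not modeled: a 25-mer needing a gap to align is not a
  functional probe, and the SAM route covers gapped alignment.
* **SAM import** (genome scale): users align the candidate FASTA with
  their aligner of choice (e.g. Bowtie2 against a full genome, reporting
  secondary alignments) and hand the SAM to `import_sam_hits()`, which
  counts primary + secondary alignments per candidate (supplementary
  records are parts of an already-counted alignment), with an optional
  alignment-score floor on the `AS` tag. The published aligner's exact
  scoring behavior is thereby reproducible without this package guessing
  its thresholds.

Zero-hit candidates are dropped by default: a probe absent from the
design reference cannot be vetted, and a transcript/reference mismatch
should surface as a loud funnel drop rather than silent off-target risk.
`keep_unmapped = TRUE` reverses this for users designing against a
deliberately partial reference.

## Pairing, regions, selection

Pairing is purely positional: windows at starts $i$ and $i + 27$
(25 + 2-nt spacer) form a pair when both passed all upstream filters.
The 2-nt spacer bases themselves are unconstrained — the gap is
positional, not sequence-specific.

Each pair's 52-nt footprint is designated 5′ UTR, ORF or 3′ UTR. A
footprint straddling a boundary takes the region holding the majority of
its bases; an exact 26/26 tie resolves toward the earlier region in the
priority order (so ORF wins a tie with either UTR). Transcripts without
a CDS get `UNANNOTATED` and are tiled purely left to right.

Selection is a greedy sweep: regions in priority order (default
ORF > 3′ UTR > 5′ UTR), pairs left to right within each region, keeping
a pair whenever its footprint is disjoint from everything already kept,
stopping at `max_pairs` (default 36). Two open choices and their
rationale:

* **Disjointness.** Overlapping probes compete for the same bases and
  cannot bind simultaneously, so selected footprints (including spacers)
  must be pairwise disjoint. This is the package's contract; it also
  makes the greedy sweep a maximal left-to-right tiling within each
  region.
* **Left-to-right, not $T_m$-ranked.** A positional sweep is
  deterministic, maximizes tiling density, and avoids biasing coverage
  toward GC-rich segments. A `--rank-by tm` hook is reserved but not
  implemented.

The whole pipeline contains no randomness: identical inputs and
configuration give byte-identical TSV/BED/FASTA outputs (the JSON report
carries a timestamp).

## Oligo assembly

The final oligos are exact concatenations: the 5′-ward probe (P1) is
`initiator_up + linker + binding_seq`, the 3′-ward probe (P2) is
`binding_seq + linker + initiator_down`, each binding sequence being the
reverse complement of its transcript window. Which half of the initiator
goes on which probe is a convention that must simply be held fixed — the
shipped config puts the upstream half on P1 and can be edited if a user's
amplifier definitions differ. The default 2-nt `AA` linkers are the
conventional short arms of v3 designs. Arm and linker sequences are data
(`inst/extdata/amplifiers.yaml`), never code; the shipped B1–B5 arms are
the published v3.0 initiator halves and should be verified against the
user's amplifier lot. The test suite uses synthetic placeholder arms
throughout, so no shipped sequence is load-bearing for correctness.

## The fixture generator

`generate_fixture()` makes the pipeline testable without downloads: a
random transcript of chosen length and GC with a defined CDS, embedded in
a single-contig genome (random flanks, default 500 nt each) together with
`n_duplications` segments copied from the transcript — exact second
copies that the specificity filter must catch, with the ground truth
(every window fully inside a copied segment) recorded in the manifest.

Design choices: base composition is exact-count (exactly
`round(gc * length)` G/C positions, shuffled), so the realized GC equals
the target to within rounding for every seed rather than merely in
expectation; one RNG, seeded explicitly, drives everything, and the seed
is recorded in the manifest; the global RNG state is left untouched.

What the fixture does *not* emulate: paralog families and processed
pseudogenes (off-target hits here come only from planted exact copies),
splice isoforms, biased dinucleotide composition, and RNA secondary
structure. Passing tests therefore demonstrate the pipeline's contracts —
counting, thermodynamic screening against the stated model, exact
substitution-bounded specificity, selection order — not wet-lab probe
performance on real transcriptomes, where an external genome-scale
alignment (the SAM route) is the appropriate specificity check. Windows
that merely graze a planted duplication by a few bases may legitimately
survive: with a 2-substitution budget, a 25-mer overhanging the copy
boundary by 3+ nt no longer matches the copy.

## Problem sizes and numerical notes

The shipped tests run on kilobase-scale fixtures: 2-kb transcripts
(≈ 2,000 windows) for end-to-end checks, a 2.25-kb genome for the
exhaustive specificity oracle, twenty 500-nt transcripts for the
determinism/funnel sweep, and a 6-kb transcript for the selection-surplus
check — sizes at which brute-force oracles stay exact and the whole suite
runs in well under a minute, while exercising every code path the method
has. Degenerate inputs are defined, not accidental: transcripts shorter
than one pair footprint (52 nt) yield an empty set with a warning; `N`
bases exclude their windows at enumeration (the nearest-neighbor model is
undefined over ambiguity codes); zero surviving pairs is a warning plus an
empty report, never an error.

## Known limitations

* No RNA secondary-structure or probe-dimer screening; windows in stable
  hairpins may underperform.
* No Mg²⁺ or dangling-end corrections in the $T_m$ model.
* The built-in matcher is substitution-only and exhaustive-exact at desk
  scale; genome-scale references go through the SAM route.
* Region designation is single-isoform; multi-isoform collapsing is out
  of scope.
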