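# hcrprobes

Design of split-initiator probe pairs for third-generation hybridization
chain reaction (HCR v3) fluorescent in situ hybridization.

HCR v3 detects an mRNA with pairs of DNA probes that bind adjacent 25-nt
sites on the transcript. Each probe carries half of an amplifier's
initiator sequence; only when both probes of a pair bind side by side —
separated by a 2-nt spacer on the target — do the two halves juxtapose and
trigger polymerization of fluorophore-bearing hairpins. Designing a probe
set for a gene therefore means tiling its transcript with compatible
25-mer pairs that (i) stay duplexed under the hybridization buffer,
(ii) occur exactly once in the genome, and (iii) preferentially cover the
open reading frame. `hcrprobes` automates that design for users of
HCR-FISH — from a transcript FASTA and its CDS coordinates to an
order-ready oligo sheet.

## The method

For a transcript of length *L* with CDS interval \[*s*, *e*), the pipeline:

1. **Enumerates** all *L* − 24 candidate windows of length 25 (windows
   containing `N` excluded).
2. **Screens** each window thermodynamically. The duplex melting
   temperature comes from the unified nearest-neighbor model,

   *T*<sub>m</sub> = ΔH° / (ΔS° + *R* ln *C*<sub>T</sub>) − 273.15,

   with SantaLucia-1998 stacked-dinucleotide ΔH°/ΔS° parameters and
   initiation terms, probe concentration *C*<sub>T</sub> = 5 nM (probe in
   excess). The monovalent-salt correction
   ΔS°(\[Na⁺\]) = ΔS°(1 M) + 0.368 (*N* − 1) ln\[Na⁺\] (or, optionally,
   the Owczarzy-2004 reciprocal-temperature form) and a linear formamide
   penalty of 0.65 °C per percent (v/v) adjust it to the buffer. Under
   the default HCR conditions — 37 °C, 1 M NaCl, 30% formamide — a window
   passes when its corrected *T*<sub>m</sub> exceeds the hybridization
   temperature by ≥ 5 °C, its GC fraction lies in \[0.25, 0.75\], and it
   has no homopolymer run longer than 4 nt.
3. **Filters for specificity**: a window is kept only if it matches at
   most one reference locus with ≤ 2 substitutions, found with an exact
   k-mer seed index over both strands (pigeonhole-complete seeds, so the
   seed search provably finds every substitution-bounded match), or with
   imported SAM alignments from an external aligner such as Bowtie2 for
   genome-scale references.
4. **Pairs** adjacent survivors whose windows sit exactly 27 nt apart
   (25 + 2-nt spacer) and assigns each pair to the 5′ UTR, ORF or 3′ UTR
   by majority of its 52-nt footprint.
5. **Selects** up to 36 non-overlapping pairs per transcript, taking ORF
   pairs first, then 3′ UTR, then 5′ UTR, sweeping 5′→3′ within each
   region, and appends the chosen amplifier's split-initiator arms
   (B1–B5 shipped, config-overridable) to produce the final oligos.

## Worked example

```r
library(hcrprobes)

# a reproducible synthetic transcript (2 kb, CDS 100-1300, 55% GC) inside
# a synthetic genome carrying one duplicated segment
fx <- generate_fixture(seed = 11, length = 2000, gc = 0.55,
                       cds = c(100, 1300), n_duplications = 1,
                       dir = tempdir())

ps <- design_probes(fx$transcript, reference = fx$genome_path, amp = "B1")
ps
#> HCR probe set: 33 pair(s) across 1 transcript(s)
#>   per region: UTR5=1, ORF=20, UTR3=12, UNANNOTATED=0

glance(ps)
#> # A tibble: 1 × 10
#>   transcript_id      n_windows n_pass_thermo n_unique n_pairs_candidate ...
#> 1 transcript_fixture      1976          1778     1650              1438

head(tidy(ps)[, c("index", "p1_start", "p2_start", "region", "oligo1_name")], 4)
#>   index p1_start p2_start region oligo1_name
#> 1     1        0       27 UTR5   transcript_fixture_B1_pair001_P1
#> 2     2       74      101 ORF    transcript_fixture_B1_pair002_P1
#> 3     3      126      153 ORF    transcript_fixture_B1_pair003_P1
#> 4     4      178      205 ORF    transcript_fixture_B1_pair004_P1
```

The funnel reads: 1,976 candidate windows, of which 1,778 pass the
thermodynamic screen and 1,650 map uniquely (the 150-nt planted
duplication removes the rest); 1,438 adjacent pairs remain, and 33
mutually disjoint pairs fit on this 2-kb transcript — ORF pairs first,
the remainder drawn from the UTRs. `autoplot(ps)` draws the probe
footprints along the transcript; `write_probe_outputs(ps, "out/geneX")`
writes the order-sheet TSV, BED footprints, oligo FASTA and a JSON
design report.

The same pipeline is scriptable from a shell via the installed CLI
(`system.file("exec", "hcrprobes", package = "hcrprobes")`):

```sh
hcrprobes design --fasta geneX.fa --cds 101-1300 --genome genome.fa \
    --amplifier B1 --out out/geneX
hcrprobes fixture --seed 3 --length 1500 --cds 101-1200 --duplications 1 \
    --out fixtures/
```

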