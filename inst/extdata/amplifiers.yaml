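# Default split-initiator amplifier set: the five HCR v3.0 amplifiers
# B1-B5, each 36-nt initiator split into its two 18-nt halves. The
# upstream half is prepended (with the arm linker) to the 5'-ward probe
# of a pair, the downstream half appended to the 3'-ward probe. These
# arms are data, not code: verify them against your amplifier lot and
# override this file (run_design(amplifier_config = ...)) if your
# definitions differ.
amplifiers:
  - name: B1
    initiator_up: GAGGAGGGCAGCAAACGG
    initiator_down: GAAGAGTCTTCCTTTACG
    arm_spacer_up: AA
    arm_spacer_down: AA
  - name: B2
    initiator_up: CCTCGTAAATCCTCATCA
    initiator_down: ATCATCCAGTAAACCGCC
    arm_spacer_up: AA
    arm_spacer_down: AA
  - name: B3
    initiator_up: GTCCCTGCCTCTATATCT
    initiator_down: CCACTCAACTTTAACCCG
    arm_spacer_up: AA
    arm_spacer_down: AA
  - name: B4
    initiator_up: CCTCAACCTACCTCCAAC
    initiator_down: TCTCACCATATTCGCTTC
    arm_spacer_up: AA
    arm_spacer_down: AA
  - name: B5
    initiator_up: CTCACTCCCAATCTCTAT
    initiator_down: CTACCCTACAAATCCAAT
    arm_spacer_up: AA
    arm_spacer_down: AA
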