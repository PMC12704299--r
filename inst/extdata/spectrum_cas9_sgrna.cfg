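# Reported deep-sequencing outcome spectrum for TRBC editing with
# SpCas9 + TRBC sgRNA (editing efficiency 64.6%). MMEJ repair is absent
# from the blunt-cutting arm.
label cas9_sgrna
wt 0.354
insertion 0.040
deletion_on_position 0.447
deletion_on_position_mmej 0.000
deletion_off_position 0.159
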