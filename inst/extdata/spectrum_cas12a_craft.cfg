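# Reported deep-sequencing outcome spectrum for TRBC editing with
# AsCas12a Ultra + CRAFT crRNA (editing efficiency 95.4%). Category
# proportions are the published summary percentages on the 0-1 scale;
# the loader normalises by their sum (printed values carry rounding).
# deletion_on_position_mmej is the subset of on-position deletions
# repaired through microhomology-mediated end joining.
label cas12a_craft
wt 0.046
insertion 0.001
deletion_on_position 0.906
deletion_on_position_mmej 0.110
deletion_off_position 0.046
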