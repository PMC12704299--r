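# ampedit

CRISPR amplicon editing-outcome analysis with microhomology-aware
classification.

## What it does, and for whom

When a nuclease such as SpCas9 or AsCas12a cuts a locus, the repaired
alleles visible in deep amplicon sequencing tell you *how* the break was
fixed. For T-cell engineering applications — e.g. knocking out the TCR β
constant region (TRBC) to build allogeneic CAR T-cells — a guide placed
next to strong microhomology drives repair through microhomology-mediated
end joining (MMEJ), which deletes one repeat copy plus the intervening
bases and so yields one dominant, predictable allele instead of the
heterogeneous small indels of canonical end joining.

`ampedit` is for researchers designing and evaluating such guides. Given a
reference amplicon, a guide and a nuclease chemistry it:

1. locates the protospacer/PAM and predicts the double-strand-break
   window — blunt for SpCas9 (3 nt 5′ of the NGG PAM), staggered for
   AsCas12a (nicks after protospacer positions 18 and 23 from the
   TTTV-proximal end, giving the canonical 5-nt 5′ overhang);
2. enumerates microhomology pairs flanking the cut and the MMEJ deletion
   allele each pair predicts;
3. merges, QC-filters and globally aligns reads (affine-gap
   Needleman–Wunsch: match +2, mismatch −2, gap open −6, extend −1),
   calling left-normalized indel events;
4. classifies every allele into a five-way repair-outcome taxonomy —
   WT/substitution, insertion, on-position deletion (MMEJ-flagged when the
   junction microhomology is ≥ 2 nt), off-position deletion — and reports
   per-category fractions, the MMEJ fraction and the editing efficiency
   (1 − WT fraction);
5. scans sequence databases for PAM-anchored off-target sites within a
   Hamming-mismatch budget (default 4), with exon/intron/intergenic
   annotation from BED/GFF3;
6. simulates MiSeq-style 2×150 paired amplicon reads from a configurable
   allele spectrum with per-read ground truth, so the whole pipeline is
   testable round-trip with no external data.

## Worked example

Simulate the AsCas12a/CRAFT-crRNA arm on the bundled TRBC1/2 consensus
amplicon and recover its outcome spectrum:

```r
library(ampedit)

amp  <- bundled_amplicons()["TRBC1_2"]
site <- locate_target(guide("CRAFT_crRNA", bundled_guides()[["CRAFT_crRNA"]]),
                      amp, nuclease_profile("AsCas12a"))
site
#>   reference_id strand proto_start proto_end pam_seq cut_start cut_end
#> 1      TRBC1_2  minus          78        99    TTTG        76      81

fixture  <- read_spectrum_config(bundled_spectrum("cas12a_craft"))
spectrum <- build_spectrum(fixture, amp, site, seed = 1)
spec <- sim_spec(amp, site, spectrum, n_reads = 2000, error_rate = 0.001,
                 mode = "paired_2x150", seed = 1001)
sim  <- simulate_reads(spec)

res <- run_profile(amp, bundled_guides()[["CRAFT_crRNA"]], "AsCas12a",
                   sim$r1, sim$r2, out_dir = "craft_run")
res$summary
#> <classification_summary> 2000 reads
#>   wt_or_sub                    96    4.80%
#>   insertion                     4    0.20%
#>   deletion_on_position       1808   90.40%
#>   deletion_off_position        92    4.60%
#>   mmej (within on-pos)              10.25%
#>   editing efficiency: 95.20%
```

The guide binds the minus strand at 0-based [78, 99) with a TTTG PAM, and
the staggered cut spans gap coordinates 76–81. Of 2,000 simulated read
pairs, 95.2% carry an indel (the editing efficiency); 90.4% are deletions
overlapping the predicted break, of which 10.25 percentage points carry
junction microhomology ≥ 2 nt — the MMEJ signature; insertions are rare
(0.2%), as expected for this chemistry. The microhomology report behind
the MMEJ alleles:

```r
enumerate_microhomologies(amp[[1]], c(site$cut_start, site$cut_end))[1:3, ]
#>   left_start left_end right_start right_end mh_seq mh_len deletion_len
#> 1         61       65          95        99   GGGC      4           34
#> 2         51       55          87        91   CCAG      4           36
#> 3         51       55         111       115   CCAG      4           60
```

`run_profile()` writes a full report bundle: `summary.json` (percentages,
0–100 scale), `alleles.tsv` (dash-notation allele table), `per_read.tsv`,
`site.tsv` and `run.log` (every effective parameter). `run_design()`,
`run_offtarget()`, `run_simulate()` and `compare_arms()` cover guide
design, off-target scanning, read simulation and two-arm comparison with
Wilson confidence intervals.

## Layout

- `R/` — target model, microhomology, alignment, classification,
  off-target scan, simulator, pipeline.
- `src/align.cpp` — affine-gap Gotoh aligner with deterministic traceback.
- `inst/extdata/` — bundled amplicons (FASTA) and the two arm-spectrum
  fixtures (key/value configs).
- `vignettes/editing-outcomes.Rmd` — the methods vignette: model,
  parameters, generator design, numerical choices, limitations.
- `tests/testthat/` — unit, property (oracle-equality) and acceptance
  suites.
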