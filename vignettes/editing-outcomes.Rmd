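---
title: "Quantifying CRISPR editing outcomes from amplicon reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CRISPR editing outcomes from amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampedit)
```

## The problem

Knocking out a gene with CRISPR-Cas leaves behind a *spectrum* of repaired
alleles at the cut site. For therapeutic T-cell engineering — e.g. disrupting
the T-cell receptor β constant region (TRBC) to make allogeneic CAR T-cells —
what matters is not just the fraction of edited molecules but *how* they were
repaired. Canonical non-homologous end joining (NHEJ) produces heterogeneous
small indels, many of them in-frame; microhomology-mediated end joining
(MMEJ) uses short direct repeats flanking the break and produces one
predictable deletion per repeat pair, so a guide placed next to a strong
microhomology yields a far more homogeneous knockout. AsCas12a cuts with a
staggered, 5′-overhanging geometry that favours MMEJ; SpCas9 cuts bluntly
and repairs mostly through NHEJ.

`ampedit` quantifies this from deep amplicon sequencing. Every read is
assigned to one of four mutually exclusive outcome categories, with an MMEJ
flag subdividing the third:

* **wt_or_sub** — no indel; substitution-only reads count as WT because
  isolated substitutions at amplicon depth are overwhelmingly sequencing or
  PCR noise, not nuclease products;
* **insertion** — any allele containing an insertion (mixed
  insertion+deletion alleles count here, keeping the taxonomy a partition);
* **deletion_on_position** — a deletion overlapping the predicted
  double-strand-break position, flagged **MMEJ** when its junction carries
  microhomology of at least `min_mh` nt;
* **deletion_off_position** — a deletion elsewhere in the amplicon.

Editing efficiency is `1 - wt_or_sub`. All fractions are computed over
assigned reads; reads aligning below the identity floor are reported
separately and excluded from every denominator.

## Cut-site geometry

A `nuclease_profile` fixes where the nuclease expects its PAM and where the
break falls. For SpCas9 (3′ NGG) the blunt cut is placed 3 nt 5′ of the PAM
— between protospacer positions 17 and 18 from the PAM-distal end — which
is the universal convention for this enzyme. For AsCas12a (5′ TTTV) the
staggered nicks default to protospacer positions 18 and 23 from the
PAM-proximal end, the canonical 5-nt 5′-overhang geometry. Both are
configurable; published estimates of the Cas12a target-strand nick vary by
a nucleotide or two, and the classifier's `pad` parameter (default 1 nt)
absorbs exactly this kind of uncertainty. Cut positions are *gap
coordinates* — positions between bases — so a blunt cut is a width-0
window and the Cas12a stagger a width-5 window.

On the bundled TRBC1/2 consensus amplicon (184 nt, spanning the region of
exon 1 shared by both TCR β constant genes) the two bundled guides land as:

```{r sites}
amp <- bundled_amplicons()["TRBC1_2"]
locate_target(guide("TRBC_sgRNA", bundled_guides()[["TRBC_sgRNA"]]),
              amp, nuclease_profile("SpCas9"))
locate_target(guide("CRAFT_crRNA", bundled_guides()[["CRAFT_crRNA"]]),
              amp, nuclease_profile("AsCas12a"))
```

Only exact spacer matches count at on-target loci; degenerate binding is
the off-target scanner's domain. Two further bundled guides — the DN TRBC
crRNA and the TRAC crRNA — do **not** occur verbatim in either bundled
amplicon (both strands scanned exhaustively; a locate_target test records
this). We deliberately do not "repair" those spacers: the amplicons and
guides are kept exactly as provided, and analyses that need a located site
use the two guides that have one.

## Microhomology model

`enumerate_microhomologies()` lists maximal direct-repeat pairs that
straddle the cut window: the left copy ends at or before the window's end,
the right copy starts at or after its start, both within `search_window`
(default 30 nt, bounding plausible deletion sizes at amplicon scale) and
at least `min_len` long (default 2 nt — the smallest signature that
distinguishes a microhomology-guided join from a blunt join). Only exact,
ungapped repeats are considered; degenerate or mismatched microhomology is
out of scope. Maximality is sequence maximality: a pair whose flanking
bases still agree is dropped in favour of its extension, even when the
extension leaves the search window — the deduplicated *products* are what
matter, and a trimmed sub-repeat predicts the same product as its
extension.

`predict_mmej_products()` deletes `[left_start, right_start)`, keeping one
repeat copy. `junction_microhomology()` inverts the logic for observed
deletions: it measures how far a deletion can slide left or right without
changing the product. That slide range is also how the classifier decides
on-position versus off-position — a deletion is compared against the cut
window through its whole ambiguity span, not one arbitrary placement, so
left-normalization never pushes a true cut-site deletion out of its own
window.

## Alignment and indel calling

Reads are aligned globally (Needleman–Wunsch with affine gaps, Gotoh
three-state DP in C++). Default scores: match +2, mismatch −2, gap open −6,
gap extend −1, with an L-base gap costing `open + L·extend`. These favour
one long gap over scattered mismatches, which is the correct prior for
nuclease-edited amplicons where single contiguous deletions dominate. The
traceback is deterministic (diagonal over gapped-read over gapped-reference
at ties) and every indel is subsequently left-normalized, so equivalent
placements inside repeats collapse to one canonical event and hence one
allele key. Substitutions are recorded but never merged with gaps and never
define alleles.

Paired 2×150 reads are merged on their best ungapped overlap (≥ 20 nt,
≤ 10% disagreement; the higher-quality base wins conflicts) before
alignment; fragments shorter than the read length simply yield two
truncated, fully overlapping copies and merge trivially. Reads shorter
than 50 nt are discarded as uninformative, and reads aligning below 60%
identity are set aside as unassigned so contaminants cannot inflate the
WT fraction. Alignment is run once per distinct sequence — amplicon data
is massively redundant, and deduplication makes the 20,000-read runs take
seconds without changing any result.

## Off-target scanning

`scan_offtargets()` reports every position, on either strand, where the
PAM matches its IUPAC pattern exactly and the protospacer is within
`max_mm` Hamming mismatches (default 4) of the spacer. PAM mismatches are
not charged to the budget — the PAM either matches or the site is not a
site, the convention of PAM-first scanners. No bulges are modelled, `N`
matches nothing, and hits are annotated exonic > intronic > intergenic
against a BED (0-based half-open, kept as-is) or GFF3 (1-based inclusive,
converted on read) feature track; the dialect applied is logged. Scores or
cleavage-likelihood rankings are out of scope, as is reproducing
genome-build-specific hit lists: correctness is established on synthetic
genomes with planted sites, where a per-position oracle can be exhaustive.

## The synthetic-read generator

Because no sequencing data is deposited with the study this package
models, recovery is validated generator → pipeline: `build_spectrum()`
expands category-level proportions into concrete alleles and
`simulate_reads()` emits MiSeq-style reads from them. The generator and
the pipeline are independent code paths — the generator only ever applies
events by string surgery; it never calls the aligner.

The bundled fixtures transcribe the two reported TRBC-editing arms: the
AsCas12a/CRAFT-crRNA arm (WT 4.6%, insertions 0.1%, on-position deletions
90.6% of which 11% of all reads are MMEJ-flagged, off-position deletions
4.6%) and the SpCas9/sgRNA arm (35.4 / 4 / 44.7 / 15.9, MMEJ absent).
The CRAFT-arm values are published rounded and sum to 99.9; the loader
normalises by the sum, shifting no category by more than 0.1 pp.

Expansion rules: MMEJ alleles are the site's top predicted MMEJ products
weighted by microhomology length; plain on-position deletions are random
1–20 nt deletions overlapping the cut window with junction microhomology
below `min_mh`; insertions are random 1–10 nt sequences at the cut;
off-position deletions sit at least `pad + 5` nt from the window. Within
each random category allele weights fall off harmonically, emulating the
long-tailed allele spectra of real editing data. Every candidate allele is
accepted only if the classifier applied to its own events reproduces the
intended label, so truth tables agree with `classify_allele()` by
construction — the *recovery* being tested is whether merge → align →
call → classify re-derives those labels from raw reads.

Sequencing noise is i.i.d. per-base substitution at rate 0.001 (a
reasonable MiSeq post-filter figure); qualities are constant Q30.
Simulated sequencing *indel* errors are deliberately excluded — they would
confound the very taxonomy under test, and platform indel error on
non-homopolymer MiSeq data is an order of magnitude rarer than
substitution error. This is the main respect in which passing round-trip
tests understate real-data difficulty; the others are PCR chimeras and
jackpot amplification, which are likewise not modelled.

## Problem sizes and numerical choices

The recovery experiments simulate 20,000 read pairs per arm (no per-locus
read count is published; 20,000 is typical MiSeq amplicon depth and makes
the binomial standard error of a 90% category about 0.2 pp, comfortably
inside the ±1.5 pp recovery tolerance). Property suites run the aligner
against an exhaustive enumeration oracle on short random pairs and against
an independent library implementation on longer ones; microhomology
enumeration against an all-substring-pairs oracle on references up to
300 nt; and the off-target scanner against a per-position oracle on 5-kb
genomes with planted 0–5-mismatch sites. Every simulation seed is fixed
and every output is byte-deterministic: ties in alignment traceback,
allele ranking (read count, then key) and classification precedence are
all resolved by stated rules, and floats are serialized at 4 decimals with
percentages on the 0–100 scale.

Degenerate inputs are handled by contract: empty references locate
nothing; a guide without a site aborts profiling (and run_design warns and
writes empty tables); summaries of zero reads are an error, not a NaN;
fraction vectors must sum to 1 within 1e-9 and are asserted on every
summary.

## Worked example

```{r example}
amp <- bundled_amplicons()["TRBC1_2"]
site <- locate_target(guide("CRAFT_crRNA", bundled_guides()[["CRAFT_crRNA"]]),
                      amp, nuclease_profile("AsCas12a"))
fixture <- read_spectrum_config(bundled_spectrum("cas12a_craft"))
spectrum <- build_spectrum(fixture, amp, site, seed = 1)
spec <- sim_spec(amp, site, spectrum, n_reads = 2000, error_rate = 0.001,
                 mode = "paired_2x150", seed = 1001)
sim <- simulate_reads(spec)
res <- run_profile(amp, bundled_guides()[["CRAFT_crRNA"]], "AsCas12a",
                   sim$r1, sim$r2, out_dir = tempfile())
res$summary
```

## Known limitations

* Substitution-only reads are indistinguishable from WT by design; a locus
  whose edits are dominated by base-level changes needs a different tool.
* Microhomology is exact-match only; mismatch-tolerant (degenerate) MMEJ
  signatures are not detected.
* The off-target scanner is a search primitive, not a risk ranker.
* The generator's error model is substitution-only and position-uniform;
  it validates the pipeline's logic, not its robustness to homopolymer
  indel noise or chimeric reads.
* Multiple co-amplified loci are treated as a single consensus reference,
  matching the consensus-targeting design of the bundled guides; per-locus
  demultiplexing is out of scope.
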