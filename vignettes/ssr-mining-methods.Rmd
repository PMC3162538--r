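---
title: "Microsatellite mining and marker statistics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microsatellite mining and marker statistics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrmine)
```

## What the package computes

`ssrmine` implements the analysis chain used when a new set of
microsatellite (SSR) markers is developed for a crop species from genomic
and transcript sequence — the motivating case being carrot (*Daucus
carota*) and its relatives in the Apiaceae. The chain has four stages:

1. **SSR mining** in FASTA sequence: perfect tandem repeats of unit length
   2–8 nt (configurable 1–10), with compound loci formed from neighbouring
   perfect repeats.
2. **ORF placement**: a purpose-built open-reading-frame finder, and
   classification of every SSR as inside, outside, or bridging an ORF,
   with chi-square tests of the observed placement against the fraction of
   sequence inside ORFs and of motif-class counts against base-composition
   expectations.
3. **Marker panel statistics**: the polymorphism index (PI) from F2
   screening matrices, polymorphism-by-repeat-class summaries, segregation
   distortion tests, and cross-taxa transferability summaries.
4. **Diversity statistics**: per-locus allele counts, allele size ranges
   and unbiased expected heterozygosity from diploid genotype tables.

A seeded synthetic-data generator emulates all of the inputs with known
ground truth, so the whole chain is testable without any external data.

## SSR detection

A perfect SSR is reported when it satisfies **both** thresholds: total
span ≥ 12 nt *and* ≥ 3 complete repeat units (`ssr_search_config()`).
The conjunction means dinucleotides need 6 units, trinucleotides 4, and
tetra- through octanucleotides 3 — consistent with tetra- to
octanucleotide surveys whose mean unit counts sit at 3.0–3.3.

Detection is a leftmost-greedy scan per unit length (the semantics of the
widely used MISA mining tool): at each position the unit is the next *k*
bases, runs consist of complete units only, and scanning resumes after a
reported run. Two rules remove double counting:

* a run whose unit is a whole-number repetition of a shorter motif
  (e.g. `ACAC` = `AC`×2) is reported only at the shorter unit length;
* runs never cross an `N` (an `N` matches nothing).

Adjacent phase-shifted periodic regions admit more than one "maximal run"
reading; the leftmost-greedy convention resolves the ambiguity
deterministically and matches what a regex-based miner reports. The test
suite checks the detector against an independent brute-force scanner on
thousands of random sequences.

### Motif classes: rotation only, no reverse complement

The canonical class of a unit is the lexicographically smallest **cyclic
rotation** (`canonical_motif()`). A motif and its reverse complement are
*not* merged: `AG` and `CT` are distinct classes. This convention is
forced by the marker-development analyses the package reproduces, whose
dinucleotide and trinucleotide goodness-of-fit tables carry df = 5 and
df = 19, i.e. 6 and 20 classes — the rotation-only counts. (Conventions
that merge reverse complements would give 4 and 10.) This differs from
some MISA-adjacent summaries and is deliberate.

### Compound SSRs

Consecutive perfect repeats separated by at most `d_max` nt are merged
into one compound locus; its repeat count is the **sum** of the member
unit counts, which is also the convention used when markers whose
amplicon spans several repeats are binned by repeat number. `d_max`
defaults to 100 nt, the common MISA default; the surveys this package
follows do not state their interruption distance, so the value is
exposed in the configuration. Compound members are removed from the
perfect-only tally, so the two sets partition the detected loci.

## ORF detection

`find_orfs()` searches each reading frame (both strands by default —
BAC-end sequence is unoriented; `strands = "forward"` suits oriented
ESTs) for an `ATG` followed by an in-frame stop (`TAA`/`TAG`/`TGA`) at
least `min_orf_len = 100` nt downstream with no intervening in-frame
stop. The length is measured from the first base of the `ATG` to the
last base before the stop, so it is always a multiple of 3 and the stop
codon is excluded — the most literal reading of "a stop codon at a
distance of 100 nt or greater".

The requirement of "no intervening start or stop codons" is contradictory
for maximal ORFs (any long ORF may contain internal `ATG`s), so two start
rules are implemented and regression-tested:

* `start_rule = "longest"` (default): the first in-frame `ATG` after the
  previous in-frame stop — the standard maximal-ORF convention;
* `start_rule = "innermost"`: the last in-frame `ATG` before the stop —
  the literal reading.

When candidates from different frames or strands overlap, the longer ORF
is retained and the shorter discarded. Chains of overlaps (the original
description covers only the pairwise case) are resolved greedily by
descending length, with ties broken by smaller start and then `+` strand;
the result is independent of input order. Codons containing `N` match
neither start nor stop.

Each SSR is then `inside` (span fully within a retained ORF), `outside`
(disjoint from all), or `bridging` (partial overlap). Bridging SSRs are
excluded from the placement tests, mirroring the practice of discarding
repeats that straddle a frame boundary.

## Statistical models

**Expected motif distributions** use a zero-order (mononucleotide)
composition model: the probability of a unit is the product of its base
frequencies computed over the dataset's non-`N` bases, and a canonical
class's probability is the normalized sum over its rotations
(`expected_motif_probs()`). This is the most literal reading of an
expectation "calculated from the overall base composition"; a
dinucleotide-aware model is deliberately not attempted. Homopolymeric and
other non-primitive units are excluded, giving 6 dinucleotide and 20
trinucleotide classes.

**Goodness of fit** is the ordinary chi-square statistic with
df = classes − 1 (`chisq_gof()`, delegating to `stats::chisq.test`); an
expected count of zero is an error advising class pooling. Placement
tests (`placement_gof()`) are two-class chi-squares per repeat type, with
the expected inside count equal to *n* × (fraction of dataset bases
inside retained ORFs). Dataset comparisons of unit counts or repeat
lengths use the Welch unequal-variance t-test (`compare_datasets()`);
the source analyses say only "t-test", and Welch is the safer default.
With zero variance in both groups, equal means report p = 1 by
convention. P-values print with a `<0.0001` floor (`format_pvalue()`).

**Polymorphism index.** For one marker screened in *n* populations,

$$\mathrm{PI} = 100 \cdot \frac{2C + D}{2\,(n - n_d)}$$

with *C*/*D* the populations with codominant/dominant segregation and
*n<sub>d</sub>* the unscored populations. The printed formula's
bracketing is ambiguous; this precedence is the only reading that bounds
PI at 100 for the all-codominant case and gives 50 for all-dominant.
Ambiguous band patterns and failed amplifications count as scored but not
polymorphic (ambiguous patterns are treated as monomorphic, as in the
screening practice the package models); only `missing` enters
*n<sub>d</sub>*. Whether failed amplifications should instead count as
unscored is not documented in the source practice, so the call coding
keeps the two cases distinct and the choice can be revisited upstream of
`compute_pi()`.

**Segregation distortion** is tested against 1:2:1 (codominant, df = 2)
or 3:1 (dominant, df = 1), with distortion declared at p < 0.01.

**Transferability.** An amplicon within ±100 bp (`size_window`) of the
expected source-species size counts as a successful heterologous
amplification; when all fragments deviate further, the cell is
`off_size` and treated as negative. A marker is broadly transferable
when it succeeds in at least `high_rate = 0.8` of the non-source
accessions — with 15 such accessions that is 12 of 15, and 12/15 = 0.80
exactly, so the comparison is ≥ with a numerical tolerance.
Interspecific allele counts cluster fragment sizes by single linkage
with a 3 bp threshold, the resolving limit of high-resolution agarose
gels; in one dimension this reduces to splitting the sorted sizes at
gaps ≥ 3 bp.

**Expected heterozygosity.** Per locus,
$H_e = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$ over the *n*
non-missing gene copies — the unbiased gene-diversity estimator used by
Arlequin, which the diversity analyses this package models were run
with; `unbiased = FALSE` gives the plain $1 - \sum p_i^2$. Allele
identity is the exact fragment size in bp (capillary-resolution data);
the 3 bp gel rule applies only to the transferability module. Missing
genotypes drop out of *n* locus by locus; nothing is imputed.

The packaged reference table `carrot_diversity_panel.tsv` holds
per-locus reference statistics for a ten-SSR carrot diversity panel
(65 accessions). Its allele counts sum to 190 with sizes spanning
144–433 bp; the per-locus columns average to a mean heterozygosity of
0.834 and a mean allele count of 19.0 (summary figures sometimes quoted
for this panel, 0.84 and 19.1, reflect coarser rounding) — the package
always reports the full-precision recomputation.
Similarly, a density of 821 loci over 3.82 Mbp is 214.9/Mbp at one
decimal, where 214.8 was presumably computed from an unrounded total.

## The synthetic-data generator

`gen_sequences()` plants SSRs and ORFs into background sequence drawn
from the zero-order composition model, then *repairs* the background:
the record is rescanned with the package's own detector and ORF finder,
and any unintended feature is destroyed by point edits outside the
planted spans (or codon-level resampling inside ORF interiors), until
detection returns exactly the planted truth. Planted repeats receive
flank guards so they cannot be extended even by one base, and each
planted ORF is preceded by an in-frame stop so the longest-ATG rule
anchors at the planted start. This rejection-repair design keeps the
emitted ground truth exact by construction instead of reconciling it
after the fact. SSRs destined for ORF interiors are frame-aligned
trinucleotides from a stop- and start-free motif set, so they never
truncate their host.

Defaults emulate a BAC-end-like genomic sample: 600 bp records, 38.3% GC,
a repeat-type mix of roughly 17% di-, 41% tri-, 24% tetra- and 18%
longer-unit repeats, and unit counts just above the reporting thresholds
(Poisson excess means per type declining from 1.8 for dinucleotides to
0.05 for octanucleotides). These are the study conditions the package's
tests run under, chosen once from the magnitudes a genomic SSR survey of
a plant genome reports.

`panel_sim_spec()` drives the marker-panel generators. Screening calls
use a two-level model — a marker is polymorphism-prone with a
per-repeat-class probability, and a prone marker segregates in each
population independently — because per-class percent-polymorphic near
77–85% together with class mean PI near 22–26% cannot be produced by any
exchangeable per-population probability (PI would be capped near 19%);
marker-level propensity is also the biologically sensible reading. The
default class parameters (prone probability 0.76/0.76/0.93/0.77 and
per-population segregation 0.15/0.24/0.30/0.44 for the <6, 6–10, 11–15
and >15 unit classes) were calibrated once against that constraint.
Transferability uses 23 accessions in groups of 8 source-species, 8
congeneric and 7 confamilial accessions with success probabilities
0.86/0.58/0.41. The diversity preset draws 65 diploids at 10 loci from
the frequency vector (0.25, 0.2, 0.15, 0.1, 0.1, 0.1, 0.05, 0.05),
whose gene diversity is exactly $1 - \sum p^2 = 0.84$.

What the generator does **not** emulate: mutation processes on repeats
(no slippage model, no coalescent), linkage between markers, population
structure in the diversity panel, sequencing error, or base-composition
heterogeneity along a record. Passing tests therefore demonstrate the
correctness of the algorithms and estimators under the stated sampling
models, not robustness to those real-data complications.

## Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open; all exported files (GFF3,
  TSV) are 1-based inclusive.
* `N` bases are excluded from the GC denominator and never match a
  repeat unit or a codon.
* Mbp values print at 2 decimals and densities at 1 decimal in reports;
  underlying values keep full precision.
* The enrichment-library caveat: a density is meaningless for a
  hybridization-enriched SSR set (it is not a random genomic sample), so
  `repeat_type_table(density = FALSE)` suppresses it.
* Ties in ORF overlap resolution break by length, then start, then `+`
  strand, making the retained set order-independent; equal-length,
  equal-start candidates on opposite strands are ordered `+` first.
* `compute_pi()` returns `NA` when every population is missing;
  `pi_vs_repeats()` requires ≥ 3 markers with defined PI and errors on a
  zero-variance predictor.
* Chi-square tests refuse expected counts of zero rather than silently
  pooling.

## Problem sizes used in the checks

The test suite and the acceptance script run entirely on synthetic data:
oracle comparisons on 2–4 kb sequences across 100 seeds, recovery checks
on 4–8 records of 500–700 bp across dozens of seeds, 300-marker panels,
and 500-replicate estimator recovery at 65 diploids. These sizes were
chosen to exercise every code path with comfortable margins while
keeping a full run in the minutes range on one CPU; the algorithms
themselves are linear in sequence length and handle megabase inputs.

## Known limitations

* Only perfect repeats (plus the compound rule) are mined; imperfect or
  approximate repeats are out of scope.
* The ORF finder is a six-frame ATG-to-stop scanner — no splice
  awareness, codon-usage scoring, or gene prediction.
* The composition model for expected motif frequencies is zero-order.
* Primer design, linkage-map construction and QTL analysis are outside
  the package's scope.
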