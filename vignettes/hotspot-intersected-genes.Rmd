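---
title: "Hotspot-intersected gene analysis: models, parameters and design choices"
author: "recspot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hotspot-intersected gene analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recspot)
```

## The problem

Meiotic recombination in humans clusters in narrow hotspots. Genes whose
transcripts overlap a hotspot window — hotspot-intersected (HI) genes —
experience recombination at high frequency, which bears on both their
evolution (elevated substitution rates, gene duplication) and their
involvement in disease-associated chromosomal rearrangements. recspot
implements the full analysis around this idea: it classifies
recombination-map windows by standardized recombination rate (SRR),
derives the HI gene set (and the matched middle- and cold-spot sets MI
and CI) by interval intersection, and runs the downstream statistics —
gene-set overrepresentation, evolutionary-rate comparisons, hotspot-motif
and repeat-element enrichment, and fragile-site censuses.

Because the real inputs (a deCODE-style standardized sex-averaged map,
RefSeq autosomal protein-coding genes, curated gene databases, ortholog
rate tables, RepeatMasker annotations) are large external resources, the
package also ships a synthetic-data generator that emulates every input
with controllable planted effects and a recorded ground truth. All
calibration and recovery claims below are statements about that
generator, not about the human data.

## Spot classification

A recombination map is a set of fixed-width windows (10 kb by default)
carrying SRR, the window rate divided by the genome average. The
classification rules are threshold rules with strict inequalities:

* **hot**: SRR > 10,
* **middle**: 0.1 < SRR < 1,
* **cold**: SRR = 0.

A window with SRR exactly 10 (or 0.1, or 1) is therefore in no set, and
windows between 1 and 10 are deliberately unclassified. Each passing
window is one spot; contiguous passing windows are *not* merged, so spot
counts are in units of map resolution. Middle and cold spots are sampled
down (uniformly, without replacement) to the hotspot count so the three
gene sets rest on equally many spots.

Coordinates are 0-based half-open (BED convention) in every file format
and 1-based closed inside `GRanges` objects; the readers convert.
Intersection requires at least `minOverlap` bases (default 1) of genuine
overlap — abutting intervals share no base and do not intersect — and
strand is ignored throughout, since spots are unstranded.

## Enrichment statistics

Every 2×2 question uses the same engine. For a query set of size
$n_q$ and a target set of size $n_t$ over a background of $N$ genes, the
expected overlap under independence is $e = n_q n_t / N$ and the signed
fold enrichment of an observed overlap $o$ is

$$\mathrm{FE} = \begin{cases} o/e, & o \ge e\\ -e/o, & o < e, \end{cases}$$

so a depletion prints as the negative reciprocal (−4.3 means 4.3-fold
depleted) and $|\mathrm{FE}| \ge 1$ always; $o = 0$ yields an undefined
FE (reported `NA`) with the expected count retained rather than a
pseudo-count. Significance is the two-sided Fisher exact p-value,
computed by summing all hypergeometric table probabilities not exceeding
the observed one (relative tolerance 1e−7 against floating-point ties;
underflowing sums are floored at the smallest positive double so
downstream FDR machinery keeps a valid domain). Two-sidedness is used
throughout because the same framework must report both enrichment and
depletion. Symbols are uppercased on both sides before matching, and
query/target symbols absent from the background are dropped with a
logged count.

Batch scans (the gene-set panel, per-branch tests, per-motif tests,
per-repeat-element tests) carry a within-table Benjamini–Hochberg
q-value. The pipeline's run-level `findings` table additionally pools
*all* batch hypotheses of a run under one BH adjustment at the
configured FDR (default 0.05): a screen that spans several families
spends one discovery budget, which keeps the end-to-end false-finding
rate at the nominal level under a global null. Single planned
comparisons — the rate comparisons and the duplicated-gene proportion —
are reported with raw p-values and are not findings candidates.

## Evolutionary-rate comparisons

Per-gene dN, dS and dN/dS are inputs (a table, not an alignment step).
When a supplied dN/dS disagrees with dN/dS recomputed from the same row
(rounding in source tables), the supplied value wins. Genes appearing
twice contribute their first row after sorting. Before comparing, shared
genes are excluded: comparisons of the HI set against housekeeping-,
tissue-specific- or secreted-protein-like sets remove the pairwise
intersection from both sides; comparisons among HI/MI/CI keep only genes
unique to each set. Missing values are dropped per metric, not listwise,
to maximise usable sample sizes.

The test is the two-sided Wilcoxon rank-sum: exact when the combined
sample size is ≤ 20 with no ties, otherwise the normal approximation
with tie and continuity corrections. The reported `direction` is the
sign of the comparison-set median minus the reference (HI) median, so a
"−" row reads "lower than HI".

## Motif and repeat analyses

The three canonical hotspot motifs (CCTCCCT, CCCCACCCC, CCNCCNTNNCCNC)
are scanned with a degenerate matcher over the alphabet A/C/G/T/N in
which motif N matches any unambiguous base but sequence N matches
nothing — an unknown base is never evidence. Overlapping occurrences all
count. Both strands are scanned by default (the motifs act on
double-stranded DNA); matches of the reverse-complement pattern at an
already-matched start are not double counted, so palindromes behave.
The enrichment unit is the *region*: the 2×2 compares
motif-bearing-region proportions between two region sets, which matches
the "elevated proportions in gene regions" framing; per-region
occurrence counts are available from `countMotif()` for density-style
analyses.

Repeat-element enrichment compares instance counts of one element
against all other elements between two region sets (e.g. hot windows vs
the autosomal complement). An instance belongs to a set if it overlaps
any of its intervals by ≥ 1 base, and may belong to both. Elements with
no instance in either set, or with no other-element margin, are skipped
with a log entry. The all-other-elements margin makes the test
compositional: planting some elements at high density in set A makes
neutral elements appear depleted there. This is a property of the
margin, not a bug; the element-level `significant` call therefore
requires both q < FDR and FE > 1.

## The synthetic-data generator

The generator emulates the statistical structure of the real inputs at
roughly one-tenth scale, the default chosen so a full bundle generates
and analyses in seconds: 4 chromosomes × 20 Mb tiled into 8,000 windows
of 10 kb, 1,800 genes with lognormal lengths (median 20 kb), 1–4
nested/overlapping transcripts per gene, and a hotspot fraction of 0.05
(≈ 400 hotspots, a tenth of the 4,008 at full scale). SRR is drawn from
a three-part mixture: hot windows take 10 + lognormal(meanlog 1, sdlog
0.5); non-hot windows are exactly 0 with mass 0.3 (the cold atom) or
follow 10·U² on (0, 10], which is skewed low so middle spots (0.1–1) are
plentiful. No published SRR distribution exists; these laws only need to
exercise the thresholds realistically.

Planted effects, all recorded in a versioned `truth` object:

* **Gene sets** — for planted enrichment $f$, target size $s$, query
  size $H$ and background $N$, membership is Bernoulli with probability
  $f p_0$ for query genes and $p_0 = s/(Hf + N - H)$ otherwise, hitting
  $s$ in expectation. Note the *marginal* FE recovered by the 2×2 is
  $fN/(Hf + N - H)$, slightly below $f$ when the query is a nontrivial
  fraction of the background — recovery tests use bands, not equality.
  The default planted magnitudes mirror the published pattern:
  housekeeping depletion (f = 0.23 ≈ 1/4.3), tissue-specific 1.3,
  secreted 1.4, disease sets 1.3–2.9 with the chromosomal-rearrangement
  set highest.
* **Rates** — baseline dN ~ lognormal(log 0.07, 0.7) and dS ~
  lognormal(log 0.5, 0.4) with 2% of dS drawn exactly 0 (dN/dS is then
  absent). A per-set shift δ adds δ to dN and 2δ to dS, which moves dN,
  dS *and* dN/dS in the direction of δ under the baseline law — one
  knob reproduces the full sign pattern (housekeeping − − −,
  tissue-specific/secreted + + +, middle/cold-intersected −). Genes in
  several shifted sets take the first set in the priority order (the
  order of the shift vector; tissue before housekeeping by default).
* **Branches** — evolutionary ages 0–12 with a controllable branch-0
  probability for HI genes (default 0.8 vs 0.55 background, mirroring
  the ~80% of HI genes in the oldest branch) and geometric decay over
  younger branches; 90% of genes receive an assignment, as age
  catalogues are incomplete.
* **Sequences** — i.i.d. uniform bases, 1,000 bp per region by default,
  with one motif instance planted per region at the class-specific
  rate. Short motifs also occur by chance in random sequence (the
  7-mer's chance presence in 1 kb is ≈ 0.1), so planted rates sit on a
  baseline shared by both classes; null comparisons are unaffected.
* **Repeats** — a marked point process with per-element intensity
  5e−5/base (one instance per 20 kb) in the background class, scaled by
  the planted density ratio in the hot class; instance lengths uniform
  150–300 bp.

One global seed fans out deterministically into per-stage child seeds,
so every stage is independently reproducible and a bundle is
byte-reproducible across runs. What the generator does *not* attempt:
real chromosome lengths, GC content, linkage between neighbouring
windows, overlapping real gene-set semantics, or real motif/repeat
biology. Passing tests on synthetic data therefore demonstrate that the
statistical machinery is correct and calibrated — not that the
biological conclusions transfer to any particular real dataset.

## Pipeline and reporting

`runPipeline()` drives the stages from one configuration (an R list, a
YAML file, or a simulated bundle): classify → sample → intersect →
HI/MI/CI sets → coverage summary → enrichments → rate comparisons →
branch/motif/repeat/fragile stages → pooled findings. The map and gene
models are required; every other stage is optional and is skipped with a
logged reason when its input is missing or its preconditions fail
(e.g. an empty HI set under an unreachable threshold). Logs record the
stage tallies (windows read, spots classified, genes per set) because
those tallies are exactly the headline counts such an analysis reports.
`writeReport()` emits one TSV per table, the gene lists, a
machine-readable `summary.json` with provenance (seed, thresholds,
configuration hash, package version) and the run log; outputs are
deterministic for a fixed configuration and seed.

## Numerical and edge-case choices

* Fisher p-values: exact hypergeometric summation at all sizes reached
  in practice (`dhyper` works in log space internally); ties in the
  probability comparison tolerate 1e−7 relative error.
* `sampleSpots()` restores the caller's RNG state; explicit seeds keep
  sampling reproducible without global side effects.
* Degenerate inputs: empty maps classify to three empty spot sets; an
  empty intersection yields a summary of `NA` statistics; exclusion
  that empties a set, zero backgrounds, and malformed files raise
  informative errors naming the offender.
* Merging uses `min.gapwidth = 0`, so regions that merely abut are kept
  separate — merging requires a shared base, consistent with the
  half-open intersection convention.
* Test problem sizes: the end-to-end calibration and recovery suites
  run 20-seed batches on a 2 × 10 Mb genome with 600 genes, and
  module-level recovery uses 60–100 seeds at the sizes stated in each
  test; these sizes were chosen so the whole suite completes in a few
  minutes while leaving the binomial error of each recovery band well
  inside its tolerance.

## Limitations

* The repeat-enrichment margin (other elements) is one of several
  defensible constructions (non-repeat bases being the main
  alternative); compositional depletion of neutral elements is expected
  when other elements are strongly enriched.
* Only the sign pattern of the published rate comparisons is
  reproducible; the underlying medians and p-values of the original
  tables are not public, so tests assert directions, not magnitudes.
* Whether published motif proportions were per-region presence or
  per-base density is ambiguous; presence is implemented as the primary
  reading, with counts exposed for the density reading.
* GO/DAVID-style term enrichment and ortholog-rate estimation are out
  of scope; rates and gene sets are inputs.
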