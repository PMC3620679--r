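# recspot

Analysis of **recombination hotspot intersected (HI) genes**: the set of
protein-coding genes whose transcripts overlap meiotic recombination
hotspots, and what that overlap implies for gene evolution and
disease-associated chromosomal rearrangements.

Human recombination clusters in narrow hotspots. Given a standardized
recombination map (fixed-width windows carrying the standardized
recombination rate, SRR), recspot

* classifies windows into **hot** (SRR > 10), **middle** (0.1 < SRR < 1)
  and **cold** (SRR = 0) spots, sampling middle and cold spots down to
  the hotspot count;
* intersects transcript models with each spot set (≥ 1 shared base,
  strand-blind, BED half-open conventions) to derive the HI, MI and CI
  gene sets, merges HI transcripts into non-overlapping regions and
  summarises hotspot coverage;
* tests gene sets (housekeeping, tissue-specific, secreted-protein,
  duplicated, disease-associated, ...) for over/underrepresentation in
  HI genes with the two-sided Fisher exact test and **signed fold
  enrichment**: for observed overlap *o* and expected
  *e = n_query · n_set / N*, FE = *o/e* when *o ≥ e* and −*e/o*
  otherwise, so −4.3 reads "4.3-fold depleted";
* compares evolutionary rates (dN, dS, dN/dS) between gene sets with
  the two-sided Wilcoxon rank-sum test after removing shared genes;
* scans degenerate hotspot motifs (CCTCCCT, CCCCACCCC, CCNCCNTNNCCNC)
  over region sequences, tests motif-bearing-region proportions, runs
  per-repeat-element enrichment between region sets with
  Benjamini–Hochberg control, and censuses fragile-site/transcript
  overlap;
* ships a **synthetic-data generator** producing every pipeline input
  with planted, recorded effects (fold enrichments, rate shifts, motif
  rates, repeat density ratios) for calibration and parameter-recovery
  testing;
* orchestrates everything through `runPipeline()` from one
  configuration, with per-stage logging, skip handling and a pooled
  FDR "findings" table.

## Worked example

The headline depletion statistic from published gene counts — 18,166
background autosomal protein-coding genes, 1,156 HI genes, 1,974
housekeeping genes, 29 genes in the overlap:

```r
library(recspot)
fe <- foldEnrichment(observed = 29, nQuery = 1156, nSet = 1974,
                     nBackground = 18166)
sprintf("expected %.1f, FE %.1f", fe$expected, round(fe$fe, 1))
#> "expected 125.6, FE -4.3"
```

Under independence ~126 housekeeping genes would fall among the HI
genes; 29 were observed, a 4.3-fold depletion.

A full synthetic run (one-tenth-scale genome, planted effects mirroring
the published magnitudes):

```r
b <- simulateBundle(seed = 1)          # map, genes, sets, rates, ...
rep <- runPipeline(b)
rep
#> recspot analysis report
#>   HI/MI/CI genes: 259/292/312
#>   HI regions: 192 (51% contain a full hotspot)
#>   findings at FDR: 18
head(rep$setEnrichment[, c("target", "observed", "expected", "fe", "p", "q")], 4)
#>   target observed expected    fe        p        q
#> 1     HK        8     27.5 -3.44 3.19e-06 3.19e-05
#> 2  TiGER       77     66.5  1.16 1.07e-01 1.34e-01
#> 3    SPD       37     24.2  1.53 5.27e-03 1.32e-02
#> 4    DGD       63     61.0  1.03 7.52e-01 7.52e-01
```

The planted housekeeping depletion (membership ratio 0.23) is recovered
as a significant negative FE; the neutral duplicated-gene set (planted
ratio 1) stays flat. `rep$findings` lists every batch hypothesis that
survives the pooled Benjamini–Hochberg adjustment, `writeReport(rep,
dir)` writes the tables, gene lists, `summary.json` and run log, and
`b$truth` holds the generating parameters for comparison.

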