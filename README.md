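# enhancersens

Genome-wide classification of PPARγ-bound enhancers by activation
status, mutation sensitivity, chromatin accessibility, and
response-element strength — as a tested, reusable R pipeline.

## The scientific problem

PPARγ drives adipocyte differentiation by binding PPREs: degenerate DR1
elements (5'-AGGTCA-3' repeated with a 1-bp spacer, PPARγ on the 5'
half-site, RXR on the 3' half-site) preceded by a 5' extension that the
receptor hinge contacts in the minor groove. Lipodystrophy-associated
point mutations in different receptor domains — R212Q in the hinge,
E379K in the ligand-binding domain — do not abolish function; they
impair binding at *subsets* of genomic sites, depending on basal
chromatin accessibility and the strength of the motif's segments.
Dissecting which enhancers each mutation disables, and why, requires a
chain of genome-scale steps that this package implements end to end:

* **Peak calling** with a local Poisson background (500-bp windows,
  ≥4-fold over ±10 kb local signal, exact Poisson `p < 1e-4`, 4-fold
  over a depth-scaled control; 35-tag floor and blacklist filtering) —
  greedy selection provably equivalent to exhaustive 1-bp enumeration.
* **Window quantification** of H3K27ac (±1500 bp), Med1, factor and
  nucleosome-free ATAC signal (±250 bp; fragments ≤ 120 bp).
* A self-contained **negative-binomial Wald test**
  (`Var = μ + dμ²`, pooled method-of-moments dispersion, delta-method
  SE on `log2` fold changes, Benjamini–Hochberg correction).
* **Enhancer taxonomy**: activation targets (mark gain at FDR < 0.1),
  mutation-sensitivity groups (`padj < 0.05` and ≥25% intensity loss per
  mutant), accessibility classes (normalized nucleosome-free counts
  vs 15), remodeling calls, and rank-based ROC evaluation of predictors.
* **PWM scanning** in natural-log odds with DR1 dissection into the 5'
  extension (bases 1–4), PPARγ half-site (5–10), spacer (11) and RXR
  half-site (12–17); segment scores sum exactly to the full score.
* **Gene-level analysis**: induced/repressed calls (FDR < 0.05, fold
  > 1.5), mutant-sensitivity classes, and enhancer-vicinity enrichment
  normalized by 10 draws of 200 non-regulated genes.
* **Spectroscopy utilities**: CD helicity
  `%H = ([θ]₂₂₂ − 3000)/(−36000 − 3000)` and Cα secondary chemical
  shifts with transient-helix calling (runs of ≥4 positive SCS).
* A **synthetic-data generator** that plants all of the above —
  motif-segment strengths, accessibility, per-condition binding, linked
  gene expression — with a truth table, so the full pipeline is
  validated against a known answer.

## Worked example

```r
library(enhancersens)
manifest <- run_all(sim_config(), seed = 1)
manifest
#> run_manifest (seed 1)
#>   peaks: 1702; targets: 394 (H3K27ac 387, Med1 389, both 382)
#>   groups: dual=98, E379K_only=95, R212Q_only=99, insensitive=102, gained=0, other=0
#>   recovery accuracy: 0.97; basal-Med1 AUC: 0.98
validate_manifest(manifest)
#> character(0)
```

Reading: of 1900 planted binding sites (400 activation targets + 1500
constitutive sites), 1702 survive calling and filtering; 394 are called
targets (gain of H3K27ac and/or Med1, FDR < 0.1); the four
mutation-sensitivity groups are recovered at 97% accuracy against the
generator's truth table; basal Med1 signal predicts mutation
sensitivity with AUC 0.98 (low basal activity → sensitive).
`validate_manifest()` confirms the internal count identities
(inclusion–exclusion of the mark union, groups partitioning targets,
induced + repressed = total regulated genes).

Individual stages are ordinary functions — `call_peaks()`,
`quantify()`, `nb_wald()`, `define_target_enhancers()`,
`classify_sensitivity()`, `scan_peaks_motif()`,
`vicinity_enrichment()`, `helicity_from_cd()` — see their help pages
and the methods vignette (`vignettes/enhancer-sensitivity-methods.Rmd`).

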