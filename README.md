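# erenet

Promoter motif scanning, estrogen-response-element detection, and
transcription-factor network ranking in R.

## The problem

Given a curated set of disease-associated genes, which transcription
factors (TFs) plausibly sit upstream of many of them — and which of those
are tied to estrogen signalling? `erenet` answers this with a
promoter-centric pipeline aimed at analysts nominating candidate
regulators (and hence candidate biomarkers) from a gene list:

1. **TFBS prediction.** Promoter windows `[-1000, +200]` around each TSS
   are scanned on both strands with a PWM library using Match-style
   scores. For a frequency matrix *f(i,b)* with information vector
   *I(i) = Σ_b f(i,b) ln(4 f(i,b))*, each window scores

   *MSS = (Current − Min) / (Max − Min)*, *Current = Σᵢ I(i) f(i, sᵢ)*,

   plus a core score (CSS) over the 5 most informative consecutive
   positions. Per-matrix cutoffs emulating a minimal-false-positive
   profile are calibrated on a background promoter set (default: the
   smallest cutoff admitting ≤ 0.5 background hits/kb).
2. **ERE detection.** The palindromic estrogen response element
   `GGTCA-nnn-TGACC` is matched with up to 2 half-site mismatches; genes
   are partitioned into four groups by ERE status × documented
   estrogen-responsiveness, and groups 1 ∪ 3 form the "experimentally
   controlled" set.
3. **Enrichment.** Each matrix gets an over-representation index against
   the background — a hit-density ratio times a promoter-coverage ratio —
   and only matrices with ORI ≥ 2 contribute network edges.
4. **Ranking.** TFs are ranked by out-degree (distinct genes with an
   enriched-matrix hit); TFs at or above the nearest-rank 80th percentile
   of out-degrees are retained as candidates.
5. **Site statistics.** TFBS-to-ERE distances, TFBS density around the
   TSS (Gaussian kernel, 512-point grid), and annotation-term fractions
   per group.

A seeded synthetic-cohort generator (`cohort_spec()`,
`paper_shape_spec()`, `generate_cohort()`) plants motifs and EREs at
controlled rates with a truth ledger, so the whole chain is testable end
to end. See `vignettes/methods.Rmd` for the models, defaults and design
choices.

## Worked example

Generate a reference-shaped synthetic cohort (323 target genes, 65 ERE
carriers of which 11 evidenced, 200 background promoters, 33-matrix
panel with 5 strongly and 20 moderately enriched TFs) and run the full
pipeline:

```r
library(erenet)
res <- run_synthetic_cohort(paper_shape_spec(seed = 7))
vapply(res$groups, length, 1L)
#>   1   2   3   4
#>  11  54  66 192
length(res$experimental_union)
#> [1] 77
head(res$rankings$full, 6)
#>   tf_id out_degree rank retained
#> 1 TF002        227    1     TRUE
#> 2 TF004        221    2     TRUE
#> 3 TF005        219    3     TRUE
#> 4 TF003        218    4     TRUE
#> 5 TF001        209    5     TRUE
#> 6 TF018        172    6     TRUE
sum(res$ori$full$enriched)
#> [1] 25
```

Reading the output: the four groups split the 323 genes by (ERE
predicted, evidence) — here exactly (11, 54, 66, 192) because the
generator's deterministic mode fixes the margins — and the union of
groups 1 and 3 gives the 77 experimentally estrogen-controlled genes.
In the full-set ranking the five strongly planted TFs (TF001–TF005)
occupy the top five out-degrees (~210–230 of 323 genes each) and are
retained above the 80th percentile, while the moderately planted TFs
(~170 genes) fill the rest of the 25 enriched matrices and the null TFs
are filtered out by the ORI ≥ 2 rule. Per-group and experimental-union
rankings, ORI tables, BED site files, distance histograms and the TSS
density are written under the run's output directory.

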