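# rejuvomics

Downstream computational analysis for partial chemical reprogramming
experiments — fibroblasts treated with small-molecule cocktails and
profiled by bulk RNA-seq and DNA-methylation arrays. The package is
aimed at computational biologists who need the bespoke statistics of
such studies as tested, reusable functions rather than one-off
scripts:

* **Splicing damage.** Percent-spliced-in from junction counts,
  `psi = (I/len_I) / (I/len_I + S/len_S)`; replicate-level differential
  splicing (`|ΔΨ| > 0.1`, BH FDR < 0.05); protein-consequence
  classification of each event into frameshift / premature stop /
  domain loss / no disruption / noncoding by re-splicing the altered
  isoform and re-translating its ORF; and the damage proportion — the
  fraction of events predicted to disrupt protein function.
* **Signature association.** Preranked GSEA on the signed metric
  `-log10(p) * sgn(lfc)` with a gene-sampling permutation null
  (5000 permutations, NES normalized by the same-sign null mean,
  FDR 0.1), signature construction (top 500 significant genes by
  |logFC|), and pairwise signature correlation (Spearman over the
  union of each table's top 650 lowest-p genes).
* **Transcriptomic clocks.** Linear age predictors over standardized
  `log2(expr + 1)` clock-gene values with training-mean imputation of
  undetected genes, and Welch contrasts of predicted age between
  treatments.
* **Expression processing.** The 5-reads-in-20%-of-samples filter,
  relative log expression (median-of-ratios) normalization, and a
  simple two-group differential-expression test feeding the metric,
  signatures and clocks.
* **Methylation.** Probe filtering, beta→M conversion, per-probe
  differential methylation (`|lfc(M)| > 1`, FDR < 0.05), and
  chromatin-state enrichment of DMPs via odds ratios with one-sided
  hypergeometric tests, reported as signed log10 adjusted p-values.
* **Synthetic data with ground truth.** A generator that designs toy
  genomes whose splicing events realize each consequence category by
  construction, plus binomial junction counts, negative-binomial
  expression, logistic-normal methylation with state-structured DMPs,
  and clock expression built by inverting a known clock — so every
  stage is validated by parameter recovery.

## Worked example

```r
library(rejuvomics)

sim <- simulateGenomeAnnotation(seed = 42, nGenes = 60)
cnt <- simulateSplicingCounts(sim$events, psiControl = 0.5,
                              delta = rep(c(-0.3, 0, 0.3), 20),
                              nReps = 4, depth = 200, seed = 43)
ds  <- differentialSplicing(psiMatrix(cnt$counts), cnt$groups)
calls <- classifyConsequences(sim$transcripts, sim$events,
                              sim$genome, sim$domains)
table(calls$category)
#>      domain_loss       frameshift    no_disruption noncoding_region
#>                6                6               33                9
#>   premature_stop
#>                6

splicingDamage(calls, records = ds, mode = "differential")
#>   n_events n_damaging proportion
#> 1       40         11      0.275

head(ds[ds$selected, c("event_id", "type", "delta_psi", "fdr")], 3)
#>     event_id type  delta_psi          fdr
#> 1 ev_gene001   SE -0.3054783 5.986363e-05
#> 3 ev_gene003 A5SS  0.2937500 7.544328e-05
#> 4 ev_gene004 A3SS -0.3462500 1.258789e-04
```

Forty of the sixty events were simulated with a true `|ΔΨ| = 0.3` and
are selected; among them 11 (27.5%) carry a damaging consequence
call — recovering the 30% damaging mix the generator was asked for.
The consequence table itself matches the designed categories exactly
(6 / 6 / 6 damaging, 9 UTR-confined, 33 neutral).

`runPipeline(defaultConfig(seed = 1), "out/")` chains every stage —
annotation, Psi, differential splicing, consequence calls, damage,
expression, signatures/GSEA, clocks, methylation — writing annotated
TSVs plus a `manifest.json` of MD5 checksums; rerunning with the same
configuration skips up-to-date stages and reproduces identical
checksums. A thin CLI over the same functions ships in
`inst/scripts/rejuvomics-cli.R` (subcommands `simulate`, `psi`,
`diff-splice`, `consequence`, `damage`, `de`, `gsea`, `assoc`,
`sig-corr`, `clock`, `dmp`, `state-enrich`, `screen`, `run-all`).
Output formats are described in `FORMATS.md`.

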