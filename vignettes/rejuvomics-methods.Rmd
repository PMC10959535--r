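---
title: "Methods: quantifying splicing damage, transcriptomic age and methylation remodelling"
author: "rejuvomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying splicing damage, transcriptomic age and methylation remodelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rejuvomics)
```

# Scope

Partial chemical reprogramming experiments — fibroblasts treated for a
few days with small-molecule cocktails — are typically profiled with
bulk RNA-seq and DNA-methylation arrays and analysed along several
axes: does treatment reduce the burden of protein-damaging splice
isoforms, does it move the transcriptome toward established
rejuvenation signatures, does it lower the age predicted by
transcriptomic clocks, and how is the methylome remodelled across
chromatin states? `rejuvomics` implements these downstream analyses as
a single tested toolkit, together with a synthetic-data generator that
produces every input with known ground truth, so that each stage can
be validated by parameter recovery rather than by eyeballing.

This vignette records the models, the tunable parameters, and the
design decisions taken where the analysis recipe left genuine freedom.

# Splicing damage

## Psi and differential splicing

For each alternative-splicing event (exon skipping SE, intron
retention RI, alternative 5'/3' splice sites A5SS/A3SS, mutually
exclusive exons MXE) the percent-spliced-in statistic is the
length-normalized inclusion ratio

$$\Psi = \frac{I/\ell_I}{I/\ell_I + S/\ell_S},$$

where $I$ and $S$ are inclusion- and skipping-supporting junction read
counts and $\ell_I, \ell_S$ the effective junction lengths. $\Psi$ is
reported as missing below a coverage floor of $I+S \ge 10$ reads (a
conventional junction-coverage floor; the estimate is unstable below
it).

Differential splicing between two groups is tested per event with a
Welch $t$ test on replicate-level $\Psi$ values, followed by
Benjamini-Hochberg adjustment across all tested events; an event is
*selected* when $|\Delta\Psi| > 0.1$ and FDR $< 0.05$. A raw p-value
selection mode (`selectBy = "pvalue"`) is exposed as well, because
both variants of the cutoff are in circulation for this analysis.
This replicate-level test deliberately replaces the hierarchical
likelihood model of junction-count tools: at the $n = 4$ replicates
the package targets, a replicate-aware $t$ test is transparent,
deterministic, and adequate, and the substitution is recorded in the
run manifest. Events with fewer than two quantified replicates in
either group are reported as untested and excluded from the BH family.

## Protein-consequence classification

Each event is anchored on a host transcript (the generator assigns one
transcript per event; with real annotations the caller chooses the
isoform, since the analysis convention does not dictate one). The
isoform that *deviates* from the annotated transcript — exclusion for
SE/MXE, inclusion (retention/extension) for RI/A5SS/A3SS — is rebuilt
base-by-base, its mRNA re-spliced, and the ORF re-translated from the
unchanged start codon. Classification applies a fixed precedence:

1. `noncoding_region` — the alteration lies entirely outside the
   coding span;
2. `frameshift` — the net altered coding length is not a multiple of 3;
3. `premature_stop` — re-translation terminates before the in-frame
   expectation (canonical protein length adjusted by the in-frame
   indel);
4. `domain_loss` — the removed codons (or the insertion-junction
   codons) overlap an annotated protein-domain interval;
5. `no_disruption` otherwise.

The precedence makes the categories mutually exclusive and
deterministic; frameshift outranks premature stop because a shifted
frame subsumes essentially all downstream stops. A premature stop is
*any* new in-frame stop before the canonical one — no
nonsense-mediated-decay 50-nt junction rule is applied, the simplest
reading of "introduces a premature stop codon".

The **splicing damage proportion** is the fraction of events whose
category is damaging (frameshift, premature stop, or domain loss).
Two denominators are offered, because either can be meant by a
per-comparison damage figure: `differential` mode uses the selected
differentially spliced events; `standing` mode computes, per sample,
the fraction of covered events whose damaging isoform is present at
$\Psi \ge 0.1$ (aligned with the $\Delta\Psi$ cutoff; the per-sample
denominator convention is otherwise unspecified). Group comparisons of
standing damage use one-way ANOVA with pairwise Welch contrasts and BH
correction in place of a studentized-range post hoc.

# Expression processing

Counts are filtered by the rule *at least 5 reads in at least 20% of
samples*, with the boundary inclusive (2 of 10 samples qualifies — the
literal reading). Normalization is relative log expression
(median-of-ratios): reference genes are those with strictly positive
counts in every sample, and a sample's size factor is
$\exp(\mathrm{median}(\log c_g - \overline{\log c_g}))$ over reference
genes — the geometric-median interpolation convention of the standard
RLE implementation, which a test cross-checks against DESeq2 to
$10^{-10}$.

Differential expression is a per-gene Welch $t$ on
$\log_2(\text{normalized} + 1)$ with BH adjustment; the pseudo-count
makes zeros representable and is stated explicitly wherever the scale
matters. The downstream consumers (ranking metric, signatures,
clocks) need only per-gene $(p, \mathrm{lfc})$ pairs, which is why a
transparent two-group test replaces a negative-binomial framework
here; the substitution is logged per run. The exposed design is a
two-group comparison per stratum (e.g. treatment vs control within an
age group) — multi-factor designs with interactions are out of scope.

# Signature association by preranked GSEA

Genes are ranked by the signed metric
$-\log_{10}(p)\cdot\mathrm{sgn}(\mathrm{lfc})$, with $p$ floored at
$10^{-300}$ before the logarithm and ties broken by gene identifier
for cross-platform determinism. The enrichment score is the extremum
of the weighted running sum (hit steps proportional to
$|r|^{w}$ normalized within the set, miss steps $1/(N-|S|)$; $w = 1$
by default, $w = 0$ gives the unweighted Kolmogorov-Smirnov-style
statistic). The null is fgsea-style *gene-set sampling*: random
same-size sets drawn from the ranked universe, 5000 permutations by
default, with one shared null per distinct set size. P-values are
add-one corrected within same-sign null scores, the normalized
enrichment score divides by the mean absolute same-sign null ES, BH
runs across all scored sets, and FDR $< 0.1$ flags significance.
Minimum set size after intersection with the universe defaults to 5;
sets disjoint from the universe yield per-set error records rather
than aborting a run.

Expression signatures are built as the top 500 genes by $|\mathrm{lfc}|$
among those with adjusted $p < 0.05$; pairwise signature correlation
is the Spearman correlation of log fold changes over the union of each
table's top 650 lowest-p genes.

# Transcriptomic clocks

A clock is a linear predictor
$\mathrm{tAge} = \beta_0 + \sum_g w_g z_g$ on standardized
$\log_2(\text{expr}+1)$ clock-gene values. "Scaling" is interpreted
as z-scaling against *training* statistics stored in the model file:
imputation of undetected clock genes with precalculated averages only
makes sense against fixed training moments, so per-dataset
standardization (also available) is not the default. Imputation
happens on the log scale before standardization, matching "not
detected" being a property of count space; with imputation values
equal to training means, a fully imputed sample predicts exactly the
intercept. Group contrasts of predicted ages are Welch $t$ tests per
treatment-vs-control pair within each age stratum.

# DNA methylation

Probes are kept only with complete beta values and detection
$p \le 0.01$ in every sample. Analysis operates on M-values
$\log_2(\beta/(1-\beta))$ after clamping $\beta$ to
$[10^{-6}, 1-10^{-6}]$. Per-probe two-group Welch tests on M-values
replace moderated linear models (at $n \ge 5$ per group the moderation
changes little; the substitution is logged), and a probe is a DMP when
$|\mathrm{lfc}_M| > 1$ and FDR $< 0.05$, where $\mathrm{lfc}_M$ is the
difference of group-mean M-values (the natural reading for signed
M-values).

Chromatin-state enrichment forms, per state and DMP direction, the
2×2 table over the analyzed probe universe (the probes surviving
filtering, not the whole array), computes an odds ratio with Haldane's
+0.5 correction when a cell is empty, and tests the upper
hypergeometric tail for enrichment (OR > 1) or the lower tail for
depletion. Enrichment and depletion tests enter a single BH family,
and results are reported as signed $\log_{10}$ adjusted p-values:
$-\log_{10}(p_\mathrm{adj})$ signed $+1$ for enrichment, $-1$ for
depletion. Probes mapped to several states keep the first-listed state
with a warning (one state per probe, following the universal
chromatin-state annotation convention).

# The synthetic-data generator

The generator is the package's test surface; it emulates the study
design, not the full complexity of real data.

* **Annotation.** Every gene is designed backwards from a canonical
  mRNA (9-nt 5'UTR, 78 stop-free codons, TAA, 3'UTR) cut into four (or
  six, for UTR events) exons, on a randomly chosen strand;
  minus-strand genes are written reverse-complemented into the toy
  genome. The gene's splicing event realizes a requested consequence
  category *by construction*: exon boundaries are codon-aligned except
  where a frameshift is intended (an SE exon of 100 nt, an intron of
  61 nt, a 7-nt splice-site shift), inserted intronic segments are
  stop-free codons unless a premature stop is intended (a TAA placed
  in frame), and domains are placed exactly on — or safely away from —
  the affected codons. Category proportions are realized as exact
  counts (largest remainder); the default mix places 30% of events in
  damaging categories, the fraction the damage-recovery analyses are
  calibrated around. The alphabet excludes N inside CDS so translation
  is deterministic.
* **Junction counts.** $I \sim \mathrm{Binomial}(d, p^*)$ per
  replicate with $p^*$ the read-level inclusion probability implied by
  the length-normalized $\Psi$; defaults of 4 replicates per group and
  depth 200 mirror the replicate structure of the targeted
  experiments. In the pipeline, retained introns receive
  negative $\Delta\Psi$ with 80% probability, emulating the
  splicing-repair phenotype in which treatment removes damaging
  retained introns.
* **Expression.** Negative-binomial counts (dispersion 0.1) with
  log-normal baselines, library factors in $[0.7, 1.4]$, and 15% of
  genes shifted by $|\mathrm{lfc}| = 2$ in the treated group.
* **Methylation.** A logistic-normal model: per-probe baselines around
  state-specific levels, Gaussian sample noise on the M scale, so beta
  values always stay in $(0,1)$. True DMPs (5%) are shifted by
  $\Delta M = 2$, hypomethylated by default, with 80% placed in one
  designated enhancer state — reproducing the
  hypomethylation-of-enhancers enrichment structure.
* **Clocks.** Expression is constructed by inverting the clock: all
  standardized clock genes of a sample share the single value that
  solves the linear model for the target age, so noiseless data
  recover true ages exactly; Gaussian noise is then added on the log2
  scale. Training means sit high enough (15-17 log2 units) that
  standardized excursions over the simulated age range never clip at
  zero expression. The default study is two age strata (4 and 20
  months) × control/treated × 4 replicates with a 5-unit rejuvenation
  shift.

What passing tests on these simulations do **not** show: robustness to
alignment artefacts, isoform-assignment ambiguity, overdispersion
beyond the NB model, array normalization effects, or batch structure —
none of which the generator emulates.

# Numerical choices and degenerate inputs

* Zero-variance Welch input with differing means returns $p = 0$ with
  a `degenerate` flag and a warning instead of raising, so synthetic
  edge cases cannot abort a pipeline; equal constants give $t = 0,
  p = 1$.
* All-zero ranking metrics fall back to equal hit weights in the
  running sum.
* Master seed → per-stream child seeds (annotation, splicing,
  expression, methylation, clock, GSEA), all below $2^{31}$, so each
  stage is independently reproducible and changing one stage's
  parameters does not reshuffle the others.
* Coordinates are 1-based inclusive `IRanges` throughout, the native
  Bioconductor convention; GTF/BED conversions happen at the reader
  boundary. This trades the 0-based half-open arithmetic style for
  reuse of a mature interval library.
* One documented falsehood avoided: BH adjustment is *not* idempotent
  (reapplying it to adjusted values inflates them), so the test suite
  asserts monotonicity and oracle equality instead.

# Problem sizes

The default pipeline configuration — 40 genes/events, 600 genes × 8
samples for expression, 800 probes × 10 samples for methylation, a
50-gene clock over 16 samples, 5000 GSEA permutations — was chosen so
that a complete run finishes in well under a minute while every stage
still has conventional statistical power; the test suite uses the same
or smaller sizes, and the null-calibration checks pool 20 simulation
repeats per screen.

# Known limitations

Single-isoform consequence calling (no multi-isoform weighting or
NMD-efficiency modelling); two-group designs only; no paired-sample
splicing mode (replicate-set testing is implemented; pairing noted as
an alternative reading of the comparison design); clock training is
out of scope (clocks are applied, not fitted); no array normalization
for methylation data; the metabolite-style feature screen treats all
condition combinations as one factor.
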