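---
title: "Direction-aware inverse-normal meta-analysis of RNA-seq differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direction-aware inverse-normal meta-analysis of RNA-seq differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finmeta)
```

## The problem

Several RNA-seq studies compare the same two conditions — tumour against
normal tissue, patients against controls — each producing a per-gene
p-value and a log2 fold change. A p-value combination meta-analysis pools
this evidence without needing the raw reads of every study. The classical
weighted inverse-normal (Stouffer) combination,

$$N_g = \sum_{s=1}^{S} w_s\, \Phi^{-1}(1 - p_{gs}),
\qquad
w_s = \sqrt{\frac{\sum_c R_{cs}}{\sum_k \sum_c R_{ck}}},$$

is standard normal under the null when the per-study p-values are uniform,
and a one-sided right-tail test detects genes that are consistently
significant. ($R_{cs}$ is the replicate count in condition $c$ of study
$s$; squared weights sum to one, and larger studies weigh more.) Its blind
spot is the *direction* of expression: a gene that is significantly up in
one study and significantly down in another still combines to a large
$N_g$. The usual remedy is to discard genes with conflicting directions,
before or after the correction for multiple testing — so no conclusion at
all is reached for them.

## Direction-signed and fused statistics

`finmeta` implements two direction-aware alternatives alongside the IN
baseline.

The **MIN** statistic signs each study's contribution by the observed
direction $B_{gs} \in \{+1, -1\}$ (the sign of the study's log2 fold
change):

$$N_g = \sum_{s=1}^{S} w_s\, B_{gs}\, \bigl|\Phi^{-1}(1 - p_{gs})\bigr|.$$

Because a symmetric random sign applied to the absolute value of a standard
normal variable is again standard normal (`test-acceptance.R` verifies this
distributional fact by simulation), $N_g$ remains standard normal under the
null, and a two-sided test applies. Discordant studies now cancel instead
of disqualifying the gene, and the sign of $N_g$ carries an *effective
direction*. The price is conservativeness for concordant genes: the
two-sided p-value doubles what the one-sided IN test would report.

One distributional subtlety is worth knowing. The signed statistic is
standard normal *unconditionally* — averaged over all sign patterns. The
fused method, however, applies the two-sided test only to genes whose
observed pattern is mismatched, and conditional on a mixed pattern the
statistic concentrates (its mean moves toward the heavier-weighted signs
and its variance drops below 1), so the mismatched branch rejects null
genes *less* often than the nominal level. The fused combination is
therefore mildly conservative under the null — never anti-conservative —
which the calibration test documents and its low empirical FDR in the
benchmark reflects.

The **FIN** statistic removes that price by fusing the two: genes whose
present-study directions all agree use the IN statistic with a one-sided
test; genes with conflicting directions use the MIN statistic with a
two-sided test; a single Benjamini–Hochberg pass over the pooled p-values
of both branches controls the overall FDR. A gene present in one study is
vacuously concordant, and its combined p-value reduces to the study's own
p-value (weight 1), so meta-analysis never *loses* information relative to
the individual analysis.

Genes need not be present in every study: the gene universe is the union
of the per-study gene lists, and for each gene the weights are renormalized
over the studies in which it was observed. A gene is declared
differentially expressed when its BH-adjusted combined p-value falls below
`alpha` (default 0.05) and — in application mode (`fc_filter = TRUE`) —
its mean absolute log2 fold change over present studies exceeds
`lfc_threshold` (default 1). For IN, genes with conflicting directions are
removed from the discovery list; the default removes them after the BH
adjustment (`in_conflict = "posthoc"`), and `"prefilter"` restricts the BH
pool to concordant genes instead, since published analyses are ambiguous
between the two orders.

## Per-study differential expression

The combination methods consume per-study results (`gene`, `pvalue`,
`log2FC`), from any upstream tool. The bundled stage `run_study_de()`
follows the standard edgeR workflow and delegates to edgeR itself rather
than re-deriving it: counts-per-million filtering (threshold 0.85 CPM in at
least the smaller group size of samples — the filter is what makes null
p-values approximately uniform, the assumption the quantile transform
rests on), TMM normalization, Cox–Reid common and tagwise negative-binomial
dispersion estimation (tagwise shrinkage with prior df 10), and a per-gene
NB GLM likelihood-ratio test of the condition coefficient. log2FC is
positive when cases exceed controls, and the direction convention
(`sign(log2FC)`, exact zero counted as `+`) is shared with the combination
stage through a single rule.

## What the simulator emulates

`default_sim_params()` and `simulate_counts()` generate multi-study count
data with known truth, emulating parameters estimated from a large
real case–control cohort:

* **Base means** are lognormal across genes (`meanlog = 4`, `sdlog = 1.5`;
  median around 55 counts with a long right tail), and library sizes are
  implied by the summed gene means (about one million reads).
* **Dispersions** are gamma with mean 0.2 (biological coefficient of
  variation near 0.45), typical of heterogeneous human cohorts.
* **True DE genes** are a fixed fraction `pi_de` (default 0.1) with
  equiprobable up/down directions. Their |log2FC| is drawn from a
  lognormal with median 0.4 truncated to `lfc_range = c(0.1, 2.5)`: a
  truth set classified from a deeply powered cohort at BH < 0.05 is
  dominated by sub-unit fold changes, and it is exactly these weak-effect
  genes that can show conflicting observed directions across small
  studies. A `"uniform"` option draws flat on `lfc_range` instead.
* **Inter-study variability** `sigma` acts twice. An expression-level
  effect $\varepsilon_{gs} \sim N(0, \sigma^2)$ multiplies both condition
  means of gene $g$ in study $s$ by $e^{\varepsilon_{gs}}$: studies drift
  apart in expression level while every null gene remains an exact null
  within every study, which is what keeps the combined p-values calibrated.
  On top of that, truly DE genes receive random-effects *effect
  heterogeneity*: the realized case-condition effect in study $s$ is
  scaled by $e^{\eta_{gs}}$ with $\eta_{gs} \sim N(0,
  \mathtt{effect\_sd}^2)$ and `effect_sd = sigma` by default, so a weak
  gene's realized direction can genuinely reverse in an individual study
  — the phenomenon the direction-aware methods exist for. We also
  implemented the alternative of drawing the expression-level effect
  independently per condition for *all* genes (`study_effect_model =
  "condition"`): it makes every null gene genuinely differentially
  expressed within each study and destroys FDR control by construction,
  so it is not the default.

What the generator does **not** emulate: zero inflation, batch effects
beyond the lognormal study effect, correlated genes, length/GC biases,
annotation mismatches between studies, or outlier samples. Passing
benchmarks on these data therefore demonstrate the statistical behaviour
of the combination methods under idealized negative-binomial sampling, not
robustness to everything real cohorts contain.

## The benchmark

`run_simulation_study()` reruns the four preset settings — inter-study
variability 0.15 or 0.5 crossed with 3 or 5 studies having replicate
layouts (10,10), (15,10), (12,16), (14,12), (20,20) — at a desk scale of
5000 genes and 20 trials per setting (chosen so the full four-setting
study completes in a few minutes on one CPU; trials are seeded
deterministically from the base seed, setting and trial index). Per trial
it simulates counts, runs the per-study DE stage, combines with each
method, calls DEGs at BH < 0.05 (no fold-change filter, since truth is
known), and scores:

* **AUC** of the ranking by combined p-value (rank-based Mann–Whitney with
  midrank ties; BH is monotone, so pre- and post-adjustment rankings are
  identical);
* **empirical FDR** of the DEG calls (0 when nothing is called);
* **unique-discovery TP proportion**: among genes a direction-aware method
  calls that the IN baseline (with post-hoc conflict removal) does not,
  the fraction truly DE — reported as missing for a trial with no unique
  calls;
* **direction recovery**: among truly-DE unique discoveries, how often the
  effective direction matches the simulated truth.

Two caveats discovered while building the benchmark are worth stating
because they shape what the harness can and cannot show. First, the IN
baseline ranks genuinely direction-conflicted true DEGs *high* (its
statistic ignores direction) while never being able to call them; FIN
ranks them lower (two-sided branch) but calls them. AUC computed on the
full ranked list therefore favours IN by an amount that grows with effect
heterogeneity, even though IN's usable output is smaller — AUC near-equality
of FIN and IN should only be expected when effect heterogeneity is
negligible. Second, with 10% true DE the method-unique discovery sets at
low heterogeneity are small (tens of genes), so their TP proportion is a
noisy statistic dominated by a handful of borderline calls.

## Numerical choices

* p-values are clamped to $[10^{-300}, 1 - 10^{-16}]$ before the quantile
  transform so every statistic is finite; ranks are unaffected. Combined
  p-values are reported without artificial floors.
* `log2FC = 0` maps to direction `+1` (deterministic, measure zero under
  the model, logged when it occurs in direction-critical paths).
* A mismatched gene with $N_g$ exactly 0 (evidence cancels exactly) gets
  effective direction `+` with a warning; its combined p-value is 1, so it
  is never a discovery.
* BH adjustment is the standard step-up procedure (`stats::p.adjust`);
  FIN pools both branches in one pass.
* The GLM stage inherits edgeR's fitting tolerances; dispersion estimates
  are non-negative by construction.

## Limitations

Two-condition designs only; no covariates, pairing, or multi-group
extensions. The per-study stage is a standard edgeR pipeline, not a
reimplementation — exact numeric parity across edgeR versions is not a
goal, and any DE tool can be substituted by supplying result tables
directly. Effect-size meta-analysis, Fisher-type combinations and Bayesian
hierarchical models are out of scope.
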