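---
title: "Methods: estrogen-stratified cross-tissue co-correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estrogen-stratified cross-tissue co-correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the approach

Hypothalamic somatostatin neurons integrate reproductive and metabolic
cues, and their communication with peripheral tissues appears to depend on
estrogen signaling. In a human multi-tissue expression cohort this can be
probed without hormone measurements: if a peripheral gene's expression
co-varies, across individuals, with a hypothalamus-expressed target gene,
the two tissues share a source of regulatory variation — a proxy for
endocrine communication. `endocor` implements that analysis as a pipeline:

1. **Estrogen state.** Each individual's estrogen-signaling activity is
   inferred from an estrogen-responsive gene signature: the signature
   genes are Z-scored within each tissue, averaged per individual and
   tissue, aggregated across the individual's available tissues by a
   weighted mean, and the cohort is split into *high* and *low* strata.
2. **Targets.** Hypothalamic target genes come from neuron-enriched
   mouse RNA-seq: genes whose mean count strictly exceeds the glial
   marker *Gfap* are called highly expressed, then mapped to human
   symbols through an ortholog table.
3. **Co-correlation.** Within each stratum, each peripheral gene from a
   functional program (all secreted proteins, known ligands, peptide
   hormones, feeding-behavior genes) is correlated against each target
   gene across the matched individuals, using the biweight
   midcorrelation.
4. **Screen.** Tissues whose donor matching is too sparse, or whose
   records show no significant correlation after Benjamini–Hochberg
   adjustment, are set aside with a recorded reason.
5. **Comparison.** Correlation coefficients are compared across
   tissue-by-stratum cells with a tie-corrected Kruskal–Wallis omnibus
   test, per-tissue high-vs-low contrasts (Welch t by default,
   BH-adjusted within each category), and a *profile similarity*: the
   biweight midcorrelation between the two strata's aligned coefficient
   vectors. Negative profile similarity means the strata communicate
   through different tissue channels.

# The robust correlation

For a vector $x$ with median $m_x$ and raw median absolute deviation
$\mathrm{MAD}_x = \mathrm{med}|x_i - m_x|$, set

$$u_i = \frac{x_i - m_x}{9\,\mathrm{MAD}_x},\qquad
a_i = (1-u_i^2)^2\,\mathbf{1}[|u_i|<1],\qquad
\tilde{x}_i = (x_i - m_x)\,a_i,$$

and analogously for $y$. The biweight midcorrelation is

$$\mathrm{bicor}(x,y) =
\frac{\sum_i \tilde{x}_i \tilde{y}_i}
     {\sqrt{\sum_i \tilde{x}_i^2}\sqrt{\sum_i \tilde{y}_i^2}}.$$

Observations more than nine MADs from the median get zero weight, so a
single extreme individual cannot dominate a coefficient the way it can a
product-moment correlation. Numerical conventions:

* the MAD carries **no** 1.4826 normal-consistency constant. The constant
  is a pure rescaling of $u$; either convention defines a valid
  statistic, but all components (and any external check) must share one.
* if either vector has zero MAD (more than half its values tied at the
  median) or all its weights vanish, the pair falls back to the
  product-moment correlation and the record says `pearson_fallback`; if
  the fallback is also degenerate (zero variance) the correlation is
  undefined and the call errors rather than emitting NaN.
* p-values use the Student-t transform
  $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom, with
  $p = 0$ at $r = \pm 1$.

# The synthetic cohort

Real multi-tissue donor cohorts cannot ship with a package, so every
stage is validated against a generator with known ground truth. It
emulates three features of donor-based resources:

* **Sparse tissue matching.** Each (individual, tissue) pair is observed
  with a per-tissue probability; hypothalamus is always present because
  the targets live there. Missingness is per individual-tissue, never
  per gene. Defaults: adipose subcutaneous 0.7, adipose visceral 0.6,
  skeletal muscle 0.7, stomach 0.5, small intestine 0.15 — the small
  intestine deliberately exercises the sparse-matching screen.
* **A latent estrogen state.** Each individual is high with probability
  `high_fraction` (default 0.5). Signature genes are unit-variance noise
  plus a mean shift of `estrogen_effect` standard deviations (default
  1.0) in high individuals, in every tissue.
* **Stratum-dependent coupling.** Each peripheral category gene is tied
  to exactly one hypothalamic target through a shared standard-normal
  latent $T$: the peripheral value is
  $\rho_s T + \sqrt{1-\rho_s^2}\,\varepsilon$ with the mixing
  coefficient $\rho_s$ chosen by the individual's stratum, so the
  population correlation within stratum $s$ is exactly the configured
  $\rho(t, s, c)$. The default pattern couples adipose depots more
  strongly in the high stratum (0.5 vs 0.2) and skeletal muscle and
  stomach more strongly in the low stratum (0.2 vs 0.5), with no signal
  in small intestine.

Expression values are continuous log-scale units (background mean 0,
SD 1); the analysis is correlation-based and unit-free, so count
modelling is confined to the neuron table. The neuron count table is
negative-binomial with log-normal gene means, and the *Gfap* reference
mean is placed at a configurable quantile of the gene-mean distribution
so the counts-above-reference filter retains a known expected fraction.

What the generator does **not** emulate: read-level sampling, library
normalization, batch effects, sex chromosomes, correlated gene modules
beyond the one-pair coupling, and non-Gaussian expression marginals.
Passing tests therefore demonstrate that the machinery recovers known
structure under idealized noise — not that any particular biological
claim holds in real data.

## Default problem sizes

The default configuration is 300 individuals, 10 signature genes, four
16-gene category programs, an 8-gene target panel and 50 background
genes per tissue. The compact target panel is deliberate: with the
one-to-one pair construction, the fraction of all (category gene,
target) pairs that carry signal is $1/n_\mathrm{target}$, and an
8-gene panel keeps that density above the screen's default 5%
significant-fraction floor while the whole demonstration runs in
seconds. Validation simulations in the tests use 100–500 individuals
and 10–200 replicates per property, sized so the full suite completes
in well under a minute per file.

# Design choices in the open points

* **Aggregation weights.** The pan-tissue aggregate is
  $\sum_t w_t s_{it} / \sum_t w_t$ over the individual's available
  tissues. Equal weights are the default — the unbiased choice when no
  tissue is known to report estrogen signaling more faithfully — and the
  weight vector is a configuration knob.
* **Binning.** Median split by default; an individual is *high* only if
  its aggregate score strictly exceeds the cohort median, so exact ties
  go to *low*, deterministically. A quantile threshold is available for
  sensitivity analyses.
* **Pair universe.** Real category programs do not come with a known
  pairing to targets, so the default correlates every category gene with
  every target (`all_pairs`), capped at `max_pairs` (50,000) by
  deterministic truncation in sorted order. The `matched` policy
  restricts to an explicit pair table and is what the validation suite
  uses to measure parameter recovery on the generating pairs.
* **Matching thresholds.** A record requires at least 3 matched
  individuals (below that a correlation is meaningless); the tissue
  screen separately requires a minimum per-stratum matched count,
  default 30, before a tissue's correlations are interpreted at all.
  Splitting the two keeps the record-level invariant independent of the
  cohort-level screen.
* **Post hoc contrasts** default to Welch t on the signed coefficients,
  with a rank-sum option; a Fisher-z transform of $r$ and an
  absolute-value mode are flags, off by default. Contrast p-values are
  BH-adjusted across tissues within each category.
* **Profile similarity** aligns records by the full
  (tissue, category, peripheral gene, target gene) key and drops
  unmatched keys with a count. Whether to restrict to a significant
  subset of records first is left to the caller; the pipeline computes
  it on all post-screen records, per category and overall.
* **Run layout.** All stage outputs are plain TSV/JSON/YAML under a
  user-chosen run directory with fixed names, so any stage can be re-run
  standalone from the previous stage's files and reruns are
  byte-comparable. The generator omits donor sex entirely; a sex label
  would be an optional annotation, not a modelled variable.
* **Ortholog ambiguity.** One-to-many mouse-to-human entries are dropped
  under the default `unique` policy (taking all targets is available as
  `all`); symbol matching is case-sensitive after whitespace trimming,
  with the ortholog table as the only cross-species bridge.
* **Counts filter units.** The counts-above-reference filter compares
  per-gene means across samples, in whatever units the table carries
  (raw or normalized); the strict inequality excludes the reference gene
  itself and the result is invariant to any common positive rescaling.

# Known limitations

* The stratification is a proxy: an expression-signature split cannot be
  confirmed against circulating hormone levels, and misclassified
  individuals attenuate stratum contrasts toward zero.
* Correlation records within a cell share genes and individuals, so they
  are not independent observations; the Kruskal–Wallis omnibus and the
  contrasts treat them as exchangeable values, which is the standard
  practice this pipeline mirrors, and its calibration under the
  generator's null is verified by simulation rather than assumed.
* With `all_pairs`, true pair-level signal is diluted by construction;
  interpret the screen's significant fraction relative to the expected
  signal density, not as a power statement.
* No partial correlations, permutation p-values or network-module
  detection in this version.
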