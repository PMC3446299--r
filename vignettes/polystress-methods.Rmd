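---
title: "Methods: multi-level analysis of stress-response gene regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-level analysis of stress-response gene regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polystress)
library(dplyr)
```

polystress quantifies how cells reshape gene expression under environmental
stress at three levels — translation (how mRNAs redistribute across
polysome fractions), mRNA abundance, and protein abundance — and then asks
where the levels agree or disagree. This vignette explains the models and
statistics the package implements, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical choices made where the underlying procedures left room for
interpretation.

## Translation profiles and the two shift statistics

A sucrose-gradient polysome preparation is pooled into four fractions
ordered by ribosome load: fraction 1 holds mRNAs with few or no ribosomes,
fraction 4 mRNAs dense with ribosomes. For a gene with signal in all four
pools, its *translation profile* is the vector of percentages of its total
signal per pool,

$$p = (p_1, p_2, p_3, p_4), \qquad \sum_k p_k = 100 .$$

Genes missing any pool are excluded, never imputed: a profile is only
meaningful as a complete distribution. Two complementary statistics compare
a stress profile with its matched control:

* **Sum of differences** $D = \sum_k |p_k^{stress} - p_k^{control}|$, an
  L1 distance in percentage points, ranging from 0 (identical) to 200
  (disjoint mass). It is sensitive to any reshaping of the profile but
  blind to direction.
* **Translation ratio** $R = S^{stress} / S^{control}$ with the weighted
  score $S = \sum_k w_k p_k$, $w = (0.1, 0.2, 0.3, 0.4)$. The increasing
  weights make mass in heavier (more ribosomes) fractions score higher, so
  $S$ spans 10–40 and $R > 1$ means translational up-regulation, $R < 1$
  down-regulation. $S$ is linear in $p$: moving $\varepsilon$ points from
  fraction $j$ to $k$ changes $S$ by exactly $\varepsilon (w_k - w_j)$.

Both statistics are computed per replicate pair — each stress round against
its own round's control — and averaged across pairs
(`compare_profiles()`, `average_replicates()`). A gene is a *candidate* at
a stress time if $\bar D \ge 30$ or $\bar R \ge 1.15$ or
$\bar R \le 1/1.15$; the union of the two criteria casts a wide net on
purpose, since each catches shifts the other can miss.

### The codified curation rule

Candidate lists were historically pruned by visual inspection. Human
curation is not reproducible, but its stated criteria are mechanical, so
`call_translation()` encodes them: a *down* call requires that, on the
replicate-mean profiles, the sub-polysomal half rises
($\Delta(p_1{+}p_2) > \delta$) while the polysomal half falls
($\Delta(p_3{+}p_4) < -\delta$); *up* is the inverse; $\delta$
(`min_fraction_delta`, default 0) optionally demands a minimum shift.
A `replicate_consistent` flag records whether every replicate pair
individually shows the same sign pattern; `mode = "strict"` makes it a
requirement, `"lenient"` (default) only reports it. Strict calls are by
construction a subset of lenient calls. We do not claim the rule equals
human curation — only that it is the deterministic content of the stated
criteria.

Interpretation choices, made once and configurable: the ratio cutoff is
applied reciprocally on the down side ($R \le 1/1.15$), the neutral reading
of a single symmetric threshold (a fixed cutoff such as 0.85 can be set via
`down_cutoff`); cutoff comparisons are inclusive, avoiding knife-edge
drop-outs; when replicate metadata does not pair stress rounds to controls,
all stress × control pairs are averaged.

## Proteome time course

Spectrum counts (MS/MS spectra matched per protein) are a semi-quantitative
abundance proxy over a 12-sample design: six time points
{0, 15, 30, 60, 120, 180} min × two replicate time courses. The grid is
configurable; this default spans the 0–3 h window over which stress
proteomes typically remodel, with denser sampling early.

1. **Detection filter** (`filter_detected()`): keep proteins with ≥ 2
   unique peptides in at least one sample and, for quantitation, a nonzero
   count in every sample. Retained/total counts are logged at each step.
2. **Calibration** (`calibrate_samples()`): a per-protein control is the
   mean count over all samples; each sample is regressed against the
   control through the origin and rescaled by the slope
   $a_s = \sum_i x_{is} c_i / \sum_i x_{is}^2$. "Calibration" is a gain
   correction, so no intercept by default (one can be enabled). Note a
   structural property: genuine, direction-unbalanced regulation inflates
   some samples' totals and is partially absorbed into $a_s$. The method
   assumes regulation touches a weak minority of the proteome — the regime
   typical stress proteome data and our generator defaults occupy.
3. **Log2 trajectories** (`log2_trajectories()`):
   $\log_2((x + c)/(x_0 + c))$ against the same replicate's 0-min sample
   (replicate-matched baselines preserve within-course structure), then
   duplicates averaged per time point. The pseudocount $c$ (default 0.5)
   is inert for detected-in-all proteins, whose counts are positive, and
   only matters under lenient filtering.
4. **Quadratic-linear fit** (`fit_temporal()`, `fit_proteome()`):
   least squares of $y(t) = \beta_0 + \beta_1 z + \beta_2 z^2$, where $z$
   is time centered and scaled to unit variance for conditioning (an
   ordinal encoding of time would discard the grid's spacing; minutes are
   retained). Temporal change is the overall F test of
   $(\beta_1, \beta_2) = 0$ versus the intercept-only model; significant
   proteins ($p < \alpha$, default 0.05) are classified by a t test on
   $\beta_2$ at the same $\alpha$: *quadratic convex* ($\beta_2 > 0$) or
   *concave* ($\beta_2 < 0$) when curvature is significant, else *linear
   up/down* by the sign of $\beta_1$. The quadratic-linear framework does
   not by itself fix the sub-tests; overall F plus a curvature t test is
   this package's choice, flagged as an interpretation.

Degenerate inputs are handled explicitly: constant trajectories get
$F = 0$ and category `unchanged`; noiseless trajectories (zero residual
variance, as arise from exact synthetic input) are reported significant
with $p = 0$ and a warning, so they remain classifiable.

```{r temporal-example}
times <- c(0, 15, 30, 60, 120, 180)
fit_temporal(c(0, 0.2, 0.35, 0.62, 1.1, 1.4), times)
```

## Integration across levels

* **mRNA direction calls** (`call_mrna_direction()`): a gene is induced if
  its expression exceeds 1.5-fold (a strict inequality — exactly 1.5-fold
  does not pass) at ≥ 4 of the pooled stress time points across the
  supplied experiments; repressed symmetrically. With the default two-experiment
  design the pool has 7 stress time points. Missing values never pass.
* **Discordance classes** (`classify_discordance()`): a fixed, ordered rule
  table maps each gene's (mRNA, translation, protein) direction triple to
  one class — the two translation-vs-mRNA antagonistic patterns first, then
  the four protein-vs-mRNA patterns, then `concordant` (some level changed
  and all changed levels agree), else `unclassified` (including genes flat
  everywhere). Protein categories collapse to a direction by the sign of
  the largest-magnitude fitted value, so a convex profile with a net rise
  counts as up. The classes partition the gene universe.
* **Correlations** (`correlate_changes()`): Pearson (two-tailed t
  approximation) or Spearman, via `stats::cor.test()`.
* **Combined change** (`combine_mrna_translation()`): the product of
  linear-scale mRNA fold change and translation ratio, a first-order
  estimate of the change in protein-synthesis input.
* **Signed maximum change** (`max_change()`): the trajectory value of
  largest magnitude with its sign retained — "maximum change" would
  otherwise be ill-defined for repressed genes.
* **Enrichment** (`hypergeom_enrichment()`): upper-tail hypergeometric
  probability $P(X \ge k)$ including the observed point mass, on
  user-supplied gene sets intersected with the universe. Raw p-values by
  default (matching how such screens are usually reported);
  Benjamini–Hochberg across sets via `adjust = TRUE`.
* **Clustering** (`cluster_genes()`): average-linkage hierarchical
  clustering with distance $1 -$ Spearman correlation between gene rows,
  hence invariance to monotone transforms of each row. Rows are put in
  canonical (id) order first so the tree does not depend on input row
  order under distance ties; constant rows, whose rank correlation is
  undefined, are dropped with a warning. Trees export to newick.

## The synthetic-data generator

Every stage above is testable against ground truth because
`simulate_stress_study()` generates all three layers with planted effects:

* **Fraction pools**: latent control profiles are Dirichlet-distributed
  percentages; planted translationally regulated genes move
  `effect_size_shift` points (default 30, i.e. exactly at the D cutoff
  before noise doubles it: a shift of $s$ points yields $D = 2s$) between
  the pooled low and high halves; observed abundances add multiplicative
  log-normal noise (`noise_sd_log`, default 0.1 — a typical two-channel
  array ratio spread).
* **mRNA tables**: two experiments (stress times {15, 60} and the proteome
  stress grid) with planted genes following a fast-rise/peak/partial-decay
  trajectory — peak `mrna_log2_effect` (default 1, i.e. 2-fold) at 60 min,
  decaying to 60% of peak, the transient shape typical of stress
  transcriptomes. `mrna_effect_cv` spreads per-gene effect sizes when
  heterogeneity is wanted.
* **Spectrum counts**: Poisson counts around per-protein means — baseline
  `count_depth` (default 200) with log-normal spread (`baseline_sdlog`
  0.5), per-sample true scale factors (log-normal, sd 0.15) that the
  calibration step must recover, and planted temporal categories: linear
  (±1 log2 over the course) and quadratic (0.75 log2 amplitude) at 2.5%
  of proteins each, i.e. 10% of the proteome regulated. These effect sizes
  were fixed by a design-time power calculation at the default depth and
  grid; larger or heavily unbalanced planted effects are partially
  absorbed by the average-control calibration (see above) and would test
  the generator's imbalance rather than the classifier.
* **Coupled protein mode** (`protein_model = "mrna_coupled"`): protein
  trajectories follow a first-order synthesis–degradation response to the
  gene's mRNA fold change, $\dot P = k_d (m(t)/m_0 - P/P_0)$, with
  $k_d = \ln 2 / 180\,\mathrm{min}$ for induced genes and $k_d = 0$
  (effectively stable protein) for repressed genes. This reproduces the
  asymmetry real proteomes show: protein gains track mRNA induction with a
  lag, while protein loss is rate-limited by slow turnover and decouples
  from mRNA repression.

With `concordant_layers = TRUE` (default) the planted up blocks coincide
across layers, emulating globally coordinated regulation; independent
assignment is available for null-association scenarios. Identical seeds
give bit-identical outputs; with zero noise and no planted effects every
statistic takes its identity value ($D = 0$, $R = 1$, $\beta = 0$).

What the generator does **not** emulate: spot-level microarray artefacts,
dye effects, MS peptide-level variation and shared-peptide inference,
overdispersion beyond Poisson, correlated noise across genes, and the long
abundance tail of deep proteomes. Passing recovery tests therefore shows
the pipeline's statistics behave as designed under their own model
assumptions — not that those assumptions capture every property of real
data.

## Problem sizes used in the test suite

The packaged tests run the generator at 2,000 genes (three replicate
rounds) for translation-recovery checks, 2,000 proteins at depth 200 for
calibration and category recovery, 10,000 simulated null trajectories for
the F test's type-I error, and exhaustive enumeration up to a 20-gene
universe for the hypergeometric oracle — sizes chosen to give stable Monte
Carlo estimates while keeping a default test run in the minutes range.

## Known limitations

* The curation rule is a codification, not a reproduction, of human
  visual inspection; manually curated gene lists are not expected to be
  reproduced gene-for-gene.
* The average-control calibration absorbs direction-unbalanced regulation
  into its scale estimates; with a heavily regulated proteome, calibrated
  trajectories of unregulated proteins acquire a compensatory trend.
* The quadratic-linear classifier's linear-vs-quadratic split at 3
  residual degrees of freedom has limited power for subtle curvature;
  convex and concave calls need amplitudes comparable to the planted
  defaults to be reliable at realistic counting depth.
* Enrichment takes user-supplied gene sets; no ontology structure or
  annotation retrieval is provided.
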