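---
title: "Network-guided differential expression analysis of treatment response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-guided differential expression analysis of treatment response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degnet)
```

## Scope and model

`degnet` analyses a two-arm, two-timepoint clinical transcriptomic
cohort — patients starting one of two biologic classes (TNFi or
IL-17Ai), profiled at baseline and month 3, and labelled responder or
non-responder at month 3 — and asks which pathways distinguish the
response groups. Group sizes in such cohorts are small (here 7–13 per
group), so the workflow leans on two stabilising devices: empirical-Bayes
variance moderation at the gene level, and protein-interaction /
pathway structure at the set level.

The expression model is deliberately simple. All analysis happens on
the log2(TPM+1) scale; for a comparison of groups 1 and 2 the effect of
interest is the per-gene difference of group means Δ (log2 fold
change), reported alongside the signed linear fold change
FC = 2^Δ for Δ ≥ 0 and −2^(−Δ) otherwise, so |FC| ≥ 1 always and
FC = −1.5 reads "1.5-fold lower in group 1". All fold-change gates in
the pipeline are applied to |FC| on this linear scale.

### Moderated t

Per comparison, each gene's pooled residual variance s² (df residual
degrees of freedom) is shrunk toward a prior:

$$s^2_{post} = \frac{d_0 s_0^2 + df\, s^2}{d_0 + df},\qquad
  t = \frac{\Delta}{\sqrt{s^2_{post}(1/n_1 + 1/n_2)}},$$

with a two-sided p from a t-distribution on $d_0 + df$ degrees of
freedom (paired comparisons use within-pair differences and
$s^2_{post}/n$). The prior $(d_0, s_0^2)$ is fitted by moment matching
on $\log s^2$: after subtracting the known mean and variance
contributions of the $\chi^2_{df}$ sampling layer
($\psi(df/2) - \log(df/2)$ and $\psi'(df/2)$), the residual dispersion
identifies $d_0$ through the inverse trigamma function and the
corrected mean identifies $s_0^2$. Two degenerate regimes are handled
explicitly: when the observed dispersion of $\log s^2$ is at or below
the sampling minimum the prior is a point mass ($d_0 = \infty$,
$s_0^2 = \overline{s^2}$), and $d_0 = 0$ disables moderation, reducing
the statistic exactly to the classical pooled t. The test suite
verifies both reductions, recovery of known $(d_0, s_0^2)$ from a
simulated hierarchy, and agreement of the estimator with the standard
empirical-Bayes implementation in `limma` used as an independent
reference.

### Gates, expansion and enrichment

Three gates drive the set-level analysis, all exposed in `run_config()`
and none hard-coded:

* seed DEGs: |FC| ≥ 1.4 and raw p ≤ 0.05 (`fc_seed`, `p_seed`);
* network expansion: |FC| ≥ 1.2 regardless of p (`fc_expand`);
* pathway membership: |FC| ≥ 1.4 regardless of p, or
  1.2 ≤ |FC| < 1.4 with p ≤ 0.05 (`fc_member_hi`, `fc_member_lo`,
  `p_member`).

Raw p-values are used at the gene level by design — with these group
sizes a genome-wide multiplicity correction would empty the lists, and
the workflow's error control instead happens at the pathway level
(BH-FDR across tested pathways). The membership band is half-open,
[1.2, 1.4), so a gene can never be counted by both clauses; a |FC|
exactly 1.4 satisfies the first.

Expansion is one hop by default (`seed_anchored`): a network edge
qualifies when both endpoints pass `fc_expand` and at least one is a
seed; the expanded list is the seeds plus qualifying-edge endpoints.
The `pairwise` mode drops the seed-adjacency requirement and harvests
every qualifying interacting pair; it is exposed because "select
interacting gene pairs passing the gate" admits both readings, and the
two modes bracket the plausible behaviours. Seeds absent from the network are
kept — they passed the stricter gate, and dropping them silently would
lose the primary DEGs.

Overlap significance is computed two ways: the exact hypergeometric
upper tail (accumulated from log densities, so p-values far below
double underflow of naive summation remain accurate) and an add-one
randomization test, p = (1 + #{replicate overlap ≥ observed})/(B + 1),
drawing both lists uniformly without replacement per replicate. The
hypergeometric is the analytic limit of the randomization test; the
suite checks their convergence at B = 10⁵.

### Key terms and profiling

Titles of enriched pathways (q ≤ α) are tokenized — lowercase, split
on non-alphanumerics, stopwords / single characters / pure numbers
dropped, no stemming — and each token is weighted by the best
enrichment p among titles containing it, on the −log10 scale. Stemming
is deliberately omitted: the statistic is qualitative, and keeping
"gtpase"/"gtpases" distinct is more transparent than any stemmer's
behaviour. Keyword retrieval of a pathway family normalizes case,
hyphens, underscores and whitespace, because real pathway collections
mix "Rho GTPase", "RHO-GTPase" and "Rho-GTPases" freely.

The family profile annotates every union gene of the family with the
membership rule per comparison; genes missing from a comparison's
expression matrix are flagged unmeasured rather than dropped. Seven
preset comparisons are built from the metadata: responder vs
non-responder within each arm at baseline, responder–responder and
non-responder–non-responder across arms at baseline, and baseline vs
month 3 for TNFi responders, IL-17Ai responders and TNFi
non-responders. Which pre/post groups merit their own comparison is a
design choice (the fourth, IL-17Ai non-responders, typically carries
the least treatment effect); the preset list is overridable, since
`ComparisonSpec` accepts arbitrary metadata filters.
Pre/post comparisons default to unpaired (a plain two-group contrast),
with pairing by patient available via `paired_prepost`.

### Clustering and PCA

The separation view takes the top-k (default 100) best-p seed DEGs,
median-centers rows (the heatmap display convention; disable with
`median_center = FALSE`), computes d = 1 − Pearson between samples,
clusters with UPGMA and cuts at k = 2. "Clear separation" is
operationalized as the adjusted Rand index against the true response
labels — ARI = 1 iff the two clusters reproduce the responder split —
which turns a qualitative claim into a testable score; this
quantification is an artifact decision of this package. PCA uses
per-gene centering without unit-variance scaling (the common default
for expression data; scaling would up-weight low-variance genes), with
a deterministic sign convention so runs are byte-reproducible.

## The synthetic-study generator

`synth_config()` describes the emulated study; defaults are the target
design: 20 patients per arm, two samples each (baseline, month 3),
responder fractions 0.65 (TNFi) and 0.35 (IL-17Ai), 1000 genes, 50
pathways with a 16-pathway keyword family, per-gene baseline means
uniform on [2, 8] log2 units, i.i.d. Gaussian noise with sd 0.5, and a
pathway-modular PPI network (edge probability 0.3 within a shared
pathway, 0.01 background). Planted effects are additive mean shifts
tied to a named comparison's group-1 samples, so each of the seven
presets has exact per-gene truth.

What the generator does *not* emulate: count-level sampling noise
(noise is Gaussian on the log scale — adequate for testing these
stages, but real log-TPM noise is mean-dependent), gene–gene
correlation beyond the planted shifts, library-size or GC biases, and
hub structure in the PPI network beyond pathway modularity. Passing
tests therefore demonstrate correctness of the statistical machinery
and recoverability of planted signal under idealized noise, not
performance on real cohorts.

## Numerical and calibration choices

* Hypergeometric tails are log-sum-exp accumulations of `dhyper`
  log-densities; p-values below ~1e-300 survive, and k = 0 returns
  exactly 1.
* `estimate_moderation` requires ≥ 10 positive variances; the inverse
  trigamma uses Newton iteration with asymptotic guards at both ends.
* Degenerate genes (identical values in both groups) get t = 0, p = 1
  rather than NaN.
* Batch adjustment rescales only when both the batch and pooled
  standard deviations are positive; zero-variance cases shift only, so
  no division by zero is possible. Full empirical-Bayes batch
  correction (ComBat-style shrinkage of the batch parameters) is
  intentionally out of scope; the location-scale standardization keeps
  the operation exactly invertible in expectation and trivially
  testable. Whether differential expression runs on adjusted or raw
  values is a config switch (`use_batch_adjusted`, default on).
* Duplicate gene rows on input collapse to the row with the larger
  total signal — deterministic and conventional.
* All rankings break ties deterministically (p, then |FC|, then
  symbol); UPGMA ties resolve to the smallest index pair; PCA signs fix
  the dominant loading positive. Rerunning any stage with the same
  seed is byte-identical, which the suite asserts end-to-end.
* The null calibration of the randomization test is checked on a dense
  instance (universe 2000, two 1000-gene lists): the overlap statistic
  is discrete, and on sparse instances the attainable p-values sit far
  below the nominal level, making any permutation test conservative
  there. Exact analysis of the add-one estimator at B = 999 gives a
  rejection probability of 0.0456 at the 0.05 level on the dense
  instance, which is what the suite's binomial band checks against.

## Problem sizes

The test suite and `scripts/acceptance.R` run the end-to-end benchmarks
at 1000 genes × 80 samples × 50 pathways with 20 seeded replicates,
moderation recovery at 20000 genes, the null-uniformity checks at
20000 genes, and the calibration check at 1000 replicates of B = 999 —
sizes chosen so the full suite completes in a couple of minutes on one
CPU while keeping Monte-Carlo error well inside the asserted bands.

## Known limitations

* The moderated model is a two-group (optionally paired) contrast;
  there is no design-matrix interface, covariate adjustment, or
  eBayes trend/robust variants.
* Enrichment treats pathway membership as literal GMT content; no
  propagation, topology weighting, or "extended association" handling.
* Expansion is at most one hop from the seeds; no diffusion scores.
* Gene identifiers are bare symbols with no mapping layer; inputs must
  share a namespace.
* The randomization and hypergeometric tests condition on list sizes;
  they do not model selection of the lists themselves.
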