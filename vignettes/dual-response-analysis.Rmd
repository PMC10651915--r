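---
title: "Two-level differential-response analysis of dual confrontation experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-level differential-response analysis of dual confrontation experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualresponse)
```

## The model

A dual confrontation experiment profiles a mycoparasite and a
signalling-mutant derivative under self-confrontation (control) and
host-confrontation (induced), each sample hybridized against a
universal reference. The data enter the pipeline as a genes × arrays
matrix of log2(sample/reference) ratios with a design mapping arrays
to the four (strain, confrontation) groups.

Per gene, a one-way cell-means model over the four groups is fitted.
Three contrasts matter:

* the WT response `(-1, +1, 0, 0)` and the mutant response
  `(0, 0, -1, +1)` — each strain's host- vs self-confrontation
  log2 fold-change;
* the second-level contrast `(+1, -1, -1, +1)`, the difference of the
  two responses (mutant minus WT). Because everything downstream is
  linear, fitting this contrast directly and subtracting the two
  aggregated first-level responses give identical values; the package
  computes both and the test suite asserts their equality to 1e-9.

The sign convention is fixed throughout: negative second-level values
mean the mutant's response is lower than the wild type's, i.e. the
kinase normally *stimulates* that response.

### Variance moderation

With four arrays per group the per-gene variance is noisy, so t
statistics are moderated: residual variances are modelled as
`s² | σ² ~ σ²·χ²(df)/df` with a scaled-inverse-chi-square prior
`(d0, s0²)`. The posterior variance is the precision-weighted mix
`s̃² = (d0·s0² + df·s²)/(d0 + df)` and the moderated t uses
`d0 + df` degrees of freedom. The hyperparameters are estimated by
moment matching on `log s²`: under the hierarchy `log s²` is a shifted
log-F variate, whose variance in excess of `trigamma(df/2)` identifies
`d0` through the trigamma inverse (solved by Newton iteration), and
whose mean identifies `s0²` after digamma bias correction. Tests
verify the estimating equations directly, compare against the same
moment estimator in limma, and against an independent grid search
maximizing the scaled-F marginal likelihood.

Degenerate inputs are handled explicitly: identical variances give
`d0 = Inf` with `s0²` equal to the common value, so moderation is a
no-op and the moderated t equals the ordinary t; all-zero variances
(noise-free data) fall back to `d0 = Inf` with a configurable variance
floor, recorded on the result object. Genes with `s² = 0` under a
finite prior follow the mixing formula unmodified.

### Multiple testing

Significance is controlled with the Benjamini–Yekutieli step-up
procedure (valid under arbitrary dependence), the conservative choice
for correlated array data; Benjamini–Hochberg is available where the
lighter correction is conventional (term enrichment). Both wrap
`stats::p.adjust`; tests compare them against a direct step-up
evaluation.

### Meta-analysis across normalizations

Each normalization branch produces its own statistics. The aggregate
effect `aLog2FC` is the arithmetic mean of per-branch log2
fold-changes; the aggregate rank `aRank` is the geometric mean of
per-branch significance ranks (rank 1 = smallest p, average ranks on
ties), so ordering by `aRank` equals ordering by the rank product. Two
interpretation choices are deliberate and documented rather than
prescribed by the source analysis: the ranking key is the branch
p-value (not |log2FC|) — consistent with reported non-integer aggregate
ranks — and no permutation p-value is attached to `aRank`; it is an
ordering statistic, while significance comes from the per-branch
q-values through a consensus gate.

### The regulatory-mode classifier

A gene is *robust* when `|D| ≥ tau_strong` (default 2 log2 units) and
the second-level contrast is consensus-significant (default: q < 0.05
in every branch; the gate is configurable, and a thresholds-only mode
exists for fixture arithmetic). Per-strain responses are bucketed as
strong Up (`r ≥ 2`), strong Down (`r ≤ -2`), or regulated below
threshold, "Rbt" (`|r| ≤ 1`). The (sign of D, WT bucket, mutant
bucket) triple maps to eight named modes; four per family. Two design
points were genuinely open:

* Only seven modes were observed in the motivating data; the eighth
  (`UP.UpWT.UpMut`, both strains up with the mutant stronger) is
  completed by symmetry with `DOWN.DownWT.DownMut`.
* The band `1 < |r| < 2` is never named in the motivating analysis.
  Robust genes with a response in this band — or in a bucket
  combination with no named mode — are reported as `MIXED` rather than
  forced into a named mode, and excluded (like `NOT_ROBUST`) from the
  summary denominator.

Summary percentages (stimulating = `DOWN.*` family, suppressing =
`UP.*`, both-strong as a share of stimulating, lost-upregulation,
newly-down, flag fractions) are rounded half-up to integers, which is
what reproduces published integer percentages such as 89% (125/140)
and 54% (68/125).

## Normalization bank

The registry ships four methods. `median_center` subtracts each
array's median; `quantile` maps every array onto the rank-wise mean
distribution (ties receive the mean of their ranks' values);
`mad_scale` median-centres and divides by the array's median absolute
deviation (MAD-0 arrays are centred only); `identity` passes data
through. All preserve gene and array order.

The default bank for the pipeline is `{median_center, mad_scale}`.
Quantile normalization is deliberately not a default branch: it
assumes all arrays share one intensity distribution, which is exactly
false in this design — host-confrontation arrays carry strong
condition-specific effects in their tails. On noise-free synthetic
data a planted +3 log2 response can be mapped to nearly 0 by the
quantile branch, and since the classifier thresholds are in log2
units, a bank member that rescales or truncates tail effects
systematically biases `aLog2FC` toward the origin. The bank remains
fully configurable (`normalizations =` in `run_config()`), and the
quantile method itself is contract-tested; analysts whose designs
satisfy the equal-distribution assumption can add it back.

For the same reason the thresholds should be interpreted with care
when `mad_scale` is in the bank: its output is in MAD units, not log2
units. With realistic per-gene baseline spread (about one log2 unit,
see below) the column MAD is close to 1 and the distortion is small,
but a bank of only scale-normalized branches would change the
effective meaning of `tau_strong`.

## What the synthetic generator emulates

`synthetic_config()` describes a 4-group × n-replicate (default 4)
reference-design experiment. Per gene, a regulatory mode is drawn from
`mode_proportions`; the default mix keeps 90% of genes unregulated so
FDR experiments have a null majority, and weights the named modes
roughly like the observed mode mix (lost-upregulation modes most
frequent). Planted responses use `effect_size` (default 3 log2 units)
for strong regulation; "Rbt" responses are planted at ±`rbt_effect`
(default 0.5) — strictly inside the |r| ≤ 1 band but away from zero,
to exercise the band edge. The config validator enforces
`effect_size > 2·rbt_effect` so modes are separable at zero noise.

Array noise is i.i.d. Gaussian on log2 ratios (`noise_sd`, default
0.25). Per-gene baselines — the stable log2 ratio of each gene against
the pooled universal reference — are drawn with `baseline_sd = 1`:
a universal reference pools all conditions, so per-gene ratios spread
by about one log2 unit across the genome. This spread matters: it is
what makes rank- and scale-based normalization well behaved, and a
much narrower choice would make column MADs small and scale branches
pathological. An optional per-array constant (`dye_bias_sd`) exercises
normalization. A configurable fraction of genes (default 10%) is
mirrored as proteome "spots" carrying the same planted responses with
independent noise on the log2 scale, so transcript–protein
corroboration (the nitrilase-style sign concordance) is testable.

Not emulated: probe-level intensities, spatial artifacts,
within-plate biological replicate hierarchy (a single noise level
covers the pooled-plates-then-replicate-arrays structure), intensity-
dependent dye bias, and missing values. Passing tests on this
generator therefore demonstrate the statistical machinery, not
robustness to array-quality pathologies.

## DIGE proteome scheme

Spot abundances (positive, standardized to an internal standard) are
compared pairwise between conditions. The reported average ratio
follows the DIGE software convention: `AR = r` if the ratio of means
`r ≥ 1`, else `-1/r`, so no values fall in (−1, 1); `log2fc = log2(r)`
is carried alongside as the analysis-grade quantity, and
`|log2fc| ≥ log2(1.5)` iff `|AR| ≥ 1.5`. P-values are two-sample
pooled-variance Student's t on log2 replicate values (log2 is the
variance-stabilizing scale for ratio data); the flag gate is
`|AR| ≥ 1.5` and `p < 0.05`. Because the exact ANOVA model of the
original software is unspecified, `spot_anova()` reports both the
strain × confrontation model with interaction and the additive model.
The proteome second-level difference subtracts response log2
fold-changes and is verified against the direct four-condition-mean
contrast.

Profiles with `|log2fc| > 1.5` in at least one comparison are
clustered by agglomerative average linkage on Euclidean distances
(both unspecified in the motivating analysis; both configurable),
with `k = 7` groups by default. Cluster labels are relabelled by the
cluster mean of the first profile column, making assignments
deterministic and row-order invariant; proteoform spots stay separate
rows with a max-|log2fc| protein roll-up available.

## Enrichment and networks

Term over-representation uses the hypergeometric upper tail against a
configurable universe (default: the full annotated gene set, the
analogue of testing against all gene models rather than the robust
subset), BH-adjusted over tested terms; terms with zero study count
are not tested. Ontology-style annotations can propagate up a
parent–child DAG (default on for ontology terms, off for flat
functional categories). Intersection networks include terms with
p ≤ 0.05 in either dataset, label membership (both / transcriptome
only / proteome only), size nodes by the summed study counts, and keep
DAG edges between included terms; export as GraphML or TSV.

The secreted-gene contingency test is Pearson's chi-squared without
continuity correction (Yates optional). The background for that test
is not recoverable from the motivating analysis; the pipeline defaults
to stimulating-family vs suppressing-family × secreted flag and logs
the full table so alternatives are auditable.

## Numerical choices and problem sizes

* Trigamma inverse: Newton iteration from the asymptotic start
  `0.5 + 1/y`, 60 iterations max, relative tolerance 1e-10.
* Quantile ties: tied values receive the mean of the reference values
  at their ranks.
* Percentages: round half away from zero (base `round()` rounds half
  to even and would not reproduce printed integers).
* Zero-variance fallback floor: 1e-8 (configurable), flagged on the
  result.
* Consensus gates: `all` (default), `any`, `median`.

The packaged checks use desk-scale problem sizes chosen to make the
statistical properties measurable: 2000-gene experiments for
planted-mode recovery, 200 simulated null datasets (2000 genes, 4
replicates, noise sd 0.25) for the realized false-discovery
proportion of the BY-gated second-level contrast, brute-force oracle
comparisons at pop_size ≤ 12 (hypergeometric) and ≤ 5 profiles
(linkage). Dataset-level counts from the motivating experiment (142
WT-response genes, 140 kinase-governed genes, 85 clustered proteins)
depend on the original arrays and gels and are exercised only through
equivalent-scale fixtures and count arithmetic.

## Known limitations

* The moment-matching estimator claims equivalence with the original
  moderated-t framework only at the property level (shrinkage between
  bounds, limiting behaviour, agreement with an independent
  maximum-likelihood grid); exact hyperparameter equality is asserted
  against the same-moment estimator, not guaranteed for all inputs.
* `aRank` carries no significance of its own; treat it as an ordering.
* The composition of published "strong stimulation or suppression"
  subsets that cannot be derived from printed group counts is not
  reproduced.
* The classifier's `MIXED` band means summaries are not exhaustive
  over robust genes when responses land in (1, 2); this is by design.
* With a significance gate of `all` over many branches the consensus
  becomes increasingly conservative; prefer `median` for large banks.
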