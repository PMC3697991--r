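---
title: "Methods: comparing microarray and RNA-Seq transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing microarray and RNA-Seq transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossplat)
```

This vignette is the package's own account of its statistical machinery: the
models it fits, the assumptions behind them, the tunable parameters and their
defaults, the numerical choices, and the limits of what the simulation-based
checks can show.

## Preprocessing and detectability

Expression tables enter as gene-by-sample tibbles tagged with platform
(`rnaseq`/`microarray`), scale (`counts`/`fpkm`/`log2`) and a
sample-to-group map.

**RNA-Seq detectability** (`filter_rnaseq_counts()`): a gene is detectable
in a group when its maximum count over that group's replicates reaches
`min_count` (default 10 reads); genes detectable in no group are removed.
The quantifier deliberately acts *per group*: a gene strongly induced in
only one condition must survive the filter, because per-group detectable
sets also feed the cross-platform overlap statistics. The dual reading —
requiring detectability in every group jointly — would delete
condition-specific genes and make the per-group detectable sets
inconsistent with the retained universe.

**Microarray detectability** (`filter_microarray_present()`): a gene must be
flagged present in *all* replicates of at least one group. Present/absent
calling itself (e.g. MAS5-style detection calls) is upstream of this
package; an explicit logical presence table is accepted, and the built-in
fallback derives presence as intensity above a per-chip quantile
(`presence_quantile`, default 0 = always present).

**Probe collapsing** (`collapse_probes()`): when several probes interrogate
one gene, the probe with the highest *mean intensity across all samples*
represents the gene. "Highest intensity" is underdetermined — per-sample
argmax would let a gene switch probes between samples and corrupt replicate
structure — so the all-sample mean is used, with ties broken by the
lexicographically smallest probe id to keep the operation deterministic.

**Housekeeping normalization** (`normalize_housekeeping()`): log2 values are
converted to unit-free ratios relative to a housekeeping gene, per sample.
Whether "dividing by a housekeeping gene" acts on the log2 values or
subtracts them (division on the raw scale) is genuinely ambiguous in common
usage and the two differ; both modes are implemented (`divide`, the literal
reading, is the default) and the applied mode is recorded in the output
metadata so downstream reports stay auditable. The default reference is
ENSG00000197935 (*ZNF311*), a moderately and consistently expressed gene; a
highly expressed reference such as *GAPDH* compresses the ratios of
ordinary genes and is a poorer anchor.

## Concordance statistics

Overlap of two gene sets is `|A ∩ B| / |A ∪ B|` (`overlap_rate()`); the
same union-based rate is reused for DEG-list comparison
(`overlap_matrix()`) so that one definition serves both uses. Correlation
(`paired_correlations()`) reports Pearson and Spearman coefficients with
`n_pairs`, because the choice of gene universe (whether filtered-out genes
are included, which unmapped genes are dropped) materially affects the
numbers; carrying the pair count makes any choice auditable.
`density_comparison()` bins two gene classes (commonly detectable versus
platform-exclusive) on shared equal-width bins and reports class medians; a
lower exclusive-class median is the signature of one platform detecting
weakly expressed genes that the other misses.

## Errors-in-variables regression

With `X_ij` the microarray and `Y_ij` the RNA-Seq measurement of gene `i`
in replicate `j` (log2, unit-free), the functional errors-in-variables
model is

$$Y_{ij} = \alpha + \beta \xi_i + \epsilon_{ij}, \qquad
  X_{ij} = \xi_i + \delta_{ij},$$

with independent normal errors and
$\lambda = \sigma_\epsilon^2 / \sigma_\delta^2$. The model acknowledges
error in *both* platforms; its intercept measures fixed bias (a baseline
offset) and its slope proportional bias (per-unit scaling discrepancy).

**Assumptions and the advisory check.** The fit assumes a common error
variance across genes. `trim_and_check()` removes the top 1% of genes by
pooled within-gene replicate variance (both platforms combined;
`ceiling(trim_fraction * n)` genes, ties broken by gene id) and runs a
Brown–Forsythe Levene test (center = median, the robust variant) comparing
the pooled within-gene residuals of the two platforms. The p-value is
reported but not enforced: the check is a prerequisite diagnostic, not a
gate. All-zero residuals make the test vacuous; p is 1 by convention.

**Estimating λ** (`estimate_lambda()`): balanced replicate measurements on
both platforms identify λ as the ratio of pooled within-gene replicate
variances. Genes whose replicates are identical contribute zero to the
pooled sums rather than being excluded, which keeps the estimator a simple
ratio of sums.

**The fit** (`fit_eiv()`): the package fits on per-gene replicate *means*
with λ estimated from the replicate spreads; with balanced replicates the
mean-based Deming fit coincides with the full replicate-level maximum
likelihood for known λ. The slope solves the concentrated score equation
$S_{xy}\beta^2 + (\lambda S_{xx} - S_{yy})\beta - \lambda S_{xy} = 0$
numerically — bracketed root finding (`uniroot`, tolerance 1e-12) between
the two limiting slopes, the ordinary-regression slope $S_{xy}/S_{xx}$
(the λ→∞ limit) and the inverse-regression slope $S_{yy}/S_{xy}$ (the λ→0
limit), between which the maximum-likelihood slope always lies. The test
suite pins this numeric path against the independent closed-form Deming
solution to 1e-6 relative. Zero covariance of the gene means leaves the
slope unidentifiable and is an error.

**Bias verdicts** (`bootstrap_bias()`): genes are resampled with
replacement, keeping each gene's paired rows together, because genes are
the exchangeable units — resampling individual (gene, replicate) cells
would break the within-gene variance structure that identifies λ. λ is
re-estimated and the model refit on every resample; percentile intervals at
the requested level (default 95%, 1000 resamples) yield the verdicts: fixed
bias iff the α interval excludes 0, proportional bias iff the β interval
excludes 1. Percentile intervals (rather than BCa) keep the procedure
simple and match the stated coverage well in the calibration study below.
Degenerate resamples (zero covariance or zero pooled microarray variance)
are redrawn and counted; more than 10% redraws triggers a warning.

**Calibration sizes.** The suite verifies: null recovery (no flags) and
alternative recovery (both flags) in at least 90% of 10 seeded runs at
2,000 genes with 200 resamples each; and 90–99% coverage of the 95% slope
interval across 200 simulations at the biased regime (α = −0.25, β = 1.45,
λ = 1) with 300 genes and 300 resamples per simulation. Those study sizes
are the package's choice: large enough for stable Monte-Carlo proportions,
small enough that the whole suite runs in seconds.

## The paired-platform simulator

The generator is first-class, tested code; its defaults *are* the study
conditions, not tuning knobs.

**Microarray error model and VST.** Observations follow the two-component
model $y = \alpha_{bg} + u e^{\eta} + \epsilon$: multiplicative log-normal
error η dominates at high intensity, additive error ε near background. Its
variance-stabilizing transformation

$$g(y) = \ln\!\left((y - \alpha_{bg}) + \sqrt{(y - \alpha_{bg})^2 + c}\right),
  \qquad c = \mathrm{sd}_\epsilon / \mathrm{sd}(e^{\eta}),$$

is total for c > 0 and strictly increasing. The package uses the
algebraically exact inverse $z = (e^{2g} - c)/(2e^{g})$; the round trip is
verified to 1e-10 over a 10,000-point grid spanning background-subtracted
intensities from −500 to 5×10⁴. Two numerical notes: for strongly negative
$z$ the sum $z + \sqrt{z^2+c}$ cancels catastrophically, so the conjugate
form $c/(\sqrt{z^2+c} - z)$ is used on that branch; and beyond roughly
10⁵ intensity units the round-trip error necessarily grows toward the
double-precision limit, since the transformed value `g` quantizes `z` at
relative precision.

**Estimating the error model** (`estimate_noise_model()`): ranking genes by
mean corrected intensity, the bottom 1% (where u ≈ 0) give sd(ε) and — by
subtracting the corrected from the uncorrected tail mean — the background
α; the top 1% give sd(η) as the spread of log corrected intensity. With
two or more arrays the spreads are pooled *within-gene* across samples;
using the across-gene spread would confound the tail's own signal spread
with measurement error and make the estimator inconsistent. Noise
correction itself (an RMA-style background step) is upstream; a naive
percentile-shift corrector is provided only to build fixtures.

**Empirical signal distribution.** VST-scale values, averaged per gene
across replicates (which approximately cancels the error terms), are binned
into a 500-bin histogram. Simulated genes draw from it by inverse-CDF
sampling with linear interpolation inside bins — exactly "assign a bin by
frequency, then add uniform turbulence of one bin width", but monotone in
the underlying quantile, which is what makes the coupling below rank-exact.

**Quantile coupling.** One uniform quantile per gene feeds both the
empirical VST quantile function and the gamma quantile function of the
RNA-Seq mean λ (shape 0.7, scale 500 by default, linearly rescaled onto
(1, 3×10⁵) — mimicking the calibration of sampled means to a real
dataset's range). Both maps are strictly monotone, so the two true-signal
vectors are rank-identical: Spearman correlation exactly 1.

**Preset truth.** `n_deg` genes (default 1,000 of 10,000) are chosen
uniformly; |log2 FC| ~ N(μ, σ) truncated at zero with
μ = level + z₀.₉₅ σ, so that 95% of preset DEGs exceed the stated minimum
level — the *95% minimum fold change* rule. Signs are up with probability
0.5. σ defaults to 0.25 log2 units: small enough that a stated level is
meaningful, large enough that preset changes are not all identical; it is
configurable and the degenerate σ = 0 limit puts every magnitude exactly at
the level.

**Observed data.** RNA-Seq: treatment mean λ·2^FC, counts negative binomial
with variance m + φm² and per-gene φ ~ Gamma(1.2, 0.08) (mild
over-dispersion around 0.1). Microarray: the fold change enters the VST
scale as `log2_fc · ln 2` — a multiplicative change of the true intensity,
since g ≈ ln u at high signal; how a count-scale fold change should map
onto an intensity scale is not determined by the models themselves, and
this choice (configurable in principle via the truth table) makes the two
platforms agree at high signal while background compresses low-signal fold
changes, a realistic asymmetry. Each replicate then draws fresh η and ε.
All defaults (α_bg = 50, sd_ε = 10, sd_η = 0.25, and the gamma parameters
above) are documented fixture values chosen once for realism — raw
intensities in the tens to low hundreds of thousands, background about 50
units — not estimates from any dataset.

**Randomness.** One master seed; each operation (coupling, truth,
dispersions, counts, intensities) draws from a deterministically derived
sub-stream, so runs are bit-reproducible and adding replicates does not
perturb gene-level draws.

**What the generator does not emulate.** Technical-versus-biological
replicate structure, library-size heterogeneity beyond the NB mean,
isoform/exon-level signal, probe sequence effects, spatial artefacts, and
between-gene correlation. Passing benchmarks on these simulations therefore
demonstrates correctness of the machinery and behaviour under the stated
models — not performance on any particular real dataset.

## DEG calling and evaluation

The built-in caller is a per-gene two-sample Welch t-test with
Benjamini–Hochberg adjustment across all tested genes. Welch rather than
pooled variance is the safer default when group spreads differ (a pooled
option exists via `var_equal = TRUE`). Analysis scales: counts are tested
on log2(count + 1); raw intensities on log2 after clamping at 1 (the
additive background model makes a non-positive intensity a ~5×10⁻⁷ event;
clamping keeps the log finite and at worst inflates that gene's variance);
log2 input is used as is. Fold changes are reported on the linear scale as
the ratio of group means, with 0/0 defined as 1 (no change). Zero variance
in both groups gives p = 1 when the means are equal.

Thresholding is strict on fold change (> 2 or < 1/2; a fold change of
exactly 2 is not called) and inclusive on FDR (≤ 0.05). Scoring against
truth uses sensitivity tp/(tp+fn), empirical FDR fp/max(tp+fp, 1) — zero
for an empty call set, a convention needed when averaging across datasets —
and specificity tn/(fp+tn). `fc_sweep()` regenerates the preset truth at
each 95%-minimum level (default 0.5 to 4 by 0.5, log2 units, the scale on
which such sweeps are interpreted here), simulates `n_datasets` paired
datasets per level and averages each metric per level and caller.

External methods (SAM, eBayes, DESeq, baySeq, SAMSeq, NOISeq, …) are out of
scope to reimplement; `external_deg_caller()` runs any command-line tool
through a template (`{input}`, `{groups}`, `{output}`) and normalizes its
output into the same result contract, including q-score semantics for
callers without FDR control (larger q is more significant; cutoff
declarable, e.g. 0.8). Failures raise a classed error carrying the captured
log, and the benchmarking loop records them and continues.

## qRT-PCR arithmetic

Delta-Ct is oriented *reference minus target* (`ct_ref - ct_gene`), so a
larger value means higher expression;
`ddCt = mean(dCt_treated) - mean(dCt_control)`. Because the textbook
`2^-ddCt` formula presumes the opposite (target minus reference)
orientation, applying it literally to this delta-Ct inverts the ratio. Both
conventions are therefore implemented — `standard` (Livak orientation,
`2^{+ddCt}`, up-regulation gives a fold change above 1, the default) and
`literal` (`2^{-ddCt}`, with an informative message) — and their product is
exactly 1 on the same data; no claim is made about which convention any
particular published table used. A fully undetected control group with
detected treated samples yields an infinite fold change (an induction from
silence), flagged rather than erroring; both groups undetected is an
undefined result. The group test is a Student t-test on the delta-Ct
vectors (Welch optional), requiring two detected values per group.

## Problem sizes in the checks

The acceptance-style checks run at the stated study conditions — 10,000
genes, 1,000 preset DEGs at 95%-minimum level 2, 5 replicates per group,
10 datasets; 10,000-gene null calibration; 10,000-point VST grid; 50-seed
oracle agreement and the 200-simulation coverage study described above —
and the whole suite completes in well under a minute. Unit tests use
smaller instances of the same constructions.

## Known limitations

* The EIV model is the functional, homoscedastic variant with known-ratio
  errors; structural (random-ξ) and heteroscedastic variants are out of
  scope, and λ is assumed constant across genes after the 1% trim.
* The simulator couples platforms through a single shared quantile — real
  cross-platform rank agreement is below 1, so simulated concordance is an
  upper bound.
* The built-in t-test/BH caller is a reference method, deliberately simple;
  count-specific methods should come in through the adapter.
* Fold-change application to the microarray side of the simulation is a
  modelling choice (multiplicative on true intensity), not an estimated
  mapping.
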