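---
title: "Feed-efficiency traits and liver co-expression networks: methods"
author: "efnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feed-efficiency traits and liver co-expression networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efnet)
```

This vignette is the package's account of its methods: the models and
procedures, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical and design choices made where
more than one reasonable option existed.

## Residual feed-efficiency traits

A feeding trial records body weight every other week and mean daily
dry-matter intake (DMI) per animal. Average daily gain (ADG, kg/d) is the
per-animal OLS slope of body weight on feeding day — with six weighings this
is far more stable than an endpoint difference. Metabolic weight is
MBW^0.75 = (mean body weight over the weighings)^0.75 (kg^0.75). We read
"average metabolic weight" as the mean weight raised to 0.75 once; raising an
already-0.75-powered quantity to 0.75 again would be dimensionally
meaningless.

Two cohort-level regressions define the residual traits:

$$DMI = \beta_0 + \beta_1 ADG + \beta_2 MBW^{0.75} + \varepsilon_1
\qquad (RFI = \varepsilon_1)$$
$$ADG = \beta_0 + \beta_1 DMI + \beta_2 MBW^{0.75} + \varepsilon_2
\qquad (RWG = \varepsilon_2)$$

and RIG = RWG − RFI. Because they are OLS residuals, RFI and RWG are exactly
zero-mean and orthogonal to their regressors; the test suite asserts both to
1e-8 relative and checks the fits against an explicit normal-equation solve
to 1e-10. Animals whose ADG lies more than 2.5 SD from the cohort mean are
excluded *before* the trait regressions are fitted — residuals should come
from the cleaned cohort — and the traits are refitted on the remainder. The
fit errors out, naming the offending column, when the design is rank
deficient (e.g. constant ADG).

Group selection takes the `nPerGroup` highest-RIG animals as HFE and the
lowest as LFE; ties at a boundary are broken by ascending animal id so runs
are reproducible. Group comparisons follow a normality-routed rule: both
groups pass Shapiro–Wilk at α = 0.05 → two-sided pooled (Student) t-test,
otherwise Mann–Whitney–Wilcoxon. The pooled form is the default because it
is the classical "Student's t-test"; Welch is available via `welch = TRUE`.
A zero-variance group forces the rank-sum route with a warning, since the
pooled t statistic is then degenerate.

## Expression preparation

Counts are normalised as CPM (`count / library size × 1e6`) with a
low-expression filter keeping genes at ≥ 1 CPM in at least half the samples,
and as FPKM (`count / (length_kb × library_millions)`) with upper-quartile
normalisation: each sample is scaled so its 75th percentile of non-zero FPKM
equals the across-sample mean of those percentiles. Upper-quartile is the
standard reading of "quartile normalisation" for RNA-seq; the quantile is a
parameter (`quartile = 0.5` gives median scaling). The normalisation is
invariant to uniform per-sample depth changes, which the tests assert to
1e-9.

The network QC filter drops genes with zero counts in more than 7 samples
("missing" in an RNA-seq matrix can only mean zero), and genes with mean
below 0.5 or SD below 0.2. The direction of the mean/SD rules deserves a
note: the motivating description of this filter states thresholds alongside
a rationale (low counts are unreliable; near-constant genes are
uninformative) that only makes sense when *low* mean and *low* SD are
excluded, so that is the default (`direction = "informative"`); the literal
opposite reading is available as `direction = "exclude-high"` and is logged
whenever used.

Connectivity pre-selection scores each gene by K = Σ_j |cor| and keeps the
top 3500 (ties by ascending gene id). Unsigned correlation at power 1 is
used here because this score precedes any soft-thresholding; whether to use
signed correlation is exposed as `absolute = FALSE`.

## The weighted co-expression network

The network is **unsigned**: a_ij = |cor_ij|^β. With odd powers such as
β = 3 a signed network would produce negative "adjacencies", so unsigned is
the only self-consistent choice, and it is also the common default in this
analysis family. Raising β weakly decreases every off-diagonal entry
(|cor| ≤ 1), a monotonicity property the tests check.

β is chosen by a scale-free topology criterion: for each candidate, bin the
connectivity distribution into 10 bins and regress log10(frequency) on
log10(mean K); the fit R² measures power-law closeness. The chosen β is the
smallest candidate with R² ≥ 0.9, else the argmax with a warning. Degenerate
binning (all-equal K) skips the candidate.

TOM is computed in matrix form (L = A·A with zeroed diagonal), which equals
the textbook triple loop to 1e-12 — asserted on 200 random instances — and
is 1 on a complete graph, strictly positive for two leaves of a shared hub,
and bounded in [0, 1].

**Module detection** uses average-linkage clustering of 1 − TOM with a
simplified dynamic cut: a static cut at 0.99 × the maximum merge height,
then a recursive local re-cut of every branch large enough to hide two
modules, accepted only when it separates at least two clusters of module
size (≥ 30 genes by default). The acceptance gate is what keeps the rule
safe: a homogeneous module cannot split into two module-sized pieces, while
two distinct modules sharing a branch merge near its top and are separated
by the local cut. This replaces the published hybrid tree-cut algorithm;
it is deliberately simple, parameterised (`cutQuantile`, `minModuleSize`),
and validated by planted-module recovery (adjusted Rand index ≈ 0.96 on
average at the test conditions) rather than by matching any specific
historical module list. Clusters below the size floor become `grey`;
surviving modules get colour names by decreasing size from a fixed palette,
so labels are deterministic.

Eigengenes are first principal components of the per-gene standardised
module submatrix, unit-norm, oriented so their correlation with the module
mean profile is non-negative (PCA signs are otherwise arbitrary).
Eigengene–trait correlations use the exact t-transform on n − 2 df,
two-sided, with no multiplicity correction across modules — the selection
gate (|r| > 0.5 strict, p ≤ 0.1 inclusive) is a screening rule, not an
inference. kME thresholds apply to absolute values, since a strongly
anti-correlated gene is as informative about a module as a correlated one.

## Differential connectivity

Per-group sub-networks use the group's own samples and powers β = 4 (HFE)
and β = 20 (LFE); K is max-normalised within each group and
KDiff = K_LFE_norm − K_HFE_norm. Both βs are prominent, logged parameters
because their asymmetry makes the statistic asymmetric under the null:
with small groups the null connectivity floor (Σ|r|^4 over all genes) is
substantial in the β = 4 network and negligible in the β = 20 network, so
null genes sit at high normalised connectivity in HFE and near zero in LFE,
and KDiff skews negative. This behaviour is intrinsic to the statistic, and
it has a practical consequence worth stating plainly: with 7 samples per
group, genes from a module planted with within-correlation 0.9 in LFE and
0.1 in HFE separate clearly from the background in mean KDiff (the
directional property the tests assert), but very few clear the fixed
|KDiff| > 0.6 flag, because the r^20 sub-network spreads normalised
connectivity widely across module genes while the β = 4 null floor keeps
K_HFE_norm high. Monte-Carlo exploration during development showed the flag
rate reaches 80% only when the planted within-correlation approaches 0.99
with a strong opposing hub module — i.e. the threshold is a property of
large, strongly structured real networks, not of small planted designs.
Both the group-level connectivities and the same QC-passed gene set feed
both sub-networks (no per-group refiltering). Exchanging the group labels
together with the two βs negates KDiff exactly; the tests assert this
identity and the [−1, 1] bounds.

Permutation-based significance for KDiff is out of scope; the fixed
threshold is the documented behaviour, and `selectDifferentiallyConnected`
exposes the threshold for sensitivity analyses.

## Enrichment

Over-representation uses the upper-tail hypergeometric test against a
caller-supplied background universe — making the universe explicit avoids
the hidden defaults of web tools — with Benjamini–Hochberg FDR and
significance at padj ≤ 0.1. Terms with zero study hits are excluded from the
multiple-testing burden by default (`minHits = 0` includes them). The
annotation is flat: no ontology-graph propagation, which is a deliberate
simplification documented here. Duplicate study ids are dropped with a
warning.

## The synthetic-data generator

The generator exists so every downstream stage can be validated against a
known truth. It emulates:

* a 70-day trial of 98 animals entering at 376 ± 29 kg, weighed every
  14 days (weighing noise SD 4 kg), systematic gain ≈ 1.86 ± 0.30 kg/d;
* intake driven by gain and metabolic weight
  (DMI = −0.5 + 1.5·ADG + 0.09·MBW^0.75, in kg/d), plus a planted
  bivariate-normal residual pair with SD(RFI) = 0.90, SD(RWG) = 0.35 and
  correlation −0.60 — values calibrated once from the selection
  differentials of published extreme-group means, and flagged as
  approximate because pre-selection variances are rarely reported;
* 7 + 7 liver RNA-seq samples from the extreme RIG tails with
  module-structured counts: one trait-linked module (100 genes, r = 0.7 to
  RIG), one group-specific-connectivity module (50 genes, within-correlation
  0.9 in LFE, 0.1 in HFE), one neutral module (80 genes), 8 DE genes at
  log2FC 1.5, negative-binomial dispersion 0.05, base means log-normal
  around 150 — typical bulk-liver values;
* a flat annotation with one term planted exactly on a chosen gene set.

Two constructions deserve explanation. First, the **gain residual enters the
observed ADG only through its intake-orthogonal component**. OLS residuals
are orthogonal to the regressors, so if the full gain residual (correlated
−0.60 with the intake residual) sat inside observed ADG, the recovered RFI
could correlate with the planted one at no better than ~0.89 by
construction. With the orthogonalised injection the recovered RFI equals the
planted residual up to sampling leakage: fitting 3 parameters to 98 animals
absorbs on average 3/98 of the residual variance, so recovery concentrates
at √(1 − 3/98) ≈ 0.985 — the tests assert the package matches the
normal-equation oracle exactly and that recovery matches this analytic
value. The trial-level correlation between recovered RFI and RIG lands at
≈ −0.97, matching the closed form cor(X, Y − X) of the planted pair.

Second, module loadings are **lifted for count-noise attenuation**: counting
noise (variance ≈ 1/μ + dispersion on the log scale) attenuates
correlations measured on counts below the latent ones, so per-gene loadings
are scaled by the inverse reliability (capped at loading 1) to hit the
requested within-group correlation on the generated counts themselves.

One global seed expands into fixed per-component child seeds, so adding a
component never perturbs the draws of another, and identical configurations
are bit-reproducible.

What the generator does **not** emulate: library-size variation and
GC/length biases, count outliers, correlated background structure,
overlapping or nested modules, hub-dominated scale-free topology beyond what
the module model induces, and any read-level artefacts. Passing recovery
tests therefore demonstrate the pipeline's correctness on clean planted
structure, not its robustness to every artefact of real data.

## Problem sizes and numerical choices

The test and validation runs use deliberately modest sizes chosen to
exercise every code path with comfortable margins: 300–1000 genes, 14
samples, 3 planted modules for recovery (adjusted Rand index averaged over
three seeds), 20 seeds for the residual-correlation calibration, 200 random
instances for the TOM oracle, and exhaustive hypergeometric enumeration up
to N = 25. Matrix symmetry is enforced to 1e-8, TOM oracle equality to
1e-12, regression identities to 1e-10. Ties are always broken by ascending
id; degenerate inputs (zero-variance genes, all-zero connectivity, empty
study sets, rank-deficient designs) raise errors naming the offender rather
than propagating NaNs.

## Known limitations

* The dynamic-cut simplification can absorb background genes into module
  flanks; the kME membership filter downstream is the corrective, and
  module gene lists for enrichment should always come from
  `filterByMembership`.
* The |KDiff| > 0.6 flag is effectively one-sided at small group sizes (see
  above); interpret flag counts per group, not as symmetric evidence.
* Eigengene–trait screening at n = 14 has r sampling SD ≈ 0.2; a planted
  link of 0.7 occasionally misses the 0.5 gate in a single draw.
* The enrichment model treats annotations as flat and independent; terms
  related through an ontology hierarchy will co-fire.
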