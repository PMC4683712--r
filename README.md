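# efnet

Feed efficiency decides much of the cost and environmental footprint of beef
production, but it cannot be read off a scale: it has to be estimated from a
feeding trial and then connected to the underlying liver physiology. `efnet`
is an R package for exactly that workflow. It computes residual
feed-efficiency traits from trial records, splits animals into extreme
efficiency groups, and analyses liver RNA-seq expression with a weighted gene
co-expression network: module detection, eigengene–trait correlation,
differential connectivity between efficiency groups, and term enrichment.
It is aimed at animal scientists and computational biologists who want the
whole chain — phenotype regression to enriched terms — as tested, scriptable
functions, plus a synthetic-data generator with planted ground truth for
validating every stage.

## The traits and statistics at the core

**Feed-efficiency traits.** Average daily gain (ADG) is the per-animal OLS
slope of body weight on feeding day; metabolic weight is
MBW^0.75 = (mean BW)^0.75. Two regressions over the cohort define the
residual traits:

    DMI = β₀ + β₁·ADG + β₂·MBW^0.75 + ε₁        (RFI = ε₁)
    ADG = β₀ + β₁·DMI + β₂·MBW^0.75 + ε₂        (RWG = ε₂)

RFI is intake not explained by growth and body size (lower = more
efficient); RWG is gain not explained by intake and size (higher = more
efficient); RIG = RWG − RFI combines both, and the extreme RIG tails define
the high- (HFE) and low-feed-efficiency (LFE) groups. FCR = DMI/ADG.

**Co-expression network.** For the filtered expression matrix, the unsigned
adjacency is a_ij = |cor(x_i, x_j)|^β with β chosen by a scale-free topology
criterion. The topological overlap

    TOM_ij = (Σ_u a_iu·a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)

measures shared neighbourhood; average-linkage clustering of 1 − TOM with a
dynamic branch cut yields modules (≥ 30 genes, colour-named). Each module is
summarised by its eigengene (first principal component); modules with
eigengene–trait correlation |r| > 0.5 (p ≤ 0.1) against RFI or RIG are
selected, and genes are kept for enrichment when their module membership
(kME) is > 0.6 for their own module and < 0.6 elsewhere.

**Differential connectivity.** Per-group sub-networks (powers β = 4 for HFE,
β = 20 for LFE) give whole-network connectivities K_i = Σ_j |cor_ij|^β,
max-normalised within each group, and

    KDiff(i) = K_LFE(i) − K_HFE(i)  ∈  [−1, 1],

with |KDiff| > 0.6 flagging differentially connected genes (negative =
HFE-connected).

**Enrichment.** Gene lists are tested against a flat gene→term annotation by
the upper-tail hypergeometric test with Benjamini–Hochberg FDR (significant
at padj ≤ 0.1).

## Worked example

```r
library(efnet)

trial <- simulateFeedTrial(trialSimConfig(seed = 1))   # 98-animal, 70-day trial
pheno <- computeFeedTraits(trial$phenotypes, nPerGroup = 20)
pheno
#> PhenotypeTable: 98 animals, 6 weigh days
#> groups: HFE=20, LFE=20, unassigned=58

tr <- feedTraits(pheno)
head(tr[order(-tr$rig), c("animal_id", "adg", "dmi", "fcr", "rfi", "rwg",
                          "rig", "group")], 4)
#>    animal_id  adg   dmi  fcr   rfi   rwg  rig group
#> 26      A026 1.80  8.04 4.46 -2.13 0.267 2.40   HFE
#> 21      A021 2.30  9.63 4.19 -1.55 0.523 2.07   HFE
#> 88      A088 2.46 10.97 4.46 -1.74 0.324 2.06   HFE
#> 57      A057 1.75  8.43 4.83 -1.84 0.156 2.00   HFE
```

The top animals by RIG eat 1.5–2.1 kg/d less than their growth and body
size predict (negative RFI) while gaining slightly more than predicted
(positive RWG). The two groups then differ sharply in feed conversion:

```r
cmp <- compareGroups(tr$fcr[tr$group != "unassigned"],
                     tr$group[tr$group != "unassigned"])
#> FCR HFE vs LFE: wilcoxon test, p = 5.4e-09
```

(`compareGroups` routes through Shapiro–Wilk and picks Student's t or the
rank-sum test accordingly.) The full expression workflow runs from one
configuration:

```r
res <- runPipeline(list(seed = 1), outdir = "run1")
#> phenotypes: 98 animals, 1 excluded (ADG outliers), 20 per group
#> expression: 1000 genes x 14 samples
#> CPM filter (>= 1 CPM in >= 7 samples): 1000 of 1000 genes kept
#> network QC filter: 1000 of 1000 genes kept
#> connectivity pre-selection: 1000 genes retained
#> soft threshold: beta = 5 (scale-free R2 = 0.914)
#> modules: 9 detected (sizes: turquoise=200, blue=145, brown=67, ...); 328 genes grey
#> trait-associated modules: turquoise (-rfi/+rig)
#> differential connectivity: 240 HFE-connected, 0 LFE-connected (of 1000)
#> enrichment: module_turquoise: 1 significant terms; diffcoexp_hfe: 0 significant terms
```

Here the planted trait-linked module is recovered as `turquoise`, selected by
the eigengene gate with the expected sign pattern (efficient animals have
lower module expression), and the term planted on its genes is the one
significant enrichment hit. Stage outputs (traits, module assignments,
eigengenes, KDiff table, enrichment) are written as TSVs under `run1/`
together with `report.txt` and the resolved configuration.

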