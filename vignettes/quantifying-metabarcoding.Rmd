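---
title: "Anchoring phytoplankton metabarcoding to microscopy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchoring phytoplankton metabarcoding to microscopy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytoanchor)
```

## The problem

Light microscopy and amplicon metabarcoding observe the same phytoplankton
community through very different instruments. Microscopy yields *absolute*
quantities — cells per litre, and biomass once cell volumes are known — but
is limited in taxonomic resolution for small and cryptic taxa.
Metabarcoding (here imagined as 18S rRNA amplicon sequence variants, ASVs)
resolves many more taxa but only yields *relative* read abundances, and
those are distorted by amplification bias: marker-gene copy number grows
with cell biovolume, and primer affinity differs between classes.
Dinoflagellates, with very high per-cell copy numbers, are the canonical
example of a class whose read share overstates its cell share.

`phytoanchor` implements the conversion of ASV relative abundances into
absolute abundance and biomass by *anchoring* them to microscopy, and the
statistical machinery used to ask whether the two methods tell a
consistent story.

## The anchoring model

Let $a_{ij}$ and $m_{ij}$ be the microscopy abundance (cells L$^{-1}$) and
biomass (mg L$^{-1}$) of species $i$ in sample $j$, and $R_{ij}$ the
relative read abundance of ASV $i$ among the phytoplankton reads of sample
$j$.

**Total anchoring** uses the sample totals
$A_j = \sum_i a_{ij}$, $M_j = \sum_i m_{ij}$:
$$\bar a_{ij} = R_{ij} A_j, \qquad \bar m_{ij} = R_{ij} M_j.$$

**Class-specific anchoring** restricts both sides to one taxonomic class
$c$: with $A_{jc}$, $M_{jc}$ the class totals and $R_{ijc}$ the ASV's
share of class-$c$ reads,
$$\bar a_{ijc} = R_{ijc} A_{jc}, \qquad \bar m_{ijc} = R_{ijc} M_{jc}.$$

Both schemes conserve their anchor exactly: the anchored estimates of a
sample (or of a class within a sample) sum back to $A_j$ (or $A_{jc}$) by
construction, and `absoluteByTotal()` / `absoluteByClass()` are tested to
hold this to relative $10^{-9}$.

The modelling assumption behind total anchoring is that an ASV's share of
phytoplankton reads approximates its share of total phytoplankton cells.
Class anchoring weakens that assumption to *within-class* proportionality:
between-class bias (copy number, primer efficiency) cancels because both
numerator and denominator live inside one class, where cell sizes — hence
copy numbers — are more homogeneous. The cost is missingness: when a class
has reads in a sample but microscopy recorded no cells of that class,
$A_{jc} = 0$ and the estimate is *undefined*. These cells are masked `NA`,
deliberately distinct from zero, and excluded pairwise from downstream
correlations; coding them as 0 would bias correlations toward agreement.
Classes seen by metabarcoding alone can be anchored through a
morphologically similar proxy class (`proxyClassMap()`).

## Microscopy-side conventions

* **Biovolume.** Cell volume is computed from an assigned geometric shape
  and measured dimensions (`cellBiovolume()`). Seven standard shapes are
  registered (sphere, cylinder, prolate spheroid, box, cone, double cone,
  ellipsoid); the registry is extensible because shape catalogues differ
  between laboratories and no single published set is canonical.
* **Biomass.** `speciesBiomass()` multiplies abundance by mean cell volume
  at unit density (1 g cm$^{-3}$). The default unit scale $10^{-9}$ maps
  µm$^3$ · cells L$^{-1}$ to mg L$^{-1}$. Published phytoplankton tables
  are not always consistent about this scale (mg L$^{-1}$ versus
  mg m$^{-3}$ differ by $10^3$), so the factor is an explicit parameter
  rather than a constant: all anchoring and correlation results are
  invariant to it except for the units of the biomass outputs.
* **Cryptic pairs.** Species pairs that light microscopy cannot separate
  can be split by electron-microscopy relative counts
  (`semSplitPair()`), which conserves the pooled totals exactly and warns
  when fewer than 100 cells were counted, the customary minimum.
* **Cyanobacteria** are dropped at table construction (they are invisible
  to an 18S marker).

## ASV-side conventions

`filterAsvs()` removes ASVs with total read support ≤ 2 and lineages
matching Metazoa, Streptophyta, nucleomorph-derived (":nucl") sequences,
Bacteria, Archaea, or unclassified at the domain rank.
`selectPhytoplankton()` then keeps autotroph and mixotroph classes
(mixotroph classes such as Chrysophyceae and Cryptophyceae count as
phytoplankton); the class→trophic lookup is configurable
(`defaultTrophicMap()`). Relative abundances are computed over
*phytoplankton-only* reads — this denominator choice is what makes
"$R_{ij}$ approximates the ASV's share of total phytoplankton" coherent.
Every filter records counts in/out so the full trail is auditable.

Two selection knobs precede correlation analysis: a prevalence filter
(default: present in ≥ 8 of 27 samples) and an optional top-$N$ cut by
total reads with lexicographic tie-break. When both relative-abundance
renormalisation scopes are defensible (all phytoplankton ASVs versus the
selected subset), the package defaults to renormalising over **all**
phytoplankton ASVs and treats the subset purely as a feature selection.

## Consistency statistics

* **clr transform.** Correlating raw proportions invites compositional
  artefacts, so `clrTransform()` maps each composition to
  $\ln(x_i/g(x))$. Zero handling is unavoidable and not standardised; the
  package uses multiplicative replacement (each zero becomes 0.5 × the
  row's smallest nonzero proportion, the rest rescaled to keep the row
  closed) and records the pseudo-value per sample in the result object.
* **Rank scaling.** `rank01Transform()` maps each feature to
  $(\mathrm{rank}-1)/(n-1)$ with average ranks for ties; constant features
  map to 0.5.
* **Spearman grids.** `spearmanGrid()` computes all-pairs Spearman
  correlations with two-sided p-values from the t approximation
  $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df, and applies Benjamini–Hochberg
  adjustment jointly over every defined cell of a grid (one family per
  grid, matching per-analysis correction). Masked values are dropped
  pairwise; pairs with fewer than 4 complete samples are undefined, not
  errors. An exact permutation p-value is available (`exact = TRUE`) for
  $n \le 12$ without ties; the t approximation is the default because it
  is well defined at every $n$ and reproducible. The companion
  `criticalR(n, alpha)` inverts the same approximation; at $n = 27$,
  $\alpha = 0.05$ it gives 0.3809, the familiar "significant if
  $|r| \ge 0.38$" threshold for a 27-sample design.
* **Heatmap ordering.** `heatmapOrder()` clusters rows and columns of a
  correlation matrix (Euclidean distance, complete linkage), imputing
  undefined cells as 0 for the distance only and sorting labels first so
  the leaf order is permutation-invariant.
* **Co-inertia / RV.** `rvCoefficient()` implements
  $\mathrm{RV} = \operatorname{tr}(X^\top Y Y^\top X) /
  \sqrt{\operatorname{tr}((X^\top X)^2)\operatorname{tr}((Y^\top Y)^2)}$
  on column-centered tables; `coinertia()` decomposes the cross-covariance
  by SVD into co-inertia axes. A classical-MDS (Euclidean PCoA) embedding
  of each table is rotation-equivalent to the centered table itself and
  yields the identical RV, so the direct form is used; rotation invariance
  is unit-tested. Note that RV on raw absolute values is dominated by the
  highest-variance features; orderings of RV across data variants are
  therefore sensitive to scaling in a way the correlation-count summaries
  are not.
* **Diversity.** `diversityProfile()` reports richness, bias-corrected
  Chao1 ($S + F_1(F_1-1)/(2(F_2+1))$, integer counts only), Shannon in
  nats, and Gini–Simpson $1-\sum p^2$; `rarefactionCurve()` returns the
  analytic hypergeometric expectation. These delegate to vegan.

## The synthetic community generator

Real paired datasets with known truth do not exist, so the package ships a
generator (`generatorConfig()`, `generateDataset()`) that emulates the
study design every downstream stage is tested against:

* a 9 stations × 3 years = 27-sample grid with identifiers `"1_20"` …
  `"9_22"`;
* six phytoplankton classes (diatom classes, Chrysophyceae,
  Cryptophyceae, Dinophyceae, green algae) with lognormal species
  abundances; a shared class-by-year lognormal effect (sd 0.7) makes
  samples within a year correlated, mirroring year-dominant spring
  communities, with residual per-sample noise (sd 0.4);
* lognormal cell volumes per class; large-celled, high-bias Dinophyceae
  versus small-celled green algae;
* microscopy observation: Poisson counting at an effective counted volume
  of 0.01 L (of the order of a settled-and-concentrated aliquot), rescaled
  to cells L$^{-1}$; zeros arise naturally from Poisson sampling, with no
  extra zero-inflation knob;
* read generation: expected ASV weight ∝ abundance × copy number ×
  class primer efficiency, with copy number = volume$^b$ ($b = 0.6$ by
  default, reflecting the published biovolume–copy-number correlation
  without species-level free parameters), multinomial sampling at depth
  30,000 (within the range of real sample depths), heterotroph ASVs with
  independent lognormal weights (22 by default), and an imperfect
  species↔ASV map (70% one-to-one, 20% merged into genus-level ASVs
  within class, 10% metabarcoding-only, allocated community-wide so small
  classes are not rounded to zero).

Two named regimes fix the conditions used by the package's own
validation: `unbiasedConfig()` ($b = 0$, equal primer efficiencies, no
heterotrophs, strict one-to-one mapping, depth $10^5$), under which read
proportions converge to true relative abundances and total anchoring
recovers true per-species abundances (per-species Spearman ≥ 0.9 across
the 27 samples for species with mean relative abundance ≥ 1%); and
`classBiasConfig()`, where bias is structured strictly at class level
(within-class volume spread zero), the premise under which class
anchoring should — and in the tests does — beat total anchoring in
matched species–ASV correlation coefficients, while total anchoring in
turn yields more significant positive correlations than raw relative
values.

What the generator does **not** emulate: sequence-level error (no FASTQ,
chimeras, or denoising — ASV inference is upstream of this package),
tag-jumping/cross-talk, within-class copy-number variation under
`classBiasConfig()`, DNA-extraction bias, and spatial hydrodynamics.
Passing tests therefore demonstrate correctness of the estimators under a
known observation model, not that any real community satisfies that model.
No quantitative bias magnitudes for real lake taxa are published, so the
default magnitudes are chosen for testability and plausibility, not fitted
to data.

## Numerical and degenerate-input choices

* Samples with zero reads in a scope are flagged empty and produce masked
  (`NA`) estimates rather than NaNs.
* Top-$N$ ties break lexicographically by ASV id; clustering leaf order
  sorts labels before linkage — both make reruns byte-identical.
* The generator derives the microscopy and read seeds from the config
  seed by fixed offsets, so each stage is individually reproducible and
  the composed dataset is too.
* Validity methods enforce the core invariants at construction: non-empty
  relative-abundance columns sum to 1 ± 10$^{-9}$, clr rows sum to
  0 ± 10$^{-9}$, class anchor totals add up to sample totals, q ≥ p in
  correlation grids.

## Problem sizes used in the test suite

The suite validates conservation on 100 random fixtures, the RV oracle on
25 random 5 × 3 tables against a brute-force double-sum, rarefaction
against $10^4$ Monte-Carlo subsamples of a small vector, convergence of
read proportions at depth $10^6$, parameter recovery at depth $10^5$ over
27 samples, and the end-to-end trend comparison on the default 27-sample
class-bias community. These sizes keep the full suite under a minute
while leaving each statistical check with comfortable power.

## Known limitations

* Biomass anchoring reuses the read-based $R$ matrix; no per-taxon
  cell-volume correction factor is applied by default (the hook exists
  but correction factors require reference data the package does not
  ship).
* Chao1 is undefined on non-integer abundances; microscopy-side diversity
  therefore omits it.
* The class scheme inherits microscopy's class-identification quality;
  masked cells concentrate exactly where microscopy is weakest.
* RV orderings across raw-scaled data variants should be interpreted with
  the scale-sensitivity caveat above.
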