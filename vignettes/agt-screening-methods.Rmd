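---
title: "Methods: screening rice germplasm for anaerobic germination tolerance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening rice germplasm for anaerobic germination tolerance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agtscreen)
```

## The screening problem

Direct-seeded rice is prone to flooding right after sowing: the germinating
seed sits under water, oxygen becomes limiting, and most genotypes fail to
establish. A minority of genotypes — many of them traditional landraces —
escape by rapidly elongating the coleoptile to the water surface.
`agtscreen` implements the complete statistical analysis of a replicated
screening trial for this trait: a panel of genotypes is germinated under
controlled submergence in a randomized complete block design (RCBD),
repeated over seasons, and scored for germination and seedling vigor.

The packaged example data (`agt_panel()`) are the pooled genotype means of
a 119-genotype panel (115 south-Indian landraces plus four check
varieties) screened twice under 15 days of 10-cm submergence, five seeds
per replicate, three replicates per season, with fourteen traits per
genotype and a published grain-type label.

## Indices and classification

Two derived quantities summarise performance under hypoxia:

* the **anaerobic vigor index**, `AVI = AGP × (SL + RL)`, combining the
  anaerobic germination percentage with shoot and root length of the
  stressed seedlings (`anaerobic_vigor_index()`), and
* the **response index**, `RI = SL(submerged) − SL(control)`, positive when
  submergence stimulates elongation (`response_index()`).

Tolerance classes partition AGP: ≥ 90 tolerant, (70, 90) moderately
tolerant, (40, 70] moderately susceptible, ≤ 40 susceptible
(`classify_tolerance()`). The published class bands are integer ranges
("71%–89%", "41%–70%"); with five seeds × three replicates × two seasons,
AGP lives on the lattice 100k/30, so fractional values such as 70.4 can
occur. We close the partition with the half-open intervals above, which
reproduce the published class counts (11/36/43/29) exactly on the packaged
panel.

Grain types come from kernel dimensions. The source report classifies
"as per the literature" without stating the rule; `grain_type_rule()`
encodes the convention that reproduces 118 of the 119 published labels:
kernel length ≥ 6 mm is *long* (slender if the length-to-breadth ratio
LBR ≥ 3, else bold); short kernels are *short-slender* (LBR ≥ 3),
*medium-slender* (2.5 ≤ LBR < 3) or *short-bold* (LBR < 2.5), with
short-slender reported merged into short-bold because both groups are
small. The one disagreement (a 5.0 mm, LBR 2.50 kernel labeled long-bold)
is unreachable by any monotone KL/LBR rule and we treat it as a data-entry
anomaly. All thresholds are arguments, not constants.

```{r score}
scored <- score_panel(agt_panel())
attr(scored, "tolerance_counts")
```

## Variance components and genetic variability

Per season, the RCBD expected mean squares give the method-of-moments
estimators `σ²e = MSe` and `σ²g = (MSg − MSe)/r` (`anova_rcbd()`). Pooled
over s seasons (`anova_pooled()`), blocks are nested within season,
`σ²ge = (MS_gxs − MSe)/r`, `σ²g = (MSg − MS_gxs)/(rs)`, and the genotype F
ratio is tested against the genotype-by-season mean square. Negative
estimates are clamped at zero and flagged; the raw values stay available.
No REML machinery is used — the method-of-moments route is the one this
type of screening report uses, and it is exactly testable against
brute-force sums over cell means (which is how the test suite checks it).

`variability_parameters()` turns components into the standard screening
statistics: GCV, PCV, broad-sense heritability `h² = 100 σ²g/σ²p`, genetic
advance `GA = k (h²/100) σ` with selection differential k = 2.06 (top-5%
selection, the community default), GAM = 100·GA/mean and
`SED = √(2σ²e/r)`. Two deliberate choices:

* **GA basis.** Textbooks put σ_p in the genetic-advance formula; screening
  reports of this kind often use σ_g. Reconstructing the published table
  from its own GCV/PCV/mean columns shows the σ_g variant reproduces the
  printed GA for 13 of 14 traits to printed precision, so `"genotypic"` is
  the default and `"phenotypic"` a flag. (The remaining trait, RI, prints
  GA and GAM exactly 10× the value implied by its own row — a scale slip in
  the source; the tests pin down that factor rather than ignore the row.)
* **Phenotypic-variance basis.** With components from a pooled analysis the
  plot basis `σ²p = σ²g + σ²ge + σ²e` is the default; with a single season,
  `σ²g + σ²e`. An entry-mean basis is available. The basis used by the
  source report is not recoverable from its printed values (its pooled
  variance components and its coefficients of variation are mutually
  inconsistent under every textbook formula), so no published variance
  *magnitudes* are asserted anywhere — only formula-level identities and
  simulation recovery.

## Group comparison

`snk_letters()` implements the Newman–Keuls studentized-range procedure on
group means with a Tukey–Kramer standard error per pair, so the unequal
group sizes of real panels (63/24/13/19 here) are handled. Quantiles come
from `stats::qtukey()`. Letters are the maximal runs of mutually
indistinguishable groups in the ranking; the test suite checks the letter
relation against an independently coded recursive range-test oracle, and
checks the familywise error rate by simulation. `group_summary()` applies
this per trait over any grouping column, with the genotype as the
experimental unit — that choice reproduces the published group means
exactly and the published letter patterns.

## Multivariate structure

`correlation_matrix()` gives Pearson correlations with two-sided t-test
p-values. `trait_pca()` standardizes the traits (population divisor n;
with n = 119 the n vs n−1 choice moves eigenvalues far below any reported
precision) and eigen-decomposes the correlation matrix; cos² values are
squared loadings, so each column sums to its eigenvalue and each trait row
sums to one. Eigenvector signs are fixed by making each vector's
largest-magnitude entry positive, so results are reproducible across
platforms.

`gower_distance()` is the range-normalized mean absolute difference
(all fourteen traits are numeric, so the general mixed-type machinery is
unnecessary; the result is checked against `cluster::daisy()` in the
tests). `ward_d2_cluster()` wraps `stats::hclust(method = "ward.D2")` and
`cutree()`; the cluster count k is a user input (the source report used 6
for phenotypes and 4 for markers) because no automatic selection rule was
given. The trait set is configurable with an `ag_traits()` preset, since
the report clusters "on the traits associated with AG potential" without
listing them; the headline co-clustering of the four most tolerant
landraces holds under both the preset and all fourteen traits.
Dendrograms export to Newick via `ape`.

## Marker diversity and association

`allele_stats()` computes allele counts, major-allele frequency and PIC per
locus. PIC defaults to the Botstein form
`1 − Σp² − Σ_{i<j} 2p²q²` used by the standard marker software for inbred
panels; the plain expected-heterozygosity form is a flag, because the two
cannot be distinguished at the rounding of the published values. Each
genotype contributes one call per locus (inbred landraces scored from band
presence); heterozygotes are out of scope.

Three marker distances are provided (`genetic_distance()`): a Nei–Li band
coefficient, a shared-allele proportion, and an unnormalized mismatch
count. Published marker-based distances for this panel exceed 1, which
only the unnormalized form can produce; since the raw marker scores were
never published, none of the published marker numbers are asserted —
marker code is validated on closed forms and simulated panels with known
frequencies. `single_marker_analysis()` is the one-way ANOVA per
marker × trait with `R² = 100·SS_between/SS_total`, reported with raw
p-values (matching the source's practice) plus Benjamini–Hochberg adjusted
ones as an extension.

## Synthetic data: what it emulates and what it does not

The generators define the study conditions under which everything is
tested, since replicate-level data and marker gels were never deposited:

* `simulate_trial()` draws from `y = μ + g + s + gs + b(s) + e` with
  independent normal effects — the model the RCBD ANOVA assumes — at the
  real design size (119 × 2 × 3 by default).
* `simulate_germination()` adds the binomial layer: emerged ~
  Binomial(5, p) per replicate, so pooled AGP values sit on the same
  100k/30 lattice as the published panel.
* `simulate_markers()` draws i.i.d. calls from per-locus allele
  frequencies (2–4 alleles, matching the published locus structure) with
  optional missingness.

What passing tests show is that the estimators are correct *under the
assumed model*: unbiased variance components, nominal type-I rates,
perfect recovery of well-separated clusters. Real screening data add
features the generators deliberately omit — bounded and discrete AGP in the
ANOVA (the normal model is an approximation there), spatial correlation
within trays, genotype-specific error variances, linkage between loci —
so simulation results quantify correctness of the arithmetic, not field
performance.

Monte-Carlo problem sizes used by the test suite (500 recovery
replicates at g = 100, 1,000-replicate null calibrations for the SNK and
marker tests) were chosen so each check resolves its tolerance with
comfortable margin while the whole suite stays quick to run.

## Numerical and design notes

* Balance is validated, never assumed; unbalanced trials are rejected with
  the offending cell named. `validate_trial()` gives a report-only path.
* Exactly constant inputs short-circuit the ANOVA sums of squares to exact
  zeros (QR noise would otherwise masquerade as variance), with F flagged
  undefined.
* Genotype labels are case- and whitespace-normalized before phenotype and
  marker tables are matched.
* Missing marker calls use the token `-`; missing phenotype cells are
  errors, because every analysis here assumes complete means.
* `run_pipeline()` funnels all stages off one config (list or YAML), writes
  only text formats, and stamps outputs with an md5 hash of the
  canonicalized config so a re-run is verifiably identical.

## Known limitations

* Published variance-component magnitudes, marker-table values and the
  exact dendrogram topology are not reproducible from the published data
  and are not targets; see above.
* The SNK letter display assumes the range-test structure (non-significant
  sets are contiguous in the ranking); it is not a general graph-coloring
  letter algorithm.
* No narrow-sense heritability, parent–offspring regression, REML, QTL or
  linkage analysis.
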