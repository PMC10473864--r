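---
title: "Models and methods behind asymlat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind asymlat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(asymlat)
```

# The angular asymmetry index

For a paired measurement (L, R) of the same structure in the left and
right hemisphere, the package's central statistic is the angle

$$\theta = \arcsin\!\left(\frac{L - R}{\sqrt{2\,(L^2 + R^2)}}\right),$$

the angular deviation of the point (L, R) from the symmetry diagonal
L = R. Its useful properties, all asserted as tests:

* **Scale invariance**: $\theta(cL, cR) = \theta(L, R)$ for any $c > 0$,
  so the index does not depend on measurement units.
* **Antisymmetry**: swapping hemispheres flips the sign.
* **Boundedness**: on nonnegative pairs $|\theta| \le \pi/4$, with
  equality exactly when one side is zero; over arbitrary real pairs
  $|\theta| \le \pi/2$.
* **Rank equivalence with the traditional index** $(L-R)/(L+R)$ on
  strictly positive pairs (Spearman correlation exactly 1) — the two
  agree where the traditional index works, and the angle remains
  well-behaved where it does not (values spanning zero).

Four trait *plans* are derived per pair: **I** signed $\theta$ on raw
values, **II** $= |\theta|$, **III** and **IV** the signed and absolute
angle on per-side z-standardized values $L_s, R_s$. The numbering
convention (signed/absolute crossed with raw/standardized) was a design
choice: the absolute forms II/IV capture asymmetry *magnitude* regardless
of direction, and the standardized forms III/IV remove betweeen-subject
location/scale differences of the two sides before measuring the angle.
Standardization uses the sample mean and SD of the analysis cohort, per
side and per phase, since different ancestry groups are normalized
separately. The pair (0, 0) has no direction and yields a missing value
rather than 0.

The expression-asymmetry statistic is the sine of the same angle,

$$AL = \frac{|L - R|}{\sqrt{2\,(L^2 + R^2)}} = |\sin \theta|,$$

bounded by $1/\sqrt{2}$ on nonnegative pairs and by 1 over real pairs
(attained at $L = -R$). Both bounds are asserted numerically, and the
identity $AL = |\sin\theta|$ is asserted to $10^{-10}$ over random pairs.

## Trait QC and normalization

Asymmetry traits are dropped when fewer than 1,000 subjects have a
non-missing value, or when the modal value accounts for more than 50% of
the non-missing values (a degenerate distribution that a quantitative
scan cannot use). Both rules are applied among non-missing values; the
alternative (counting missing subjects in the denominator of the
identical-value rule) would only make the filter laxer.

Normalization is a rank-based inverse-normal transform,
$\Phi^{-1}((r - 0.5)/n)$ with average ranks for ties — the transform an
automated normalization tournament almost always selects for continuous
biobank traits. A transform on heavily tied data is meaningless, so
`method = "auto"` falls back to plain z-scaling when more than 25% of the
values are tied at a single point; the 25% trigger is this package's own
operationalization of a "poor transformation".

# Synthetic cohorts: what they emulate and what they do not

The generators define the package's study conditions; their defaults are
fixed once and used throughout the tests.

* **Genotypes** (`sim_genotypes`): biallelic SNPs in LD blocks
  (default 10 SNPs, 1 kb spacing, 500 kb between blocks, up to 22
  chromosomes). Within a block, haplotypes follow a copying chain: each
  SNP copies the previous SNP's allele with probability `ld_decay`
  (default 0.9), otherwise draws fresh at the block's allele frequency.
  Block-constant MAF (uniform on (0.05, 0.5)) makes marginal frequencies
  exact, and adjacent-SNP correlation decays geometrically with distance,
  which is what radius-plus-r² clumping needs to be exercised honestly.
* **Phenotypes** (`sim_phenotypes`): L = base + common + A/2 + noise,
  R = base + common − A/2 + noise, where A is the signed asymmetry
  component carrying the genetic signal plus any asymmetric covariate
  effect. Per-allele effects are scaled so each causal SNP explains its
  configured fraction of var(L − R) after covariate adjustment; because
  the angle is locally linear in L − R near the diagonal (base level 10,
  unit noise), those fractions carry through to the derived trait. Age is
  uniform on [40, 69] (the cohort age range of the motivating biobank),
  sex Bernoulli(0.5), and the 20 PC-like columns standard normal.
* **Phases**: the discovery phase has 4,000 subjects; a
  different-ancestry replication phase perturbs each block's allele
  frequency on the logit scale (SD 0.3) and is smaller (1,200); a
  second-time-period phase redraws subjects and noise at 1,000. This
  reproduces the qualitative regime where same-ancestry replication is
  cleaner than cross-ancestry replication.
* **Expression tensors**: log2-normal with shared gene and organ effects;
  the planted effects are a log2 shift of focal genes in the human brain
  (`sim_species_expression`) and an opposite-sign log2 hemispheric
  perturbation of focal genes (`sim_region_expression`).

What the generators deliberately do **not** emulate: realistic phenotypic
covariance across brain regions, imputation dosage uncertainty,
population stratification beyond the per-phase frequency shift, X/MT
chromosomes, and real anatomical region ontologies. Passing recovery
tests therefore demonstrate the *procedures* are correct and calibrated,
not that the pipeline would reproduce any particular real-data result.

# Association model

The scan is ordinary least squares of the residualized, normalized trait
on each SNP dosage. A mixed model with a sparse genetic relatedness
matrix would be the field tool on real biobank data; on the synthetic
cohorts subjects are unrelated, where the mixed model reduces to exactly
this regression, so OLS is used as a stated simplification while the
sparse-GRM machinery (`compute_grm`, `sparsify_grm`, `prune_related`) is
implemented for the relatedness-pruning procedure itself. Hardy–Weinberg
filtering uses the 1-df chi-square on genotype counts rather than the
exact test — cheap, and on the scale of the 10⁻⁶ threshold the two
agree. LD r² is the squared Pearson correlation of dosages
(composite LD), since dosages are what the pipeline holds; missing
dosages use pairwise-complete subjects, with no imputation.

Clumping is greedy: the smallest-P unassigned SNP below 5×10⁻⁸ becomes
an index, absorbing unassigned SNPs below the member threshold within
250 kb (centre to centre) and r² ≥ 0.5; ties at equal P break by
(chromosome, position) ascending for determinism. The implementation is
checked against an independent brute-force re-scanning oracle on
hundreds of random instances.

Numerical conventions: monomorphic SNPs yield missing results rather
than errors; the inflation factor is median(χ²)/0.4549364; a
rank-deficient covariate design is an error that names the collinear
columns (silently dropping them would hide data problems).

# Enrichment procedures

Per-clade enrichment is the one-sided binomial tail
P(X ≥ k | n, p₀) with p₀ the clade's background proportion. One-sided
tails are used throughout (here, in the sign-concordance and
QTL-replication tests, and in the Wilcoxon comparisons) because every
hypothesis in this pipeline is directional — enrichment, excess
concordance, higher brain specificity; sidedness choices are asserted in
tests. Per-clade flags are unadjusted at α = 0.05, matching the
field's convention for these descriptive bar-panel tests.

The stepwise procedure addresses the non-independence of per-clade
tests: after selecting the most significant clade, its genes are removed
from both the focal set and the background, background proportions are
renormalized over the remaining clades, and the test repeats until
nothing reaches α. Ties in the minimum P select the more ancient clade
(deterministic). The loop terminates in at most one round per clade
because each selection strictly removes a clade.

`degenerate_tree` merges all clades strictly more ancient than a
boundary (default Tetrapoda) into one "ancient" stratum, preserving gene
counts — used to put trees of different ancient-clade resolution on a
common footing.

# Expression analyses

**BSI.** For a gene, species, and stage,
$BSI = \log_2(\bar x_{\mathrm{brain}} / \overline{\bar x_{\mathrm{other}}})$,
where each $\bar x$ is a replicate mean. In the cross-species test an
organ enters the denominator only if it is profiled and its replicate
mean exceeds the RPKM floor **in both species** — the strictest reading
of the common-organ rule, and the one that guarantees both species'
indexes are computed over the same organ set. Whether the floor should
also gate the brain itself is ambiguous; here the brain is always kept
when profiled, since a lowly expressed brain is itself informative
(strongly negative BSI). The floor is swept over 0.5/1/1.5 to show
robustness.

**Paired Wilcoxon.** The cross-species comparison is a one-tailed paired
signed-rank test across genes (the per-gene pairing over common organs
makes the paired test the coherent choice over a rank-sum across
organs). The package implements the signed-rank tail directly because
log-ratio differences are frequently tied in magnitude and the stock
implementation abandons exactness under ties: zeros are dropped
(Wilcoxon convention, with an all-zero comparison reporting P = 1 — no
evidence), average ranks are doubled to integers, and the exact null
distribution of the rank sum is built by dynamic programming up to 200
pairs (so n identical positive differences give exactly $2^{-n}$);
larger samples use the tie-corrected normal approximation with
continuity correction. The implementation is verified against
`stats::wilcox.test` where that is exact and against full sign
enumeration where it is not.

**AL analysis.** Expression is first normalized to relative abundance
(each donor × region × hemisphere × replicate sample divided by its
total over genes) — the package's recorded interpretation of a
"relative" low-expression mask — and relative values below 10⁻⁷ are
masked as missing. Replicate means per hemisphere precede the AL;
missing replicates are dropped, never zero-filled, and a hemisphere with
no surviving replicate makes the AL missing. Group tests are one-sided
rank-sum (focal > others), overall or per region with
Benjamini–Hochberg adjustment across regions. Cross-donor averaging
restricts to shared regions, reports the stacked (gene, region) Pearson
correlation, and by default falls back to the present donor when one
donor's value is missing (`strict_both = FALSE` is the recorded choice;
the strict variant is available).

# Study sizes used by the test suite

The quantitative test studies run at: parameter recovery — 5 causal SNPs
each explaining 1% of asymmetry variance, 4,000 subjects, 10⁴ SNPs, 50
seeds; null calibration — 2,000 subjects, 10⁴ SNPs; clumping oracle —
200 random instances of up to 50 SNPs; clade enrichment — focal sets of
200–400 genes over 5 clades, 100 seeds; BSI — 600 genes (500 focal), 6
species, 4 organs, 2 replicates, 100 seeds per threshold. These sizes
were chosen as the smallest at which the sampling bounds in the tests
are comfortably inside their thresholds.

At these conditions the per-SNP power to reach 5×10⁻⁸ with 1% explained
variance and n = 4,000 is about 0.82
($\Phi(\sqrt{nq^2/(1-q^2)} - \sqrt{\chi^2_{5\times10^{-8}}})$), so the
probability that *all five* planted QTLs are genome-wide significant in
one seed is only ≈ 0.35–0.5 even with the LD max-statistic gain; the
corresponding all-five recovery assertion in the acceptance suite
documents this gap rather than papering over it (the suite's measured
all-five rate is ~30%, while false-positive index SNPs are absent in
100% of seeds and null-scan λ stays within [0.95, 1.05]).

# Known limitations

* The OLS scan is not a mixed model; on cohorts with real relatedness
  the inflation factor would drift above 1.
* The copying-chain LD model produces block-local LD only; long-range LD
  and MAF-dependent LD structure are absent.
* The AL's theoretical range over real pairs is [0, 1], but on
  nonnegative expression data the attainable range is [0, 1/√2]; both
  facts are encoded as separate invariants rather than reconciled.
* Gene-age maps, DEG sets, and ortholog tables are consumed as given;
  building them is out of scope.
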