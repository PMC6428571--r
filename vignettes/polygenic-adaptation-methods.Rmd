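---
title: "Methods: polygenic adaptation tests, tSDS trends, and stratification diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic adaptation tests, tSDS trends, and stratification diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(polystrat)
```

# Scope

`polystrat` implements population-level tests of polygenic adaptation
(the Qx overdispersion statistic and a latitude-cline statistic under a
multivariate-normal drift null, with Beta-posterior credible intervals),
trait-aligned singleton-density-score (tSDS) trend analysis, LD-based SNP
ascertainment, and diagnostics that detect residual population
stratification in GWAS effect estimates. A seeded synthetic-data
generator ties the pieces together: it produces allele-frequency drift,
GWAS summary statistics with an optional stratification bias, SDS-like
scores with an optional frequency-cline confound and true-selection
component, and diploid genotype panels — all with recorded ground truth,
so the null calibration and the power mechanisms of every statistic can
be verified rather than assumed.

This vignette documents the model, the conventions the package fixes
where the literature is ambiguous, the numerical choices, and the
standard study conditions used by the test suite and by
`scripts/acceptance.R`.

# The drift null and the F convention

The population polygenic score is $Z_m = \sum_\ell \beta_\ell p_{\ell m}$
over $L$ ascertained SNPs. Scores are reported centered and standardized
as $(Z_m - \mu)/\sqrt{V_A}$ with $\mu = \sum_\ell \beta_\ell \bar p_\ell$
and $V_A = \sum_\ell \beta_\ell^2 \bar p_\ell (1 - \bar p_\ell)$, where
$\bar p_\ell$ is the **unweighted** mean frequency across the analyzed
populations. The unweighted mean is deliberate: sample sizes differ by
orders of magnitude between, say, ancient meta-populations and modern
sequencing panels, and a size-weighted mean would let one panel define
the centering.

Under neutral drift the mean-centered score vector is taken to be

$$Z \sim \mathrm{MVN}(0,\; 2\, V_A\, F).$$

For this null, the standardization of $V_A$, and the drift matrix to be
mutually consistent, **the package defines $F$ as the covariance of
allele-frequency deviations standardized by
$\sqrt{2\,\bar p(1-\bar p)}$** — half the expected heterozygosity, the
scale on which additive genetic variance is conventionally written. All
three places where $F$ appears use this one convention:

* `simulate_frequencies()` draws
  $p_{\ell\cdot} = \bar p_\ell + \varepsilon$,
  $\varepsilon \sim \mathrm{MVN}(0,\, 2\bar p_\ell(1-\bar p_\ell)F)$;
* `estimate_F()` averages
  $\mathrm{outer}(p_{\ell\cdot}-\bar p_\ell)/(2\bar p_\ell(1-\bar p_\ell))$
  over putatively neutral SNPs;
* `qx_test()` / `latitude_test()` use $2 V_A F$ verbatim.

With any other pairing of scalings the statistic is mis-calibrated by a
factor of two; the test suite checks calibration directly (mean Qx equal
to $M-1$ and uniform P values over replicates under the null).

**Centering of the F estimator.** With the default across-population
mean $\bar p_\ell$, only the centered projection $T F T'$
($T = I - \mathbf{1}\mathbf{1}'/M$) is identifiable — the projection is
exactly what `qx_test()` and `latitude_test()` consume, so this is
sufficient for inference. When known ancestral frequencies are available
(the simulator records them), passing them via `ancestral` makes the
full $F$ identifiable; the parameter-recovery tests use this mode. The
estimate is symmetrized and eigenvalue-clipped to the PSD cone, with the
clip magnitude reported.

**Degenerate geometry.** `qx_test()` inverts $2V_A\,TFT'$ by eigenvalue
pseudo-inversion on the rank-$(M-1)$ contrast space rather than dropping
one population: the result is basis-independent, and if the centered
drift matrix is numerically rank-deficient the degrees of freedom are
reduced to the numerical rank and flagged. `latitude_test()` refuses a
non-positive variance $Y'FY$ along the latitude contrast.

# Credible intervals

The posterior of the underlying frequency at each locus in each
population is $\mathrm{Beta}(1+x,\ 1+n-x)$ (Uniform prior updated with
$x$ effect alleles out of $n$ haploid observations). The score variance
$V_Z(m) = \sum_\ell \beta_\ell^2 \mathrm{Var}_{\mathrm{post}}(\ell, m)$
treats loci and populations as independent — no LD correction — and the
95% half-width is $1.96\sqrt{V_Z}$. Half-widths are reported in raw
trait units and also divided by $\sqrt{V_A}$, since plots of
standardized scores need the latter and the two conventions are easy to
confuse; both are labelled in the output.

# SNP ascertainment

Three strategies, matching standard practice:

* `lowest_p_per_block()` — one SNP per non-overlapping LD block, the one
  with the smallest P value. Block files are read as BED-like 0-based
  half-open intervals and converted to the package's 1-based inclusive
  representation at the boundary. Ties are broken by lowest position,
  then lexicographic id, making runs bit-reproducible.
* `clump()` — greedy P-value clumping: index SNPs in ascending P order
  below `p1` absorb unassigned SNPs below `p2` within `window` bp and
  with $r^2 \ge$ the threshold. The window is measured index-SNP to
  candidate (not clump extent). The defaults (`r2 = 0.1`,
  `window = 1e6`) correspond to the usual gw-sig/sub-sig regimes at
  `p1 = 5e-8` and `p1 = 0.01`.
* `prune()` — sliding-window removal so no retained pair within the
  window has $r^2$ at or above the threshold; the earlier-position SNP
  is always kept.

LD is **genotypic** $r^2$ — squared Pearson correlation of 0/1/2 allele
counts — because reference panels may be unphased; a monomorphic SNP has
undefined correlation and is treated as $r^2 = 0$ with a warning (nothing
can be clumped on it). Both `clump()` and `prune()` are verified against
naive brute-force reference implementations on hundreds of randomized
small instances in the test suite.

# Harmonization

`harmonize()` aligns effect estimates to the allele counted by a target
frequency table or panel: matching pairs are kept, swapped pairs negate
the effect and map $f \to 1-f$, strand-flipped pairs are resolved via
complements, and palindromic A/T and C/G SNPs are dropped — with no
strand information, frequency-based resolution would import exactly the
kind of differential error this package is designed to detect, so
dropping is the conservative default. All actions are tallied in a log
attribute, and harmonization is idempotent. Positions are 1-based
inclusive throughout (VCF convention).

# tSDS analysis

`normalize_sds()` z-scores raw SDS within each 1% derived-allele-
frequency bin (sample SD, $n-1$), after removing the MHC region. The
package fixes the MHC bounds at chr6:25–35 Mb — the region is
conventionally named but not given coordinates, and these bounds
comfortably cover the extended locus. A bin with a single SNP has no
defined SD; that SNP is dropped with a warning.

`align_tsds()` signs each score so positive means the trait-increasing
allele rose in frequency: the score keeps its sign when the derived
allele is the trait-increasing one, and is negated otherwise. Zero
effects and derived alleles matching neither GWAS allele are dropped and
tallied.

`trend()` reports the Spearman correlation between the score and the
ranks of $-P$, so that **positive means selection-like** (higher scores
at stronger associations); this orientation is fixed and documented
because "correlation with P values" is sign-ambiguous. Standard errors
and P values come from a delete-one-block jackknife over contiguous
blocks in genomic order (default $B = 100$, i.e. leaving out 1% of SNPs
at a time), which is robust to local LD; on singleton blocks it reduces
exactly to the classical SE of the mean, a property the tests assert.
An un-binned least-squares slope on the significance-rank scale with its
analytic P value, and binned means (default 1000 SNPs per bin, smaller
final bin flagged), are also returned. The same function runs the
two-population frequency-contrast probe — pass the `DELTA` column of
`freq_contrast()` as the score.

`gw_sig_shift()` tests the mean tSDS of an LD-independent genome-wide-
significant set against the N(0, 1/n) null.

# Stratification diagnostics

`compute_pcs()` performs PCA of the individuals-by-SNPs matrix of
centered allele counts after a MAF floor (default 5%), optional
exclusion intervals, and optional $r^2$ pruning; counts are scaled by
$1/\sqrt{2p(1-p)}$ by default (unit variance under Hardy–Weinberg,
toggleable, since external tools differ silently on this point). Missing
genotypes are mean-imputed here — and only here, never in frequency
computation. `pc_loadings()` obtains per-SNP loadings as the
allele-count coefficient in a regression of the PC score on (intercept,
sex, count), which extends loadings to SNPs outside the PCA input set.
`loading_correlations()` correlates any per-SNP vector (effect sizes,
SDS) with the loadings, with jackknife errors over $B = 1000$ contiguous
genomic blocks and two flags: nominal ($P<0.05$) and Bonferroni for 20
PCs ($P < 0.0025$). `maf_bin_heatmap()` bins a per-SNP quantity on
minor-allele frequency in two populations (0.05-wide bins) and masks
cells with fewer than 300 SNPs, so sparsely-populated corners cannot
masquerade as signal.

# The synthetic generator: what it emulates, and what it does not

The generator reproduces the statistical structure the analyses assume,
not the biology underneath:

* **Drift** is exactly the MVN model of the Qx null (plus clipping to
  [0.001, 0.999]), not a Balding–Nichols or coalescent model — by
  design, so calibration tests are clean and a calibration failure
  indicts the statistic, not the generator.
* **GWAS effects** are $\hat\beta_\ell = \beta_\ell + a\,\delta_\ell +
  \mathcal{N}(0, se^2)$ with $\delta_\ell$ the frequency contrast along
  a chosen population axis: the mechanism by which an uncorrected GWAS
  assigns spurious effects to differentiated alleles. P values are
  normal-theory from $z = \hat\beta/se$; no genomic control is applied.
* **SDS-like scores** carry a cline term $c\,\delta_\ell$ (the confound
  that arises when the sequencing panel is itself structured), a
  true-selection shift $s$ on selected SNPs oriented along the true
  effect sign, and unit-scale noise. The derived allele is defined to be
  the effect allele; real SDS files need not satisfy this, which is why
  `align_tsds()` does its own allele matching.
* **Genotype panels** draw diploid counts Binomial(2, p), optionally
  with a block-latent-variable LD scheme (consecutive SNPs share a
  latent haplotype indicator with stated correlation) — sufficient to
  exercise clumping and pruning, with no pretense of realistic
  recombination.

Consequently, passing tests demonstrate the *statistical mechanisms* —
calibration under the assumed null, inflation under stratification, the
dissociation between confound-driven and selection-driven tSDS signals —
not robustness to demographic histories that violate the MVN
approximation, to realistic LD, or to ascertainment schemes entangled
with selection itself.

# Standard study conditions

The test suite and `scripts/acceptance.R` run the stack under one set of
conditions, chosen to be realistic for a European-transect analysis and
fixed in advance:

* Six populations, drift matrix $F = 0.02 I + 0.01$ (within-continent
  scale), latitudes 40–65°; ancestral frequencies U(0.05, 0.95);
  $L = 1000$ ascertained SNPs per replicate.
* True effects $\beta \sim \mathcal{N}(0, 0.02^2)$ trait units per
  allele, GWAS standard error $se = 0.01$ — a well-powered
  meta-analysis-scale study.
* The stratification coefficient is set so that
  $E|a\,\delta| = se$: the systematic error has the same magnitude as
  the sampling error, the regime where a confounded GWAS looks clean
  marginally. The coefficient is computed analytically from the drift
  scale ($E|a\delta| = a\,\sigma_\delta\sqrt{2/\pi}$ with
  $\sigma_\delta^2 = 2\,E[\bar p(1-\bar p)]\,\mathrm{axis}'F\,
  \mathrm{axis}$), not fitted.
* The SDS cline coefficient makes the cline explain ~20% of raw score
  variance (cline SD 0.5 against unit noise); the true-selection shift
  is 0.3 normalized-score units at 300 selected loci.
* Monte-Carlo sizes: 300 replicates for null calibration, 100 for power
  curves, 100 for the tSDS contrast at $L = 5000$ SNPs, 50 for the
  selection-shift check, 2000 population-scores for credible-interval
  coverage at $n = 50$ haploids, 20 replicates per arm for the
  PC-loading diagnostic, and $L = 50000$ null SNPs for drift-matrix
  recovery.
* Drift-matrix recovery is evaluated with ancestral frequencies
  U(0.25, 0.75): at rare ancestral frequencies the documented
  [0.001, 0.999] clipping censors a non-negligible tail of the drift
  distribution and biases *any* moment-based estimator downward, so the
  recovery check is run where clipping mass is below 1% and the result
  reflects the estimator, not the censoring.

# Known limitations

* The Qx null conditions on the ascertained SNPs and their effect sizes;
  ascertainment schemes correlated with drift (e.g. frequency-dependent
  power) are only partly covered by the random-ascertainment empirical
  null (`empirical_qx_null()`).
* Credible intervals ignore LD between loci, as is standard; they are
  sampling intervals for the score given frequencies, not posterior
  intervals on selection.
* The jackknife assumes contiguous genomic blocks break dependence;
  with only a few hundred SNPs the normal approximation to the
  jackknife P value is rough.
* INDELs, liftover, imputation and multi-trait extensions are out of
  scope; SDS itself is consumed pre-computed, never estimated from
  sequence data.
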