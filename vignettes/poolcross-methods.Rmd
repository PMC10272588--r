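---
title: "Defining heterotic pools and predicting single crosses from SNP data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defining heterotic pools and predicting single crosses from SNP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolcross)
```

## The problem

Hybrid breeding rests on heterotic pools: sets of inbred lines that show
little heterosis when crossed among themselves and strong heterosis when
crossed to the opposite pool. Established crops inherited their pools from
decades of reciprocal selection; a breeding program starting from a diverse,
unstructured panel — an orphan crop, or a new germplasm pool — has to
*construct* them. `poolcross` implements a marker-based route: genotype the
candidate parents on whatever SNP platform is available, phenotype an
(incomplete) diallel of single crosses in multi-environment trials, fit a
genomic combining-ability model, read the heterotic groups off the
specific-combining-ability surface, elect a tester per group, and predict
every untested inter-group cross with an additive–dominance GBLUP model. A
synthetic-data generator reproduces the statistical shape of this scenario
end to end, so every claim the package makes is testable without external
data.

Because different genotyping platforms (fixed arrays, genotyping-by-
sequencing against a true or an ad-hoc reference) deliver marker sets of
different density and ascertainment, the pipeline runs per platform and
reports cross-platform concordance: Mantel correlation of Rogers distance
matrices, Kendall agreement of cluster memberships, eigenvector R²
grids, heterotic-partition correlation and tester coincidence.

## Models

### Stage 1: adjusted means from augmented-block trials

Plot values are modelled as

$$y = Q\ell + Sb + Tc + Ug + Vi + \varepsilon,$$

with fixed environments $\ell$, random blocks within environments
$b \sim N(0, I\sigma^2_b)$, fixed checks $c$, fixed single-cross effects
$g$, fixed check-by-environment interactions $i$, and residuals with an
independent variance per environment. Entries are *fixed* at this stage so
the stage-2 genomic models receive unshrunken BLUEs. Environment effects use
sum-to-zero contrasts, so each entry's coefficient is its adjusted mean in
the average environment.

A full unstructured residual covariance across environments would require an
environment-as-trait multivariate formulation; since every plot belongs to
exactly one environment, independent per-environment variances capture the
heteroscedasticity that matters here (contrasting trial conditions), and a
homogeneous-residual mode is available for comparison
(`stage1_blues(..., homogeneous = TRUE)`).

### Stage 2a: the GCA/SCA genomic diallel

Adjusted means of the observed crosses follow

$$y = 1\mu + Z_P g_P + Z_H h + \varepsilon,$$

where $g_P \sim N(0, \sigma^2_P G_P)$ holds the general combining abilities
of the parents, $h \sim N(0, \sigma^2_H H)$ the specific combining abilities
of the crosses, and $Z_P$ adds the two parental incidences of each cross.
$G_P = W_P W_P' / p$ is built from column-centred *and standardised* parental
markers — the reading of "centred and patterned" that yields the expected
average diagonal of about 1, putting $\sigma^2_P$ on the residual scale. The
SCA kernel derives from the Kronecker product $G_P \otimes G_P$ restricted
to the crosses; because crosses are unordered pairs we symmetrise over
parent order,
$H_{(ij),(kl)} = \tfrac12 (G_{ik}G_{jl} + G_{il}G_{jk})$,
with the plain Kronecker subset available behind
`sca_kernel(..., symmetrize = FALSE)`.

### Heterotic groups and testers

High SCA between two parents indicates complementary allele frequencies at
loci with dominance — the raw material of heterosis. The completed SCA
surface (observed BLUPs plus kernel-based predictions for the unobserved
pairs, zero diagonal) is therefore treated as a genetic-distance-like
matrix: k-means on its rows (k = 2 by default) yields the heterotic
partition. Unobserved cells are filled by model prediction rather than a
constant because the fitted kernel defines them naturally and k-means needs
complete rows; rows are not rescaled since all entries share trait units.

The tester of a group is the line with the highest *mean predicted
inter-group cross value* $\hat g_i + \hat g_j + \hat s_{ij}$ averaged over
the opposite group — the operational reading of "highest GCA with the other
group" that uses all fitted information; a pure-GCA ranking is available via
`choose_testers(..., rule = "gca")`. Ties break to the lexicographically
first parent id, making elections deterministic.

### Stage 2b: additive–dominance GBLUP

For the NCII (inter-group) crosses,

$$y = 1\mu + Za + Zd + \varepsilon, \qquad
a \sim N(0, G_a\sigma^2_a),\; d \sim N(0, G_d\sigma^2_d),$$

with hybrid marker codes built in silico from the homozygous parents:
$W_A = (g_{\text{mother}} + g_{\text{father}})/2 \in \{0,1,2\}$ and
$W_D = 1$ exactly where the parents differ (the hybrid is heterozygous).
$G_a$ centres $W_A$ by $2p_i$ and scales by $2\sum p_i(1-p_i)$;
$G_d$ centres $W_D$ by $2p_i(1-p_i)$ and scales by
$4\sum (p_i(1-p_i))^2$, with allele frequencies taken from the modelled
cross population itself. The dominance columns are centred even though the
raw 0/1 coding is sometimes printed uncentred: without centring the kernels
lose the row-sum-zero property and the variance-component interpretation; a
strict uncentred mode exists (`dominance_G(..., strict_uncentered = TRUE)`)
but is untested against any external value.

Heritabilities are
$H^2 = (\hat\sigma^2_a + \hat\sigma^2_d) / (\hat\sigma^2_a + \hat\sigma^2_d + \hat\sigma^2_\varepsilon)$
and
$h^2 = \hat\sigma^2_a / (\hat\sigma^2_a + \hat\sigma^2_d + \hat\sigma^2_\varepsilon)$.
Model validation uses replicated random k-fold cross-validation on crosses
(5 folds × 4 replicates by default; fold sizes differ by at most one; no
stratification by parent, so the usual caveat applies that parents of
validation crosses are seen in training). Predictive ability is the Pearson
correlation between predicted and observed adjusted means, pooled per
replicate after collecting all five validation folds (per-fold values are
also reported). Accuracy divides predictive ability by $\sqrt{H^2}$,
clamped to $[-1, 1]$ — the standard operationalisation of scaling
predictive ability by heritability. Selection coincidence compares the top
$\lceil sn/100 \rceil$ crosses by adjusted mean and by GEBV at intensities
$s \in \{1, 10, 20, 30, 40\}\%$, with the direction of selection
configurable per trait.

### The REML engine

All variance components are estimated by a single multi-kernel REML engine
(`reml_fit()`): EM fixed-point updates accelerated by average-information
steps, where any AI step that would decrease the restricted likelihood or
cross the variance floor ($10^{-8}$) is step-halved and ultimately replaced
by the (ascent-guaranteed) EM move — so the log-likelihood trajectory is
non-decreasing by construction, which the test suite asserts on every
iteration. Convergence is declared on a log-likelihood change below
$10^{-8}$; initial values split the phenotypic variance equally among
components, making the optimiser deterministic and seed-free. Kernel
inverses downstream (BLUP prediction of new levels, SCA completion) are
ridge-stabilised with $10^{-6} I$.

## The synthetic world

The generator's defaults state one scenario, chosen once: 330 inbred lines
in 6 subpopulations (the shape of a tropical maize diversity panel), a
45-parent diallel with 751 of 990 crosses realised, three marker panels of
differing density and ascertainment, and 8 environments of augmented blocks
with 16 entries and 2 replicated checks each.

* **Population structure** follows a Balding–Nichols-style hierarchical
  Beta model: ancestral frequencies Uniform(0.1, 0.9) (avoiding near-fixed
  markers), subpopulation frequencies Beta-distributed around them with a
  single $F_{st}$-like `divergence` knob, default 0.15 — moderate
  differentiation typical of breeding germplasm split by origin.
  Monomorphic markers are redrawn; lines are fully homozygous.
* **Platform views** subsample markers uniformly (`"random"`) or
  proportionally to the minor-allele frequency in a reference subset of
  lines (`"biased"`, array-like ascertainment), then inject missingness
  completely at random. Genotyping error is exposed as an optional
  homozygote-flip rate but defaults to 0, since no error model is stated
  for the emulated platforms.
* **Genetic effects.** Additive marker effects are i.i.d. normal draws
  rescaled so the realized additive variance over the design's hybrids
  equals `var_additive` exactly. Dominance effects are calibrated on the
  *model scale* — their implied covariance is `var_dominance * Gd` —
  because the 0/1 heterozygosity coding with the
  $4\sum(p_iq_i)^2$ denominator makes the mean diagonal of $G_d$ about 1.4
  at intermediate frequencies, so realized-variance calibration and
  variance-component recovery cannot both hold; recovery is only well
  defined on the model scale. (For the additive kernel the two scales
  coincide, since the mean diagonal of $G_a$ is ~1.)
* **Directional dominance.** By default dominance effects are half-normal
  (all positive). This is a substantive modelling decision, not a
  convenience: with zero-mean dominance effects the expected SCA difference
  between inter- and intra-pool crosses is zero — only its *variance*
  differs — so even the true SCA surface separates pools unreliably.
  Heterosis as a directional phenomenon (hybrid superiority) requires
  dominance effects of predominantly one sign, and SCA-based heterotic
  grouping presupposes it. Experiments that measure variance-component
  recovery instead use `directional_dominance = FALSE`, the regime matching
  the zero-mean prior of the GBLUP estimator; under the directional regime
  the heterosis mean-shift is (correctly) absorbed into the dominance
  variance and no estimator could return the nominal input triple.
* **Trials.** Plot values add an environment main effect, a block effect,
  and a residual whose variance is per-environment (`var_residual` scaled
  by a Uniform(0.5, 1.5) factor). Entries appear once per environment; the
  last block may be short; checks are not genotyped and carry fixed true
  values spaced around the hybrid mean.

What a green test on this world does *not* establish: linkage
disequilibrium and recombination maps (markers are independent), epistasis,
genotype-by-environment interaction beyond additive environment shifts,
genotyping error structure, or any real-data result. Real marker counts,
Mantel correlations and predictive abilities depend on raw sequence data
and are outside the package's scope.

## Numerical and QC conventions

* Dosages count the alternate (second-listed) allele; files are 1-based,
  internal indices follow R. Multi-allelic VCF records are flagged and
  removed by the biallelic filter; genotypes carrying a third allele are
  unresolvable as biallelic dosages and become missing.
* The parent-panel cascade runs call-rate filter (call rate ≥ 90% kept —
  markers *below* 90% are removed, so the boundary survives), biallelic
  filter, per-marker mode imputation (ties to the lower dosage; the
  haplotype-based imputation a sequencing pipeline would use is deliberately
  replaced by this dependency-free rule, defensible for inbred panels with
  low missingness), and LD pruning: markers are scanned in input order and
  dropped when their squared allele-frequency correlation with an already
  kept marker on the same chromosome exceeds 0.99 (all pairs globally when
  no coordinates are present). The keep-first rule and the
  chromosome restriction are explicit choices where the convention is
  ambiguous.
* The hybrid-panel cascade removes markers heterozygous in any parent,
  duplicated marker content across chromosomes (keep first), and markers
  with MAF < 0.05 in the derived single-cross matrix (the boundary 0.05
  survives). Structure analyses use the parent-panel output — keeping
  heterozygous and rare variants to capture all diversity — while kernels
  for prediction use the hybrid-panel output; the pipeline keeps both
  branches.
* PCoA (classical scaling of Rogers distances) truncates negative
  eigenvalues to zero for explained-variance normalisation. Whether to
  compute principal axes from the genotype matrix or the distance matrix is
  genuinely ambiguous in practice; the distance route is the default and
  both are reachable through the API.
* K-means uses `stats::kmeans` with 100 random restarts; the number of
  clusters comes from the largest second difference of the WSS curve
  (overridable). Structure clustering runs on the first 3 principal
  coordinates by default (`n_coords`).
* Kendall agreement between partitions first aligns labels by the
  assignment maximising the contingency diagonal (exhaustive up to 7
  groups), then computes tau-b with the large-sample p-value; partition
  correlation for two-group partitions is the phi coefficient after
  identity-or-swap alignment.
* Permutation p-values (Mantel) use the add-one estimator
  $(1 + \#\{r^\ast \ge r\}) / (n_{\text{perm}} + 1)$, so $p > 0$ always and
  the resolution is $1/(n_{\text{perm}}+1)$.
* The master seed fans out to per-stage seeds by a fixed affine map
  (`seed * 101 + offset`, modulo a prime below $2^{31}$), so any stage can
  be reproduced in isolation.

## Known limitations

Tester election is an exact-argmax decision among all candidates of a
group; when the margin between the best and second-best line's true mean
inter-group cross value is comparable to the noise of a per-line score
averaged over a dozen observed crosses, no election rule — genomic or
phenotypic — identifies the single best line reliably, and the recovery
tests show the model-based rule only slightly ahead of the best phenotypic
one. Marker independence in the generator means LD-based properties cannot
be studied; the diallel engine fits homogeneous residuals for adjusted means
(heterogeneity belongs to stage 1); no reciprocal or maternal effects; NCII
enumeration supports exactly two groups; CV is not stratified by parent, so
predictive abilities are "T2-style" (both parents seen in training) and
will exceed what untested-parent prediction would achieve.
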