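---
title: "Decomposing DNA methylation variance in twin families: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing DNA methylation variance in twin families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methvc)
```

## The scientific problem

At a single CpG site, methylation levels vary between people. Three
classical designs quantify where that variation comes from:

1. **Twin comparisons.** Monozygotic (MZ) co-twins share their whole
   genome; dizygotic (DZ) co-twins share on average half of it additively
   (a quarter for dominance deviations). If genetics matters at a site,
   MZ co-twins resemble each other more than DZ co-twins do.
2. **Genome-wide SNP data.** Even nominally unrelated people share small,
   measurable fractions of their genomes. Relating phenotypic similarity
   to this measured genetic similarity estimates how much variance the
   genotyped SNPs *tag* — which can be much less than the total genetic
   variance if rare or structural variants matter.
3. **Moderation.** The balance of genetic and environmental variance need
   not be constant: environmental variance can accumulate with age
   (epigenetic drift), and variance components can differ by sex.

`methvc` implements all three per site, plus the preprocessing,
annotation and summary machinery around them, and ships a synthetic
twin-family generator with known ground truth so that every estimator is
validated by parameter recovery.

## Models

### Classical twin models

For complete twin pairs, the pair vector `(y1, y2)` is modelled as
bivariate normal with a common mean and total variance across zygosity
groups. Expected co-twin covariances are

* ACE: MZ `a² + c²`, DZ `a²/2 + c²`
* ADE: MZ `a² + d²`, DZ `a²/2 + d²/4`

with `a²` (additive genetic), `c²` (common environment), `d²`
(dominance) and `e²` (unique environment, including measurement error)
expressed as proportions of total variance. Components are kept
non-negative by a softplus reparameterization and estimated by
quasi-Newton maximum likelihood with three random restarts beyond a
moment-based start. Component significance is assessed by likelihood-
ratio tests between nested models (A: AE vs E; C: ACE vs AE; D: ADE vs
AE). P-values use the standard χ² reference; at the `c² = 0` / `d² = 0`
boundaries this is conservative (the correct reference is a χ² mixture),
which we accept and verify empirically: under a true AE model the LRT for
C rejects at or below the nominal rate.

The Falconer moment estimate `h² = 2(rMZ − rDZ)` is reported unclamped
with an out-of-range flag, as a fast first impression.

### The two-GRM mixed model

The genotyped-SNP relationship matrix (GRM) is the standardized-genotype
estimator over SNPs with MAF > 0.01,
`A_jk = (1/N) Σ_i (x_ij − 2p_i)(x_ik − 2p_i) / (2 p_i (1 − p_i))`,
with allele frequencies estimated in the full sample (a founder-only
option is exposed). A second matrix zeroes all entries strictly below
0.05, so that what remains approximates the proportion of the genome
shared identity-by-descent among close relatives. The per-site model for
the standardized, covariate-adjusted values is

```
V = A_IBS · σ²_SNP + A_IBD · σ²_(A−SNP) + I · σ²_e
```

with a free intercept. Because the IBD-like matrix carries the *extra*
resemblance of close relatives beyond what SNPs tag, `σ²_(A−SNP)` is the
untagged additive genetic variance, and

```
h²_IBD  = (σ²_SNP + σ²_(A−SNP)) / (σ²_SNP + σ²_(A−SNP) + σ²_e)
h²_SNPs =  σ²_SNP               / (σ²_SNP + σ²_(A−SNP) + σ²_e)
```

so `h²_SNPs ≤ h²_IBD` by construction. The ratio `h²_SNPs / h²_IBD` (the
share of heritability tagged by SNPs) is reported only when
`h²_IBD ≥ 1e-6`.

Estimation is maximum likelihood on log-scale variances (quasi-Newton
with analytic gradients; REML available via a flag — the recovery
surfaces here are insensitive to the choice). The likelihood factorises
over connected components of the combined kernel sparsity pattern, so
pedigree-structured kernels evaluate per family in linear time; dense
kernels use one Cholesky factorisation per evaluation (O(n³), fine for
cohorts up to a few thousand samples). Standard errors come from the
numerically evaluated observed information on the variance scale. A
non-positive-definite observed information at the optimum (e.g. when the
two kernels coincide and the split is unidentified) flags the fit as a
boundary case. Sites whose fit fails are kept in the catalogue with a
status column rather than silently dropped.

### Variance-moderation models

For a moderator `m` (sex coded 0/1, or age z-scored on the analysis
sample's own mean and s.d., which are stored so that heritability can be
evaluated at chosen ages later), the covariance is

```
V_ij = A_ij (σ_a + β_g m_i)(σ_a + β_g m_j) + δ_ij (σ_e + β_e m_i)²
```

Each slope is tested with a Wald χ² = (β/s.e.)² on 1 df — the exact form
of the test, rather than an LRT. The likelihood is invariant to jointly
flipping the sign of (σ_a, β_g) or of (σ_e, β_e); fits are reported with
both baseline σ's non-negative. Standard errors use a central-difference
Hessian with step 1e-4 on the parameter scale; a singular Hessian flags
the fit. Heritability trajectories are
`Va(m) = (σ_a + β_g m)²`, `Ve(m) = (σ_e + β_e m)²`,
`h²(m) = Va/(Va + Ve)`, reported by default at ages 25 and 50 (converted
through the stored z-scoring) or at sex 0/1.

The model uses a single total-genetic component: moderation results
concern total genetic versus environmental variance, not the SNP/pedigree
split. Which relatedness matrix carries that component is a
configuration choice. The pipeline default is the pedigree-expected
matrix: with a modest SNP panel the thresholded GRM is a noisy IBD
estimate (at 500 SNPs, sampling noise alone pushes over a tenth of
between-family entries past the 0.05 cutoff), whereas the pedigree
expectation is exact for the simulated families and keeps the model
block-diagonal, hence fast. With dense genotyping the two coincide and
`moderation_grm = "ibd"` selects the SNP-based matrix. Whether a residual
SNP-variance term should remain inside the interaction model is left as
a sensitivity analysis rather than assumed; the implementation omits it.

## Preprocessing rules

* β from intensities: `β = M / (M + U + α)` with offset α = 100, so β
  never reaches 0 or 1 on real arrays. `M = log2(β/(1−β))` and its exact
  inverse; synthetic or rounded β at the endpoints are clamped to
  `[1e-6, 1 − 1e-6]` with a warning before the transform.
* Probe filters, in order: global blacklists (ambiguous mapping, SNP at
  the interrogated CpG); per-cell failures set missing (detection
  p > 0.01, bead count < 3, zero intensity); probes with success rate
  < 0.95 across samples dropped last. Per-sample success rates and
  removal counts by reason are reported.
* Contamination: of 65 SNP control probes, an allele-signal proportion in
  [0.2, 0.4] or [0.6, 0.8] (closed intervals — the conservative reading,
  configurable) is an unclear genotype; ≥ 15 unclear genotypes flags the
  sample.
* Imputation: site-mean by default (deterministic); a k-nearest-sites
  imputer (k = 10) is available for the nearest-neighbour behaviour of
  standard array pipelines.
* Residualization: per-site OLS on sex, age, array row, plate (dummy
  coded), white-blood-cell percentages, and — for analyses that use SNP
  data — the first ten genotype PCs, computed as eigenvectors of the IBS
  GRM. Residuals are z-standardized before the mixed models.
* Covariate association tests use family-clustered sandwich standard
  errors (robust z), the working-independence GEE form; with singleton
  families this reduces to heteroskedasticity-robust OLS.

## The synthetic generator

Each site is the sum of five components with specified variance
fractions at moderator value zero (summing to 1): a SNP-tagged additive
score (a weighted sum of `n_causal` genotyped SNPs, rescaled so its
realized variance equals the requested fraction exactly — ground truth
for recovery tests, not an approximation), an untagged polygenic deviate
drawn from the *expected* additive relatedness (MZ 1, DZ/sib and
parent-offspring 0.5), a family-shared common-environment deviate, a
dominance deviate (correlation 1 in MZ, 0.25 in DZ/sib — the standard
coefficient), and an independent unique-environment deviate. Moderation
multiplies the polygenic and environmental standard deviations by
`(σ + β m)/σ`; configurations whose moderated s.d. crosses zero over the
sampled moderator range are rejected. Genotypes are gene-dropped: founders
under Hardy–Weinberg at MAFs drawn from the configured range, offspring
inheriting one allele per parent, MZ co-twins genotypically identical.

Defaults emulate an adult twin cohort: age mean 37.2, s.d. 13.3, range
17–79 years, two-thirds female, and 0.1% missing methylation cells. The
`desk` preset (200 MZ + 200 DZ pairs, 500 SNPs, 50 sites) keeps a full
pipeline run in minutes; recovery experiments for the two-GRM model use
2,000 SNPs, where the GRM's per-entry sampling noise is small enough for
the component split to be well estimated.

What the generator does **not** emulate: linkage disequilibrium,
array-intensity-level artefacts, batch structure beyond categorical
covariates, or non-normal site distributions. Passing recovery tests
therefore demonstrates correctness of the estimators under the stated
model, not robustness to every feature of real arrays.

## Numerical choices and scale

Twin likelihoods are closed-form over 2×2 pair covariances and vectorised
over pairs; fits take milliseconds. Two-GRM fits at n = 800 with dense
kernels take ~3 s per site (a few dozen Cholesky factorisations);
pedigree-structured fits are ~20× faster through the family-block path.
Validation runs use 50–60 replicate sites per recovery experiment and
400 replicate sites for the Wald-size calibration; at 400 twin pairs the
per-site sampling s.d. of a twin-model component is ~0.15, so recovery
is asserted on the bias of component means (the per-site noise floor is
a property of the design, not the estimator). Thresholded GRMs estimated
from few SNPs are mildly indefinite (thresholding keeps only positive
sampling noise); inputs are accepted unless grossly indefinite, and every
likelihood evaluation is guarded by its Cholesky factorisation.

## Annotation conventions

Coordinates are 1-based inclusive; BED input is converted on read. Sites
take the region of their *nearest TSS*, windows oriented by strand:
proximal promoter (−1.5 kb to +500 bp), distal promoter (−10 kb to
−1.5 kb), gene body (+500 bp to the 3′ end), downstream (3′ end + 5 kb),
otherwise intergenic. Boundary positions belong to the more
promoter-proximal class; equidistant TSS ties break by smaller gene id.
CGI classes: island, shore (≤ 2 kb from an island edge), shelf (2–4 kb),
non-CGI; the CpG-island sequence test requires GC > 50%, length > 200 bp
and observed/expected CpG > 0.6, all strict, with expected
`(#C × #G)/length`. Enrichment uses Pearson χ² without continuity
correction (a flag restores it) and Bonferroni control across the family
of tests (default 117). Category thresholds: variable sites
`sd(β) > 0.03` (strict), high/low heritability `h² ≥ 0.5` / `h² < 0.2`,
longitudinal stability `r ≥ 0.5` / `r < 0.2`.

## Known limitations

* Boundary p-values (twin LRTs) are conservative; no χ² mixture
  correction is applied.
* The moderation model omits a separate SNP-variance term; sex-limitation
  and bivariate twin models, mQTL mapping, LD-aware simulation and raw
  idat processing are out of scope.
* Equal total variance across zygosity groups is assumed in twin models;
  zygosity-specific variances are not estimated.
* The two-GRM split degrades gracefully but noticeably as the SNP panel
  shrinks; with a few hundred SNPs the thresholded GRM is a poor IBD
  proxy and the pedigree matrix should be preferred where available.
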