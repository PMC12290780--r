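---
title: "Methods: vertex-wise SC-FC coupling and its genetic architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vertex-wise SC-FC coupling and its genetic architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The phenotype: coupling between structural and functional connectivity

Structural connectivity (SC, white-matter connection strength from
diffusion tractography) and functional connectivity (FC, correlation of
BOLD time series) can both be represented on the white surface — the
interface between cortical gray and white matter — as vertex × vertex
matrices. At a vertex $x_0$, the local SC profile $f_1(y) = \ell_{SC}(x_0, y)$
and FC profile $f_2(y) = \ell_{FC}(x_0, y)$ describe how that location
connects to the rest of the cortex. Their similarity over a local region
$E$ is measured by the normalized inner product

$$\mathrm{SFC}(x_0) \;=\;
  \Big\langle \tfrac{f_1}{\|f_1\|},\; \tfrac{f_2}{\|f_2\|} \Big\rangle_E
  \;\in\; [-1, 1],$$

which is $1$ when the profiles are proportional, $0$ when orthogonal and
$-1$ when opposite. `compute_coupling()` implements this with:

* $E$ = the unmasked vertices sharing $x_0$'s functional network *on
  $x_0$'s hemisphere*. Hemispheres are processed as separate meshes
  upstream, so a network patch never spans the midline.
* $x_0$ excluded from its own $E$. Including it would let the unit FC
  diagonal dominate the product at every vertex; exclusion makes the
  statistic a property of the off-diagonal profile.
* SC log-transformed as $\log(1 + SC)$ (offset configurable via
  `log_offset`). Streamline-derived SC is heavy-tailed and contains exact
  zeros; the unit offset keeps zeros finite and the profile non-negative.
* uniform vertex weights in the discretized inner product. The
  downsampled meshes the method targets are approximately uniform, so
  area weighting is omitted; the discrete sum is then the natural
  quadrature.
* Pearson and Spearman profile correlations as alternative couplings
  (`method = "pearson"/"spearman"`), with average ranks for Spearman
  ties.

A vertex whose restricted SC or FC profile has zero norm has no defined
coupling; it is reported as `NA` with a warning rather than silently
imputed.

`smooth_sc()` provides the kernel smoothing step used upstream of coupling
for sparse SC: rows are convolved with a Gaussian kernel over inter-vertex
Euclidean distance, kernel weights normalized per target vertex, and
symmetry restored by averaging with the transpose. Below the minimum
vertex spacing the kernel degenerates to the identity, which the tests
exploit as a limit check.

## Variance components: heritability, genetic correlation, repeated scans

The central estimator is single-component GREML: for trait $y$ with fixed
effects $X\beta$,

$$y = X\beta + u + e, \qquad u \sim N(0, K\sigma_g^2),
  \quad e \sim N(0, I\sigma_e^2),$$

so $\mathrm{cov}(y) = K h^2 + I (1 - h^2)$ after standardization, with
$h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)$. $K$ is either the SNP-based
genetic relationship matrix (`compute_grm()`, the standard
standardized-dosage estimator with pairwise-complete SNP counts) or the
pedigree expectation (`pedigree_grm()`: 1 for MZ twins, 1/2 for DZ twins
and full siblings, 0 otherwise).

`greml()` maximizes the restricted likelihood by average-information (AI)
REML. Numerical choices:

* the univariate model is rotated onto the eigenbasis of $K$ once, making
  every iteration $O(np^2)$; `grm_eigen()` lets callers amortize the
  decomposition across thousands of traits or replicates;
* initialization $\sigma_g^2 = \sigma_e^2 = \tfrac12 \mathrm{var}(y)$;
  convergence when the restricted log-likelihood moves less than $10^{-8}$
  and parameters less than $10^{-8}$ (relative); at most 100 iterations;
* variances floored at $10^{-6}\,\mathrm{var}(y)$; an AI step that fails
  to increase the likelihood is step-halved, then retried along the
  gradient; if no uphill move exists the current point is accepted;
* the SE of $h^2$ comes from the delta method on the inverse AI matrix;
* the test of $\sigma_g^2 = 0$ is a likelihood-ratio test against the
  closed-form null REML, referred to the boundary mixture
  $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ (a Wald test is anti-conservative
  at a boundary parameter).

The standard covariate set for the heritability and association models is
age, age², sex, age×sex, age²×sex, handedness, total brain volume and the
top 10 genetic PCs (`covariate_design()`, `genetic_pcs()`).

`reml_bivariate()` stacks two traits with genetic and residual covariance
components; $r_g = \sigma_{g12} / \sqrt{\sigma_{g1}^2 \sigma_{g2}^2}$,
constrained to $[-1, 1]$ by clamping the covariance inside the cone of
positive-definite structures (factor 0.9999, so collinear traits report
$r_g \approx 1$ rather than a singular fit). Its p-value is a 1-df LRT of
$\sigma_{g12} = 0$ — not boundary-corrected, because a covariance is
two-sided. The optimizer starts with the phenotypic covariance split
evenly between the genetic and residual covariance terms; starting either
at zero or at the full phenotypic covariance leaves no ascent direction
for degenerate (duplicated) traits.

`reml_repeated()` handles two scans per subject with a three-component
decomposition: genetic ($K_{ped}\sigma_g^2$, shared across scans),
common subject environment ($I\sigma_c^2$, shared across scans) and
scan-level residual ($\sigma_e^2$);
$h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_c^2 + \sigma_e^2)$. The exact
random-effect structure of published repeated-measures twin models varies;
this three-component reading is the package's own, and the test suite
checks it by parameter recovery and by its rank agreement with univariate
estimates on scan means.

## Association, loci, enrichment

`lmm_gwas()` is the fast two-step mixed-model scan: the null REML fixes
$\hat V = \hat\sigma_g^2 K + \hat\sigma_e^2 I$; a single symmetric
eigendecomposition turns each SNP into one weighted regression (Wald
test), so per-SNP cost is linear in $n$ after an $n^3$ setup. Variance
components are not re-estimated per SNP and no leave-one-chromosome-out
is applied — the single-pass design of the tool class it follows. With
$K = I$ the scan reduces exactly to OLS, which the tests assert.
Missing genotypes are mean-imputed per SNP; monomorphic SNPs are skipped
with a recorded reason.

`define_loci()` implements clumping-and-merging: significant SNPs
($p$ below the threshold, e.g. `bonferroni_threshold(0.05, n_tests)`),
greedy ascending-$p$ selection of independent significant SNPs at
$r^2 < 0.6$, lead SNPs at $r^2 < 0.1$, tagging at $r^2 \ge 0.6$ with
MAF $\ge 5\times10^{-4}$, block spans from tagged positions, and iterative
merging of same-chromosome blocks closer than 250 kb. Ties in $p$ break
by genomic position so the procedure is order-invariant. LD is computed
in-sample; tagging uses only analyzed SNPs (no external reference panel).
Cytobands come from a UCSC-dialect table, converted on read from 0-based
half-open to 1-based inclusive intervals, so a position at a UCSC `end`
boundary belongs to the lower band.

Enrichment is plain Pearson chi-squared on 2×2 tables without continuity
correction, with the (SNP, vertex) association pair as the default
counting unit (a vertex-level variant is available through the same
functions by passing per-vertex flags). Degenerate tables (zero margins)
are skipped with warnings, never silently zeroed. `dice_overlap()`
measures robustness of association sets as $2|A\cap B|/(|A|+|B|)$.

## Genetic correlation structure and distance decay

`pairwise_rg()` runs bivariate GREML per vertex pair and flags pairs by
Benjamini–Hochberg FDR. `fit_distance_decay()` compares linear and
quadratic least-squares fits of $r_g$ against inter-vertex Euclidean
distance with the standard nested F-test; pairs with undefined $r_g$
(boundary variance components) are dropped listwise. The package reports
the residual-sum-of-squares difference together with the F statistic and
its p-value; no chi-squared presentation of the comparison is offered,
because the nested F-test is the standard exact finite-sample procedure
for one added polynomial term.

## The synthetic cohort generator

The generator exists so the whole pipeline is testable without any
restricted data. It emulates:

* **Cohort structure** — MZ/DZ twin pairs, full-sibling pairs and
  singletons with synthetic founder parents
  (`generate_pedigree()`); the reference composition is 140 MZ pairs,
  85 DZ pairs, 280 full siblings and 204 singletons (899 individuals).
* **Genotypes** — gene dropping: founder haplotypes from a uniform MAF
  spectrum, optional within-block LD via a Gaussian copula with AR(1)
  latent correlation, one transmitted allele per parent per SNP, MZ
  twins copying their co-twin (`simulate_genotypes()`).
* **Covariates** — young-adult ages shared within twin families, sex,
  handedness scores, total brain volume, with the derived interaction
  columns (`simulate_covariates()`).
* **Phenotypes** (`simulate_phenotype()`) in two modes. *Covariance*
  mode draws $y \sim N(X_c\beta,\; K h^2 + I(1-h^2))$ with $\beta \sim
  N(-0.5, 0.5)$ over 500 random causal SNPs — the classical sensitivity
  design, read with 0.5 as a variance and with centered causal dosages.
  Its realized heritability exceeds $h^2$ because the causal mean term
  adds genetic variance on top of $\Sigma$. *Causal* mode builds
  $y = g + e$ with $g = X_c\beta$ rescaled so the realized genetic
  variance fraction equals $h^2$ exactly; parameter-recovery experiments
  use it.
* **Connectivity** (`simulate_connectivity()`) — per subject and vertex a
  latent coupling target with between-subject covariance
  $h^2 K + (1-h^2) I$ (location 0.3, scale 0.15, clipped into $(-1,1)$
  with a warning), realized by writing the FC local profile as
  $\cos\theta\,u + \sin\theta\,w$ with $u$ the unit log1p-SC profile,
  $w$ a unit orthogonal direction and $\theta = \arccos(c)$. The
  emitted profiles therefore reproduce their targets *exactly* under
  `compute_coupling()` (the suite asserts agreement to $10^{-10}$).
  Because each vertex's FC row is constructed independently, generated FC
  matrices are row-profile-oriented rather than globally symmetric;
  symmetry validation applies to profiles read from disk, which is where
  real (symmetric) data enters.
* **Mesh** (`generate_mesh()`) — Fibonacci-lattice hemispheres with
  contiguous angular network/region sectors and a small masked medial
  patch standing in for the corpus callosum.

What the generator does *not* emulate: realistic human LD maps,
imputation uncertainty, genotyping error, sex chromosomes, spatial
autocorrelation of real cortical maps, scanner/site effects. Passing
tests therefore demonstrate the correctness and calibration of the
estimators under their assumed models, not robustness to every artifact
of real imaging genetics data.

### LD in the panel versus LD among causal variants

One generator subtlety matters for interpretation. In the study design
being emulated, 500 causal SNPs are drawn from over a million genome-wide
variants, so causal pairs are essentially mutually unlinked. A desk-scale
panel of 2,000 SNPs arranged in dense LD blocks would instead place many
causal SNPs in strong mutual LD; the aggregate burden component
($\bar\beta \ne 0$) then aligns with the leading directions of the GRM
and inflates heritability estimates — a condition the original design
does not contain. The heritability-recovery experiments therefore
simulate their panel with `ld_block_size = 1` (mutually unlinked
variants), while the locus-definition and clumping functionality — the
reason LD is generated at all — keeps the dense-block default
(blocks of 50 SNPs, latent AR correlation 0.8).

## Problem sizes and reproducibility

The packaged experiments run at desk scale, chosen so the full suite and
the acceptance script complete in minutes on one core: recovery
experiments use a 500-individual cohort (70 MZ, 45 DZ, 70 sibling pairs,
130 singletons), 2,000 SNPs and 200 replicates; subsample grids use 25
replicates per proportion, which is ample for the low-variance mean-SE
monotonicity they examine; the sensitivity-experiment default is 200
replicates with an argument to raise it to the full 4,000-replicate
protocol. Every generator takes an explicit integer seed and each
pipeline stage derives a named substream from the master seed, so any
stage can be reproduced in isolation and a rerun with the same
configuration is byte-identical.

## Known limitations

* Bivariate REML on thousands of vertex pairs is $O((2n)^3)$ per pair;
  `pairwise_rg()` is meant for selected vertex sets, not all ~7M pairs.
* The LRT mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ is asymptotic;
  at a few hundred individuals rejection rates sit slightly below the
  nominal level (conservative), which the calibration tests bound rather
  than pin.
* In-sample LD for clumping differs from reference-panel LD; locus
  boundaries on small cohorts are correspondingly noisy.
* `hwe_exact_test()` enumerates heterozygote configurations; it is exact
  and fast for cohort-scale counts but not meant for biobank-scale
  allele counts in a tight loop.
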