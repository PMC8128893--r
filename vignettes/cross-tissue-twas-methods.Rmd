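---
title: "Cross-tissue TWAS: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-tissue TWAS: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its statistical machinery: the
models and their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the design decisions taken where more than one reasonable
convention exists. It states no empirical result that the test suite does not
itself compute.

## 1. The model

A TWAS asks whether the *genetically regulated* component of a gene's
expression is associated with a trait. With training data (a reference panel
with genotypes and expression) summarized as per-SNP weights $w_g$ per gene
and tissue, and a GWAS summarized as per-SNP z-scores $z$, the single-tissue
statistic is the standard summary-statistic form

$$ Z_{g,t} \;=\; \frac{w^\top z}{\sqrt{w^\top D\, w}}, $$

where $D$ is the SNP correlation matrix from an LD reference. Because the
package stores weights on the *standardized-genotype* scale (training
standardizes genotypes and expression), no per-SNP variance terms appear: the
denominator is exactly the variance of the imputed expression under $D$.
Assumptions: the GWAS z-scores are marginal statistics on one consistent
allele coding (the harmonizer enforces this), the LD reference matches the
GWAS population, and the trait was residualized on its covariates before the
marginal regressions. When $D$ is the GWAS cohort's own LD, $Z_{g,t}$ equals
the individual-level OLS z of the trait on imputed expression up to the
t-vs-normal correction; the suite verifies correlation $> 0.99$ across
simulated genes.

## 2. Cross-tissue combination (generalized Berk-Jones)

The tissue-level statistics of one gene are strongly dependent: tissue models
share eQTLs and all sit on the same LD. Under the null they are jointly
normal with correlation

$$ \Sigma_{ts} = \frac{w_t^\top D w_s}
   {\sqrt{(w_t^\top D w_t)(w_s^\top D w_s)}}, $$

the correlation of the imputed expressions — computable from weights and LD
alone (verified against a genotype-level oracle at $10^{-6}$).

The combination statistic scans the sorted absolute statistics
$|Z|_{(1)} \ge |Z|_{(2)} \ge \dots$: at depth $k$ (restricted to
$k \le \lceil d/2 \rceil$, the usual Berk-Jones convention) with two-sided
tail probability $p_k = 2\bar\Phi(|Z|_{(k)})$, eligible when $k/d > p_k$, it
computes the binomial log generalized-likelihood-ratio
$\mathrm{BJ}_k = k\log\frac{k}{dp_k} + (d-k)\log\frac{d-k}{d(1-p_k)}$ and
deflates it by the variance-inflation ratio
$\sigma_k^2 / \{d p_k (1-p_k)\}$, where
$\sigma_k^2 = d p_k(1-p_k) + \sum_{i \ne j}\big[\Pr(|Z_i|\ge t_k, |Z_j|\ge
t_k) - p_k^2\big]$ uses pairwise bivariate-normal orthant probabilities under
$\Sigma$. The statistic is the maximum over eligible $k$ (zero if none). With
$\Sigma = I$ the ratio is 1 and the statistic *is* classical Berk-Jones
(checked against an independently coded oracle). Two choices here are
deliberate:

- **The $k \le \lceil d/2 \rceil$ rule.** The plain $k \le d/2$ convention
  leaves $d = 1$ with no eligible depth, yet a one-tissue gene must still be
  testable; the ceiling makes $d=1$ a monotone function of $|z|$ and is
  identical to $d/2$ for the even $d$ used everywhere else.
- **Ratio, not difference.** The correction is tabulated (241-point threshold
  grid per $\Sigma$, 32-node Gauss–Legendre orthant integrals, linear
  interpolation) as the dimensionless ratio $\sigma^2/\{dp(1-p)\}$. The
  additive form underflows catastrophically for large $|z|$ (the binomial
  variance reaches $10^{-300}$ while interpolation error stays finite,
  collapsing genuine signals to statistic 0); the ratio tends to 1 in the
  tails and is numerically safe at any signal strength.

**P-values are Monte Carlo**: $p = (1 + \#\{\text{null} \ge \text{obs}\}) /
(B+1)$ with null draws from $\mathrm{MVN}(0, \Sigma)$ via an eigenvalue
square root (tolerating rank-deficient $\Sigma$), bit-reproducible given the
seed. Because the null is simulated under the *same* statistic, the test is
valid regardless of how well the variance approximation tracks the exact
exceedance variance. The analytic boundary-crossing p-value of the original
GBJ construction is intentionally not implemented — its numerics belong to
that method's own reference implementation, and the Monte-Carlo path is the
package's reference method. Consequences: the smallest attainable p is
$1/(B+1)$, so genome-wide thresholds near $10^{-8}$ require large $B$; the
package targets method studies at desk scale, where $B$ of a few thousand
suffices. Near-duplicate tissues (pairwise correlation $> 0.999$) are
collapsed to one representative before testing to avoid a singular null.

## 3. Weight training (sparse group lasso)

Multi-tissue weights minimize

$$ \sum_t \frac{1}{2N}\lVert y_t - X\beta_t\rVert^2
   + \lambda_1 \sum_{j,t} |\beta_{jt}|
   + \lambda_g \sum_j \lVert \beta_{j\cdot}\rVert_2 , $$

with SNP-across-tissues groups: the group penalty removes a SNP from every
tissue or keeps it in several, the lasso penalty sparsifies within tissue.
Inputs are standardized internally on the population scale so the design has
*exactly* unit column norms, making each block update the closed-form group
soft-threshold — which is why the objective is provably non-increasing at
every sweep (asserted on every test fixture). Convergence requires both a
relative objective change below `tol` (default $10^{-7}$) and a stationarity
(KKT) residual below `10 * tol`; non-convergence within `max_iter` warns and
flags the partial result. The per-tissue loss scaling is $1/(2N)$ with
unweighted penalties — the plain sparse-group-lasso form, stated openly,
since sample-size-specific penalty weighting is a training detail the source
method defers to its own supplement. Cross-validation assigns folds by a
seeded permutation and breaks error ties toward the larger total penalty
(sparser model).

## 4. Synthetic data: what it emulates, what it does not

The generator produces the statistical *structure* the pipeline assumes, not
realistic human genetics:

- **Genotypes.** One independent LD block per gene; two haplotypes per
  individual from a latent Gaussian AR(1) chain thresholded at each SNP's
  MAF, dosage = haplotype sum (valid $\{0,1,2\}$, Hardy–Weinberg by
  construction). The latent adjacent correlation is *calibrated* by
  bivariate-normal root finding so the realized dosage correlation equals
  `ld_rho` — thresholding attenuates correlation, so the latent value is
  inflated. One honest caveat: binary variables with unequal MAFs bound the
  reachable correlation (a Fréchet-type cap), so the calibration saturates
  (latent capped at 0.9995) when `ld_rho` exceeds that bound for a pair;
  high-`ld_rho` worlds should use a narrow `maf_range`. Allele pairs are
  mostly non-ambiguous, with ~10% strand-ambiguous (A/T, C/G) SNPs kept so
  the harmonization drop rule stays exercised.
- **Expression.** Per gene, `n_causal_eqtl_per_gene` causal SNPs share
  effects across tissues through a one-factor model with correlation
  `cross_tissue_cor`; per-tissue effects are rescaled on the reference panel
  so the genetic variance share equals `cis_h2`, and noise fills the variance
  to 1. Defaults (`cis_h2 = 0.3`, `cross_tissue_cor = 0.7`, 3 causal eQTLs,
  `n_ref = 800`) reflect typical bulk-tissue cis-heritability and the strong
  cross-tissue eQTL sharing that motivates multi-tissue methods.
- **Phenotype and GWAS.** Phenotype = expression-mediated genetic component
  (through the tissue-averaged effect vector) + direct SNP effects (on a
  random 10% of SNPs) + covariates + noise; `mediated_h2` and `direct_h2` are
  calibrated on the reference sample, so realized shares in an independent
  cohort match up to sampling error (the suite asserts 20% relative at GWAS
  scale). Covariates are an age-like standard normal and a sex-like
  Bernoulli(0.5) with fixed effects of 0.1 — free parameters, since the
  source study does not report covariate effect sizes. Summary statistics
  are marginal OLS t-statistics on the covariate-residualized phenotype:
  the artifact consumes GWAS machinery, it does not reproduce mixed-model
  pipelines.
- **Chromatin interactions.** Negative-binomial per-gene counts
  (`mu0 = 2`, `size = 5`) with an additive mean shift (+2) for a designated
  active gene set, each emitted as an interval pair with a confidence score;
  distal anchors land outside the gene map so every interaction overlaps
  exactly one gene and the emitted counts are exactly recoverable by the
  counting routine.

Not emulated: realistic LD maps, imputation uncertainty, relatedness,
population structure, binary traits. A green test therefore establishes that
the *statistics* behave as designed under their own assumptions — not that
the pipeline is robust to real-data pathologies such as mismatched LD panels.

## 5. Conditional analysis from summary statistics

The source procedure fits `phenotype ~ imputed expression + variant` on
individual-level data. This package realizes the same test from summary
statistics via partial correlation: with $r_{Ey} = z_E/\sqrt n$,
$r_{vy} = z_v/\sqrt n$ and $r_{Ev} = (Dw)_v / \sqrt{w^\top Dw}$,

$$ r_{Ey\cdot v} = \frac{r_{Ey} - r_{Ev} r_{vy}}
   {\sqrt{(1-r_{Ev}^2)(1-r_{vy}^2)}}, \qquad
   t = r_{Ey\cdot v}\sqrt{\frac{n-3}{1-r_{Ey\cdot v}^2}} . $$

This keeps the pipeline summary-statistic-native; the individual-level fit
survives as a test oracle (correlation $> 0.99$ on simulated cohorts, exact
when LD is in-sample). A gene imputed (near-)collinearly with the
conditioned variant ($|r_{Ev}| \ge 1 - 10^{-6}$, e.g. single-SNP models) is
a defined degenerate case: flagged `fully_explained`, $p = 1$. The
conditional z-vector is recombined with GBJ using the *same* tissue
covariance as the marginal test (the marginal and conditional analyses are
declared "similar" by the source procedure, and the conditional statistics'
null correlation is dominated by the same shared-LD structure). Persistence
classes follow the published cutoffs ($p > 0.05$, $\le 10^{-3}$,
$\le 10^{-6}$); these are not exhaustive, so the package adds the in-between
band $0.001 < p \le 0.05$ and the `fully_explained` class so every result is
classified.

## 6. Discovery and PRS conventions

- **Neighbour rule.** "Neighbouring gene within ±1 Mb" is interpreted as
  interval overlap of the ±1 Mb-padded gene *bodies* (equivalently, bodies
  within 1 Mb on the same chromosome). The anchor (TSS vs body) is not
  specified by the source; gene body was chosen, is stated here, and the
  window is a parameter.
- **Significance** is `p < threshold` (strict), with thresholds
  `alpha / n_genes / n_traits` kept in exact double arithmetic.
- **Drop rules.** SNPs in a weight model but absent from GWAS or LD are
  dropped, never imputed; a gene-tissue pair is skipped when more than 50% of
  its absolute weight mass is dropped (a package decision, logged per pair).
  Strand-ambiguous SNPs are dropped by default behind a flag, since the
  source pipeline does not state its convention.
- **PRS.** Training effect sizes use the fuller covariate set (age, age²,
  sex, age×sex, age²×sex, optional total-volume column); evaluation adjusts
  for age and sex only — both mirroring the source's split. "Best prediction
  power" is the maximum incremental R² over the 17-threshold grid within a
  panel, reported alongside all 17 values so the selection optimism is
  visible. The variant-based GWAS PRS for the joint models is a
  clumping-free z-score-thresholded score built from the synthetic GWAS: the
  original analysis imports its variant PRS from earlier work that is out of
  scope, so this is a documented substitute with the same interface.
- **Enrichment sidedness.** The published analysis reports enrichment without
  stating sidedness; the hypothesis is directional (significant genes carry
  *more* interactions), so the default is one-sided "greater" with a
  two-sided option. Exact tie-aware enumeration is used when both groups have
  at most 12 genes; otherwise the normal approximation with tie and
  continuity correction (the two paths agree within 0.02 at the boundary, by
  test).

## 7. Numerical choices and degenerate inputs

- Ridge `1e-6` on $D$'s diagonal in the TWAS quadratic form: estimated LD
  matrices are near-singular for dense blocks; the ridge is far below any
  meaningful weight-variance scale.
- Tissue covariance entries are clipped to $[-1, 1]$ and the matrix projected
  to the nearest PSD surface (eigenvalue clipping, diagonal renormalized)
  only when the smallest eigenvalue is below $-10^{-8}$; projection is
  reported.
- Zero weight vectors, empty SNP intersections, rank-deficient PRS designs
  and constant phenotypes are all hard-defined: skip with log, error, or
  exact-zero result, never silent NA propagation.
- Ties in top-variant selection break by position then lexicographic id;
  CV-error ties break toward the sparser model — both deterministic.
- All stochastic routines take explicit seeds and restore the caller's RNG
  state, so pipeline results are bit-reproducible.

## 8. Known limitations

Monte-Carlo p-value granularity at genome-wide thresholds (see §2); no
analytic GBJ path; no mixed-model or case-control GWAS generation; no
covariate correction inside expression (the generator emits pre-residualized
expression, so PEER-style factors are out of scope); single-variant
conditioning only (no joint multi-variant conditioning); the consensus rule's
TSS-vs-body ambiguity is resolved by convention, not evidence.
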