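---
title: "Methods: integrative Bayesian multi-trait association with a G-Wishart-constrained mixed model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative Bayesian multi-trait association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ibmt)
```

## The model

`ibmt` fits the multi-trait polygenic mixed model

$$
Y = \mu + (X \otimes I_q)\,\beta + U + \epsilon,
\qquad \epsilon \sim N(0,\; I_n \otimes R),
$$

where $Y$ stacks $q$ quantitative traits for $n$ individuals
(individual-major, trait index fastest), $X$ is the $n \times p$ matrix of
standardized variant dosages, $\beta$ holds the per-variant, per-trait
effects, and $U$ collects random polygenic effects with
$\mathrm{Var}(U) = K \otimes \Lambda^{-1}$ for a kinship matrix $K$
(identity by default, for nominally unrelated samples; a VanRaden-style GRM
may be supplied) and a trait precision matrix $\Lambda$.

The point of the method is the prior on $\Lambda$. Correlated clinical
traits typically have a *sparse* conditional-dependence structure: most
pairs are independent given the rest. We first learn that structure as an
undirected Gaussian graphical model over the traits, then constrain
$\Lambda$ to the graph with a G-Wishart prior, which places exact zeros on
the non-edges. This removes free covariance parameters, which is what buys
the power gain over an unconstrained multi-trait model at equal data.

### Trait network

Edges are defined by full-conditional partial correlations: for traits $i$
and $j$, the partial correlation given all remaining traits is read off the
inverse of the trait correlation matrix, and tested with the Fisher
z-transform using effective degrees of freedom $n - (q-2) - 3$. An edge is
included when $p < \alpha$. We deliberately fit the undirected
concentration graph rather than a directed network: the G-Wishart prior
consumes exactly the undirected zero pattern, and edge orientation would be
discarded anyway.

The working significance level is chosen from candidates
$\{0.005, 0.01, 0.05\}$ by structural stability: `select_alpha()` keeps the
largest level whose graph is within Hamming distance 1 of the graph at the
next-smaller level (ties resolved toward the largest level, a single
qualifying pair suffices; if none qualifies the smallest level is
returned). The rule is configurable and all candidate graphs are returned
so the analyst can override. Two cautions, both visible in our validation:

* with a per-pair $\alpha = 0.05$ rule and $\binom{q}{2}$ tested pairs, the
  expected number of false edges is $\alpha$ times the number of null
  pairs. For ten traits with a 9-edge true structure that is roughly 1.8
  spurious edges per fit — edge *recall* is essentially perfect at
  $n = 3000$ with partial correlations of 0.3–0.4, but edge *precision*
  plateaus near 0.85. A harsher level or a multiplicity correction would
  fix this at some cost in recall; we keep the plain rule because the
  selection level is itself a tuning input.
* the network must be learned on samples that are *not* reused for
  association (the phenotype-only cohort), otherwise the prior is fit to
  the same data twice. The pipeline does this; the library function warns
  but does not block.

A practical subtlety for simulation studies: the graph learned from
observed traits reflects the *marginal* trait precision
$(\Lambda_0^{-1} + R_0)^{-1}$, which is sparse only when the residual
covariance $R_0$ is (approximately) proportional to $\Lambda_0^{-1}$. The
synthetic generator's default $R_0 = I$ therefore produces data whose
observable graph is close to, but not exactly, the random-effect graph.

### G-Wishart prior and sampler

The G-Wishart distribution $W_G(\delta, D)$ has unnormalized density
$|\Lambda|^{(\delta-2)/2}\exp\{-\tfrac12\mathrm{tr}(D\Lambda)\}$ supported
on symmetric positive-definite matrices with exact zeros off the graph $G$.
On the complete graph it coincides with the Wishart distribution with
$\delta + q - 1$ degrees of freedom and scale $D^{-1}$; our tests exploit
this as an independent oracle. The normalizing constant is intractable for
general graphs and is never needed here, because the graph is fixed.

Sampling uses block Gibbs over node columns: with node $j$ ordered last and
$\Lambda_{11}$ the rest, the free entries of column $j$ (neighbors of $j$)
are Gaussian with precision $d_{jj}(\Lambda_{11}^{-1})_{AA}$, and the Schur
complement $\gamma = \lambda_{jj} - \lambda_{12}'\Lambda_{11}^{-1}
\lambda_{12}$ is Gamma$(\delta/2,\, d_{jj}/2)$, independent of them.
Updating $\lambda_{jj}$ through $\gamma$ keeps every draw positive-definite
by construction and non-edges stay at exact (bitwise) zero. The prior is
conjugate: observing $n$ random-effect rows updates
$(\delta, D) \to (\delta + n,\; D + U'K^{-1}U)$ on the same graph. Default
hyperparameters are $\delta = q + 2$, $D = I$; both are exposed.

### Gibbs sweep

One iteration updates, in order:

1. $\beta \mid \cdot$ — a single exact joint draw of all $pq$ effects.
   Rotating the traits into the eigenbasis of $R^{-1}$ makes the
   full conditional factor into $q$ independent $p$-dimensional Gaussians
   (the iid $N(0, \sigma_\beta^2)$ prior is rotation-invariant), so the
   block costs $q$ Cholesky factorizations of $p \times p$ matrices. This
   replaces a sequential per-variant scan: same full conditional, exact
   blocking, and several-fold faster at the window sizes used here.
2. $U \mid \cdot$ — Gaussian with precision $K^{-1}\otimes\Lambda +
   I_n \otimes R^{-1}$; with identity kinship all rows share one $q\times q$
   factorization, with a general $K$ the update works in $K$'s eigenbasis.
3. $\Lambda \mid U$ — conjugate G-Wishart update followed by one
   constrained block-Gibbs sweep (the outer chain supplies mixing).
4. $R \mid \epsilon$ — conjugate inverse-Wishart, prior IW$(q+2, I)$.
5. $\sigma_\beta^2 \mid \beta$ — conjugate inverse-gamma with IG$(1,1)$
   hyperprior (the hierarchical default), or held fixed.
6. $\mu \mid \cdot$ — Gaussian under a flat prior.

Initialization is deterministic: trait means for $\mu$, zeros for $\beta$
and $U$, identity for $\Lambda$, diagonal trait variances for $R$. All
randomness flows through R's RNG, so a seed makes the whole chain, and the
whole window scan, bit-reproducible.

### Credible intervals and the stopping rule

Point estimates are posterior means over retained draws (200 burn-in by
default). Selection uses the equal-tailed 98% credible interval
$(q^L, q^U)$ with type-7 (linear-interpolation) quantiles: a variant-trait
effect is selected when its interval excludes zero. No further multiplicity
correction is applied; the interval level is the error-control device.

Chain length is governed by a quantile-stability rule: after each batch of
`check_every = 100` retained draws the interval endpoints of every
coefficient are compared with the previous check, and sampling stops when
every endpoint moved by less than $\zeta = 0.01$ (on the standardized trait
scale), or when `max_iter` is reached (flagged, not an error). In the
window-scan setting (300 coefficients per window) this typically terminates
around 1,400 retained draws.

### Sliding-window scan

Genome-wide, variants are analyzed in windows of 100 consecutive variants
advancing by 25, restarting at chromosome boundaries, so interior variants
appear in exactly 4 windows. A variant is *reported* only if it is selected
in every window containing it (edge variants sit in fewer than 4 windows;
the all-windows rule applies to however many there are), and a trait is
attached to the report only if that same trait was selected in all
containing windows. Pooled effects and SDs are arithmetic means of the
per-window posterior means and SDs; per-window values are retained for
audit. Window chains are seeded as `seed + window index`, making the result
independent of processing order. Monomorphic variants are dropped (their
standardization is undefined) and listed.

Because a 98% interval falsely excludes zero for about 2% of null
coefficients, a variant contained in a single window (the first and last
`step` variants of a chromosome) has a false-report probability near
$1 - 0.98^q$, while interior variants need four correlated exceedances.
The per-variant false-report rate in our null simulations stays well under
2% at the default geometry; the rate is dominated by chromosome-edge
variants.

## Preprocessing

* **Variant QC** — drop multi-allelic records, missingness > 20%, and
  exact Hardy-Weinberg p < 5e-6 (two-sided conditional exact test,
  recurrence implementation; no mid-p). Remaining missing dosages are
  mean-imputed per variant, then dosages are standardized.
* **Traits** — winsorize at the (0.005, 0.995) empirical quantiles
  (type-1, inverse-CDF quantiles: this makes winsorization exactly
  idempotent, which interpolated quantiles do not); test normality
  (Shapiro–Wilk at 0.05, deterministically thinned to 5,000 points above
  the test's size limit); when rejected, apply the natural log if all
  values are positive — or a user-supplied recorded shift — and only if it
  improves the Shapiro–Wilk statistic; finally standardize.
* **Covariates** — screened on the phenotype-only cohort: a candidate is
  kept when its univariable regression is significant at 0.05 for at least
  half the traits (both thresholds configurable). Kept covariates plus any
  supplied principal components are regressed out of every trait;
  residuals are exactly orthogonal to the design. PCs are accepted as
  input, not computed here.

## The synthetic generator

`sim_config()`/`simulate_ibmt_data()` emulate a realistic study design end
to end: a three-way cohort split (defaults 442 genotype-only / 339 both /
127 phenotype-only), ten traits
(named after the echocardiographic panel at $q = 10$) generated as
$y = \mu + B_c c + \sum_k \beta_k x_k + u + e$ with chain-structured
random-effect precision, BMI-like lognormal, sex and hypertension
covariates (Bernoulli rates tuned to female/male $\approx 1.3$ and
with/without hypertension $\approx 2.5$), independent Binomial$(2,
\mathrm{MAF})$ variants with a rare tail at 0.25–0.38% MAF, and one rare
pleiotropic variant affecting three traits (effects 1.1, 1.3, 1.3 per
allele). Planted rare variants are resampled until at least 4 carriers
exist in the both-cohort, so their effects are estimable; phenotype-only
samples receive no genetic term (their genotypes are unobserved), which
also keeps covariate screening unconfounded. Covariate distributions are
qualitative stand-ins, not calibrated to any real cohort. Variants are
independent by default — the scan does not model LD, so synthetic LD would
only blur planted-variant attribution.

What passing tests on these data do *not* show: robustness to LD, to
population structure beyond supplied PCs, to non-Gaussian trait residuals
after transformation, or to model misspecification of the kinship.

## Validation design and problem sizes

The test suite validates each layer against an independent route:

* HWE exact test vs brute-force log-factorial enumeration ($n \le 50$).
* Partial correlations vs regression-residual correlations; Hamming
  distance vs pairwise brute force ($q \le 7$), including metric axioms.
* G-Wishart: complete-graph moments vs `stats::rWishart` (within 3
  ESS-adjusted Monte-Carlo SEs at $q \in \{2, 3\}$), exact zeros on chains,
  conjugate recovery of a known $\Lambda_0$ within 5% at $n = 5000$, and
  closed-form log-density values.
* Sampler: the $\beta$ full conditional vs closed-form Bayesian regression;
  prior recovery under a zero design; 98% interval coverage of a planted
  0.5-SD effect measured over 200 replicates at $n = 300$, $q = 3$,
  $p = 10$ (200 burn-in, 1,000 retained draws per fit). The calibration
  study fixes $\sigma_\beta^2 = 1$: coverage of a *fixed* planted effect is
  a frequentist statement, and the adaptive hierarchical prior — designed
  to shrink — trades a point or two of coverage (bias about $-0.04$ SD on
  the planted effect in the same design) for fewer false selections. Both
  behaviours are measurable via `coverage_study()`.
* Scan: 20 simulated exomes ($n = 500$, $q = 3$, $p = 300$, planted
  interior variant at MAF 5% with a 1.0-SD-per-allele effect) for recall
  and per-variant false-report rate; determinism, idempotence and
  level-monotonicity checks.

These sizes are the package's validation settings; they were chosen so the
statistical assertions have usable power while each suite stays at desk
scale.

## Known limitations

* With identity kinship, $U$ and $\epsilon$ are separated only by their
  priors and cross-trait covariance structure; individual-level random
  effects are weakly identified (the $\beta$ inferences, which integrate
  over both, are unaffected — this is expected, not a defect).
* The hierarchical effect prior shrinks isolated large effects among many
  nulls; see the calibration discussion above.
* Per-pair edge testing at $\alpha = 0.05$ admits a predictable number of
  spurious edges; a too-dense pattern costs efficiency, not validity, since
  the G-Wishart prior still shrinks those entries.
* Windows are index-based, not annotation-aware, and the scan assumes
  variants ordered by chromosome and position.
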