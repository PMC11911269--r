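---
title: "Methodology of the generalized two-step procedure"
author: "gtsfdr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methodology of the generalized two-step procedure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtsfdr)
```

## The model and the testing problem

We observe independent responses $Y_1,\dots,Y_n$ and covariate rows
$x_i \in \mathbb{R}^d$ following a generalized linear model
$g(\mu_i) = \eta_i = x_i^T\beta$, where $\mu_i = E(Y_i)$ and $g$ is a
canonical link (identity, logit, or log). The goal is to test all
$H_{0j}: \beta_j = 0$ simultaneously with false discovery rate control at a
target level $\alpha$, without assumptions on the dependence between the
Wald statistics. The setting is low-dimensional with $n > 2d$; the
asymptotics keep $d$ fixed as $n \to \infty$, which is also why normal
(not $t$) reference distributions are used throughout.

The maximum likelihood estimator satisfies
$\hat\Gamma^{-1/2}(\hat\beta - \beta) \approx N(0, I_d)$ with
$\hat\Gamma = (X^T \hat W X)^{-1}$ and
$W = \mathrm{diag}(w_i)$, $w_i = (d\mu_i/d\eta_i)^2/\mathrm{var}(Y_i)$. The
mean–variance relationship makes $w_i$ depend on the fitted means
($\mu_i(1-\mu_i)$ for Bernoulli, $\mu_i$ for Poisson), and this
heterogeneity is the crux of everything that follows.

## Conditionally null regeneration

The procedure augments $X$ with a regenerated matrix $\tilde X$ that,
conditional on $X$, is independent of $Y$. The package enforces this by
construction: the regeneration functions accept only $X$ and a seed.
Three strategies are provided.

* **Row permutation** (default): one uniform permutation of the rows.
  It preserves the empirical between-column covariance exactly and needs
  no model for the covariates, which is why it is the recommended default.
* **Full entry permutation**: all $nd$ entries are shuffled globally,
  destroying the column covariance as well. Whether a "full rearrangement"
  should permute entries globally or within columns is genuinely open; we
  implement the global version as the default interpretation and expose
  column-wise permutation as a separate strategy.
* **Second-order Gaussian Model-X knockoffs** with the equicorrelated
  rule: $s_j = \min(1, 2\lambda_{\min}(\hat\Sigma_{\mathrm{corr}}))\,
  \hat\Sigma_{jj}$ and rows drawn from the Gaussian conditional
  $N\!\left(X_i - (X_i-\hat m)\hat\Sigma^{-1}S,\; 2S - S\hat\Sigma^{-1}S\right)$.
  We use the equicorrelated rather than the SDP construction: it is exact
  arithmetic on $\hat\Sigma$, has no optimization dependency, and the
  choice of knockoff flavour is orthogonal to the method's contribution.
  When $\lambda_{\min}$ of the correlation matrix falls below $10^{-6}$,
  $\hat\Sigma$ is shrunk toward its diagonal in increasing steps; a
  constant column is an error, not a silent degenerate draw.

If the augmented matrix $(X, \tilde X)$ is numerically rank-deficient the
draw is repeated with an incremented seed up to 10 times before failing:
with $n > 2d$ this is rare, and a silent pseudo-inverse would corrupt the
covariance estimate downstream.

## The working fit

The working model $g(\mu_i) = x_i^T\theta_1 + \tilde x_i^T\theta_2$ is fit
by iteratively reweighted least squares on the $n \times 2d$ augmented
design. If the original model holds, the truth is $\theta_1 = \beta$,
$\theta_2 = 0$, and
$\hat\Omega^{-1/2}(\hat\theta - \theta_0) \approx N(0, I_{2d})$ with
$\hat\Omega = \{(X,\tilde X)^T \hat W (X,\tilde X)\}^{-1}$, where
$\hat W$ is evaluated at the augmented fit's means (the working model
defines $\hat\Omega$, so its own weights are the coherent choice).

IRLS details, all conventional: starting means from a link-transformed
adjusted response; convergence when the relative change of the coefficient
vector drops below $10^{-8}$ (default; at most 100 iterations); weighted
least squares through QR, covariance through a Cholesky solve of the
information matrix. No intercept is added implicitly — the model has no
separate intercept term, and a user-supplied constant column is tested
like any other coefficient. Gaussian dispersion is the Pearson estimator
$\hat\sigma^2 = \sum_i (y_i-\hat\mu_i)^2/(n-p)$ (binomial and Poisson
dispersion is fixed at 1); the procedure itself does not prescribe a
gaussian dispersion estimator, so we adopt the standard one. Binomial
non-convergence with fitted probabilities within $10^{-10}$ of 0 or 1 is
reported as separation: failing loudly beats emitting huge-variance
p-values.

## The transformation

Write $\hat\Omega = \bigl[\begin{smallmatrix} J & K \\ K^T & N
\end{smallmatrix}\bigr]$ and seek
$Z = \bigl[\begin{smallmatrix} I & P \\ I & V \end{smallmatrix}\bigr]$ so
that $Z\hat\theta = (\hat\beta_1^T, \hat\beta_2^T)^T$ gives two unbiased
estimators of $\beta$ with

1. $\mathrm{cov}(\hat\beta_1, \hat\beta_2) = J + PK^T + KV^T + PNV^T = 0$, and
2. $\mathrm{cov}(\hat\beta_2) = J + VK^T + KV^T + VNV^T = D$ diagonal.

In homoskedastic linear models with knockoffs, $P = I$, $V = -I$ achieves
both. With GLM weight heterogeneity it does not — the package's test suite
reproduces this failure quantitatively (the off-diagonal block of
$Z\hat\Omega Z^T$ stays bounded away from zero on logistic knockoff fits
with strong same-sign signal) — so $V$ must be solved for. Objective (2)
with symmetric $V$ is a continuous algebraic Riccati equation
$$F^T V + V F - V G V + H = 0,\qquad
F = -K^T,\quad G = N,\quad H = D - J,$$
whose stabilizing solution we compute by the Schur method: form the
Hamiltonian $\Phi = \bigl[\begin{smallmatrix} F & -G \\ -H & -F^T
\end{smallmatrix}\bigr]$, take a real Schur factorization with the $d$
eigenvalues of negative real part ordered first (LAPACK `dgees` with a
sort callback, wrapped in `src/`), and set $V = U_{21}U_{11}^{-1}$ from
the leading Schur vectors. Then $P = -(J + KV^T)(K^T + NV^T)^{-1}$ from
objective (1). Numerical policy:

* $V$ is symmetrized as $(V+V^T)/2$; pre-symmetrization asymmetry above
  $10^{-6}\lVert V\rVert_F$ raises a warning as a solver-quality signal.
* the equation residual must satisfy $\lVert\cdot\rVert_F \le
  10^{-6}(1+\lVert H\rVert_F)$ — the method itself fixes no tolerance, so
  this is our acceptance threshold, chosen comfortably above accumulated
  rounding at $d \le 100$ and far below any statistically meaningful
  perturbation;
* Hamiltonian eigenvalues within $10^{-10}$ of the imaginary axis, a wrong
  stable-subspace dimension, $\mathrm{rcond}(U_{11}) < 10^{-12}$, or an
  unstable closed loop $F - GV$ are all hard errors — ties at the axis are
  never resolved by guessing;
* linear systems are solved by factorization throughout; only the
  information matrix is explicitly inverted (via Cholesky) because
  $\hat\Omega$ itself is the quantity of interest.

**Choice of $D$.** $D = \delta_c\,\lambda_{\max}(J)\,I$ with
$\delta_c \ge 1$, which makes $H = D - J$ positive semi-definite (its
eigenvalues are $\delta - \lambda_{J,i}$). Smaller $\delta_c$ means
smaller variance for $\hat\beta_2$ and hence more power, but $\delta_c = 1$
makes $H$ exactly singular; $\delta_c = 1.1$ is the recommended default and
is used everywhere in the package's calibration. Non-constant diagonals
for $D$ are a known possible refinement and are out of scope.

## Paired p-values and decision rules

With $\mathrm{var}(\hat\beta_1) = J + PK^T + KP^T + PNP^T$ and
$\mathrm{var}(\hat\beta_2) = D$, the marginal two-sided p-values are
$P^{(1)}_j = 2\{1-\Phi(|\hat\beta_{1j}|/\sqrt{(\mathrm{var}_1)_{jj}})\}$
and $P^{(2)}_j = 2\{1-\Phi(|\hat\beta_{2j}|/\sqrt{D_{jj}})\}$, and the
step-2 p-values are $\tilde P_j = \max(P^{(1)}_j, P^{(2)}_j)$. The max is
the conservative pairing of two independent p-values and is isolated in a
single line of `paired_pvalues()` so an alternative pairing is a one-line
change; we adopt it because it is the only combination consistent with
both cutoffs acting as thresholds on the screened hypotheses.

* **GTS**: screen $S = \{j: P^{(1)}_j \le \sqrt\alpha\}$ (non-strict
  inequality), BH at level $\sqrt\alpha$ on $\{\tilde P_j : j \in S\}$
  with $m = |S|$. Product of cutoffs $= \alpha$; asymptotic FDR
  $\le \pi_0\alpha$.
* **GTS-$\lambda$**: screen at $\lambda \in (\alpha, 1]$, BH at
  $\alpha/\lambda$. $\lambda = \sqrt\alpha$ recovers GTS exactly;
  $\lambda$ near $\alpha$ (e.g. $1.001\alpha$, giving BH level
  $1.001^{-1}$) trades screening stringency for a nearly unconstrained
  second step.
* **AGTS**: Storey estimate
  $\hat\pi_0 = \min\{1, (1+\#\{j: P^{(2)}_j > \lambda_0\})/(d(1-\lambda_0))\}$
  with $\lambda_0 = 0.5$ (the BH-adaptive convention; $P^{(2)}$ is used
  because its components are asymptotically independent), then the GTS
  rule at working level $\alpha' = \alpha/\hat\pi_0$ — the adjustment is
  applied to the whole two-step rule, mirroring adaptive-BH practice.
  Asymptotic FDR $\le \alpha$.
* **Beta-2-Only**: plain BH at $\alpha$ on $P^{(2)}$.

Ties in BH share a fate (standard step-up semantics, via
`stats::p.adjust`). One subtlety the test suite documents: enlarging the
screened set (by raising $\alpha$ or via $\hat\pi_0 < 1$) can *dilute* BH
— $m$ grows along with the level — so rejection sets are provably nested
in $\alpha$ only when the screening cutoff is held fixed; the adaptive
rule is more powerful in expectation, not uniformly per dataset.

## What the synthetic-data generator emulates

The generator reproduces the calibration design: rows of $X$ i.i.d.
$N(0,\Sigma)$ with AR(1) structure $\Sigma_{ij} = \rho^{|i-j|}$ (drawn by
the AR recursion, exact for this $\Sigma$); $k$ of $d$ coefficients
nonzero at $\pm\,\mathrm{amplitude}/\sqrt n$ with fair-coin signs on a
uniform random support; responses drawn from the family at the linked
mean (unit-variance noise in the gaussian case). The $1/\sqrt n$ scaling
keeps signals in the local-alternative regime where the paired-estimator
asymptotics are informative. A Poisson linear predictor above 30 aborts
generation — with a log link that is a mean of $10^{13}$, i.e. a
misconfigured amplitude, and the default study configurations keep
$|\eta|$ far below this.

What it does **not** emulate: non-Gaussian or heavy-tailed covariates,
model misspecification (omitted nonlinearity, overdispersion), clustered
or dependent observations. Passing calibration here shows the procedure
behaves as its asymptotic theory predicts under its stated conditions; it
does not certify performance under covariate model violation, which
matters particularly for the knockoff regeneration (row permutation is
covariate-model-free, a practical argument for the default).

The replication harness derives per-replicate seeds from the base seed by
a counter scheme (seed $+ 104729\,r + 7919\,s \bmod 2^{31}-1$ for stream
$s$), so replicates are independent, reorderable and reproducible;
failed replicates are excluded from the rates and counted, with a warning
(or an error under `strict = TRUE`) above a 10 % failure share.

## Study sizes used in calibration

The packaged calibration studies use $n = 800$, $d = 40$, $k = 10$,
$\rho = 0.5$, $\alpha = 0.1$, with 100 replicates per configuration
(amplitude 6 for logistic, 3 for Poisson — chosen so Poisson means stay
moderate, respecting the family's variance blow-up with its mean), and a
500-replicate global null at $n = 1000$, $d = 10$ for uniformity and
calibration checks. These sizes put the Monte-Carlo standard error of an
empirical FDR near 0.01, small enough to make the $\le \alpha$ bounds
meaningful. The full-scale design (250 replicates) is available by
setting `reps` in `gts_study_config()`.

## Known limitations

* Low-dimensional only: $n > 2d$ is enforced, and the normal
  approximation needs $n$ comfortably larger than $2d$; no augmentation
  scheme for $n < 2d$ is attempted.
* The Schur method is dense ($O(d^3)$ on a $2d$ Hamiltonian) and is known
  to degrade in high dimensions.
* FDR control is asymptotic; at small $n$ the procedure is typically
  conservative (empirical FDR well below $\alpha$), with correspondingly
  modest power at weak amplitudes.
* Quasi-likelihood families, offsets, observation weights and regularized
  fitting are out of scope.
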