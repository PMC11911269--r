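# gtsfdr

Paired p-value multiple testing for generalized linear models with
asymptotic false discovery rate (FDR) control under arbitrary dependence
between test statistics.

## The problem

Given a GLM \(g(\mu_i) = x_i^T\beta\) (gaussian/identity, binomial/logit or
poisson/log) with \(n > 2d\), we want to test \(H_{0j}: \beta_j = 0\) for all
\(d\) coefficients while controlling the FDR. Applying Benjamini–Hochberg
(BH) to the usual Wald p-values is only justified under independence or
special positive dependence; coefficient estimates of a GLM are arbitrarily
correlated. `gtsfdr` implements the **generalized two-step (GTS)**
procedure, which restores FDR control by manufacturing a pair of
asymptotically *independent* estimators for every coefficient:

1. **Regenerate** a conditionally null copy \(\tilde X\) of the design —
   by random row permutation (default), full entry permutation, or
   second-order Gaussian Model-X knockoffs.  Conditional on \(X\),
   \(\tilde X\) carries no information about \(Y\).
2. **Fit** the working model \(g(\mu_i) = x_i^T\theta_1 + \tilde x_i^T
   \theta_2\) on the augmented design \((X, \tilde X)\) by maximum
   likelihood, with estimated covariance
   \(\hat\Omega = \{(X,\tilde X)^T \hat W (X,\tilde X)\}^{-1}
   = \bigl[\begin{smallmatrix} J & K \\ K^T & N \end{smallmatrix}\bigr]\).
3. **Transform**: find \(Z = \bigl[\begin{smallmatrix} I & P \\ I & V
   \end{smallmatrix}\bigr]\) so that \(Z\hat\theta = (\hat\beta_1^T,
   \hat\beta_2^T)^T\) satisfies (i) \(\hat\beta_1 \perp \hat\beta_2\)
   asymptotically and (ii) \(\mathrm{cov}(\hat\beta_2) = D\) diagonal, with
   \(D = \delta_c\,\lambda_{\max}(J)\, I\), \(\delta_c = 1.1\).  Condition
   (ii) is a continuous algebraic Riccati equation
   \(F^TV + VF - VGV + H = 0\) with \(F = -K^T\), \(G = N\), \(H = D - J\),
   solved by the Schur method (ordered real Schur factorization of the
   Hamiltonian; \(V = U_{21}U_{11}^{-1}\)); then
   \(P = -(J + KV^T)(K^T + NV^T)^{-1}\).
   In linear models with homoskedastic errors the fixed choice
   \(P = I, V = -I\) works; the heterogeneous GLM weights break it, which
   is why the Riccati construction is needed.
4. **Decide**: form paired p-values \(P^{(1)}_j, P^{(2)}_j\) from the
   normal limits of \(\hat\beta_1, \hat\beta_2\) and apply a screen-then-BH
   rule: keep \(S = \{j : P^{(1)}_j \le \sqrt\alpha\}\), then run BH at
   level \(\sqrt\alpha\) on \(\tilde P_j = \max(P^{(1)}_j, P^{(2)}_j)\)
   over \(S\).  This controls the FDR at \(\pi_0\alpha\) asymptotically;
   the adaptive variant (AGTS) plugs in a Storey estimate \(\hat\pi_0\) to
   control at \(\alpha\).  A BH-only rule on \(P^{(2)}\) and a
   generalized-cutoff rule (screen at \(\lambda\), BH at \(\alpha/\lambda\))
   are also provided.

## Worked example

```r
library(gtsfdr)
n <- 600; d <- 12
X    <- gts_sim_design(n, d, rho = 0.5, seed = 11)        # AR(1) covariates
beta <- gts_sim_coefficients(d, 3, amplitude = 14, n = n, seed = 12)
attr(beta, "support")                                      # 2 7 10
y    <- gts_sim_response(X, beta, "binomial", seed = 13)

res <- gts(X, y, family = "binomial", alpha = 0.1, method = "agts", seed = 14)
res
#> Generalized two-step multiple testing
#>   family: binomial | regeneration: row_permutation | method: agts
#>   n = 600 , d = 12 , alpha = 0.1
#>   screened: 5 | rejected: 3
#>   selected: X2, X7, X10
```

The procedure screens 5 of 12 coefficients on the first p-value vector and
rejects exactly the three true signals. `summary(res)` returns the full
per-coefficient table (paired estimates, standard errors, \(P^{(1)}\),
\(P^{(2)}\), \(\tilde P\), screened/rejected flags); for X10 it shows
`beta1 = -0.68`, `beta2 = -0.50`, `p1 = 0.0020`, `p2 = 0.0062` — two
independent looks at the same coefficient, both small, so the rejection
survives both steps. `plot(res)` draws the paired p-values with the
screening cutoff; `write_gts_decisions(res, "decisions.tsv")` saves the
table with a provenance header.

Monte-Carlo calibration of the whole pipeline:

```r
cfg <- gts_study_config(n = 800, d = 40, k = 10, rho = 0.5, amplitude = 6,
                        family = "binomial", alpha = 0.1, reps = 100, seed = 1)
run_gts_study(cfg)
#>   empirical FDR  : 0.0133 (MC se 0.0105)
#>   empirical power: 0.0270 (MC se 0.0079)
```

A command-line front end for file-based analyses lives in
`inst/cli/gts.R` (`fit` and `simulate` subcommands).

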