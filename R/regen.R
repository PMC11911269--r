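#' Regenerated (conditionally null) model matrices
#'
#' Constructs a regenerated copy \eqn{\tilde X} of the design matrix that,
#' conditional on \eqn{X}, carries no information about the response: the
#' construction consumes only \eqn{X} and a seed, never \eqn{Y}, so
#' conditional independence holds by design.  Three strategies are provided:
#'
#' \describe{
#'   \item{\code{row_permutation}}{(default for the two-step procedure)
#'     shuffles whole rows of \eqn{X} by one uniformly random permutation,
#'     preserving the between-column sample covariance exactly while breaking
#'     the covariate-response association.}
#'   \item{\code{full_permutation}}{permutes all \eqn{n d} entries globally,
#'     destroying both row structure and between-column covariance; the
#'     multiset of entries is preserved.}
#'   \item{\code{column_permutation}}{permutes each column independently
#'     (variant of the full rearrangement that keeps marginals per column).}
#'   \item{\code{model_x_gaussian}}{second-order Gaussian Model-X knockoffs
#'     with the equicorrelated rule: estimate \eqn{\hat m} and
#'     \eqn{\hat\Sigma} from \eqn{X}, set \eqn{s_j = \min(1,
#'     2\lambda_{\min}(\hat\Sigma_{\mathrm{corr}}))\,\hat\Sigma_{jj}} and draw
#'     each row from the Gaussian conditional
#'     \eqn{N(X_i - (X_i - \hat m)\hat\Sigma^{-1}S,\; 2S - S\hat\Sigma^{-1}S)}
#'     with \eqn{S = \mathrm{diag}(s)}, so the joint second moments of
#'     \eqn{(X, \tilde X)} match the knockoff exchangeability conditions in
#'     population.  \eqn{\hat\Sigma} is shrunk toward its diagonal when its
#'     smallest eigenvalue falls below \code{1e-6}.}
#' }
#'
#' @param x numeric matrix, \eqn{n \times d}.
#' @param strategy regeneration strategy, see Details.
#' @param seed integer RNG seed recorded in the result for reproducibility.
#' @return Object of class \code{"gts_regen"}: list with \code{matrix}
#'   (\eqn{\tilde X}), \code{strategy} and \code{seed}.
#' @examples
#' X <- matrix(rnorm(40), 10, 4)
#' xt <- gts_regenerate(X, "row_permutation", seed = 1)
#' # rows are preserved as a multiset:
#' all(sort(X[, 1]) == sort(xt$matrix[, 1]))
#' @export
gts_regenerate <- function(x,
                           strategy = c("row_permutation", "full_permutation",
                                        "column_permutation",
                                        "model_x_gaussian"),
                           seed = NULL) {
  strategy <- match.arg(strategy)
  x <- as.matrix(x)
  n <- nrow(x)
  d <- ncol(x)
  if (n < 2 || n * d < 2) stop("design too small to regenerate", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  xt <- switch(strategy,
    row_permutation = x[sample.int(n), , drop = FALSE],
    full_permutation = matrix(sample(as.vector(x)), n, d),
    column_permutation = apply(x, 2, sample),
    model_x_gaussian = model_x_gaussian_draw(x)
  )
  dimnames(xt) <- dimnames(x)
  structure(list(matrix = xt, strategy = strategy, seed = seed),
            class = "gts_regen")
}

#' @export
print.gts_regen <- function(x, ...) {
  cat("Regenerated design (", x$strategy, "), ", nrow(x$matrix), " x ",
      ncol(x$matrix), if (!is.null(x$seed)) paste0(", seed ", x$seed), "\n",
      sep = "")
  invisible(x)
}

# Second-order Gaussian knockoff sampler (equicorrelated rule).
model_x_gaussian_draw <- function(x) {
  n <- nrow(x)
  d <- ncol(x)
  m_hat <- colMeans(x)
  sigma <- stats::cov(x)
  sds <- sqrt(diag(sigma))
  if (any(sds <= 0)) {
    stop("knockoff construction failed: a column of X is constant",
         call. = FALSE)
  }
  corr <- sigma / tcrossprod(sds)
  lam_min <- min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values)
  if (lam_min < 1e-6) {
    # shrink toward the diagonal until the correlation matrix is safely PD
    gamma <- 0.05
    repeat {
      corr <- (1 - gamma) * corr + gamma * diag(d)
      sigma <- corr * tcrossprod(sds)
      lam_min <- min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values)
      if (lam_min >= 1e-6) break
      gamma <- gamma * 2
      if (gamma > 1) {
        stop("knockoff construction failed: covariance not positive ",
             "definite even after shrinkage; consider more shrinkage or ",
             "standardizing X", call. = FALSE)
      }
    }
  }
  s <- min(1, 2 * lam_min) * diag(sigma)  # equicorrelated rule, cov scale

  sig_chol <- chol(sigma)
  # Sigma^{-1} S via two triangular solves
  sinv_s <- backsolve(sig_chol,
                      forwardsolve(t(sig_chol), diag(s, d, d)))
  centered <- sweep(x, 2, m_hat)
  cond_mean <- x - centered %*% sinv_s
  cond_cov <- 2 * diag(s, d, d) - diag(s, d, d) %*% sinv_s
  cond_cov <- (cond_cov + t(cond_cov)) / 2

  ev <- eigen(cond_cov, symmetric = TRUE)
  vals <- ev$values
  if (any(vals < -1e-8 * max(abs(vals), 1))) {
    stop("knockoff conditional covariance not positive semi-definite; ",
         "consider more shrinkage", call. = FALSE)
  }
  vals[vals < 0] <- 0
  root <- ev$vectors %*% (sqrt(vals) * t(ev$vectors))
  cond_mean + matrix(stats::rnorm(n * d), n, d) %*% root
}

# Augments X with a regenerated copy and checks rank; on numerical rank
# deficiency the regeneration is redrawn with the next seed, up to 10 times.
augment_design <- function(x, strategy, seed) {
  n <- nrow(x)
  d <- ncol(x)
  if (n <= 2 * d) {
    stop("the two-step procedure requires n > 2d (got n = ", n,
         ", d = ", d, ")", call. = FALSE)
  }
  for (try in 0:10) {
    regen <- gts_regenerate(x, strategy,
                            seed = if (is.null(seed)) NULL else seed + try)
    aug <- cbind(x, regen$matrix)
    if (qr(aug)$rank == 2 * d) {
      return(list(augmented = aug, regen = regen))
    }
  }
  stop("augmented design (X, Xtilde) is numerically rank deficient after ",
       "10 redraws", call. = FALSE)
}
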