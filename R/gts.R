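#' Generalized two-step multiple testing for GLM coefficients
#'
#' Fits the full pipeline: regenerate a conditionally null copy
#' \eqn{\tilde X} of the design, fit the working GLM on the augmented matrix
#' \eqn{(X, \tilde X)} by maximum likelihood, build the decorrelating
#' transformation by solving a continuous algebraic Riccati equation, form
#' paired p-values for every coefficient, and apply the selected
#' screening-plus-BH decision rule.  The result is a classed object carrying
#' the fit, the transformation diagnostics, the paired estimates and
#' p-values, and the rejection set, with the usual accessor methods.
#'
#' Tests are of \eqn{H_{0j}: \beta_j = 0} for each of the \eqn{d} columns of
#' \code{x}; no intercept is added implicitly (include a constant column if
#' wanted — it is then tested like any other coefficient).  The method
#' requires \eqn{n > 2d}.
#'
#' @param x numeric design matrix, \eqn{n \times d} with \eqn{n > 2d}.
#' @param y response vector of length \eqn{n}.
#' @param family \code{"gaussian"}, \code{"binomial"} (alias
#'   \code{"logistic"}) or \code{"poisson"}, or a \code{\link{gts_family}}
#'   object.
#' @param alpha target false discovery rate in (0, 1); default 0.1.
#' @param method decision rule: \code{"gts"} (two-step, FDR \eqn{\le
#'   \pi_0\alpha}), \code{"agts"} (adaptive, FDR \eqn{\le \alpha}),
#'   \code{"beta2_only"} (BH on the second p-values), or
#'   \code{"gts_lambda"} (generalized screening cutoff, requires \code{lam}).
#' @param regen regeneration strategy for \eqn{\tilde X}; see
#'   \code{\link{gts_regenerate}}.  Default \code{"row_permutation"}.
#' @param delta_c constant \eqn{\delta_c \ge 1} scaling the diagonal variance
#'   target \eqn{D = \delta_c\,\lambda_{\max}(J) I}; default 1.1.
#' @param lam screening cutoff for \code{method = "gts_lambda"}.
#' @param lambda0 tuning constant of the null-proportion estimator used by
#'   \code{method = "agts"}; default 0.5.
#' @param seed integer seed for the regeneration draw (recorded); optional.
#' @param standardize logical; center and scale the columns of \code{x}
#'   before the analysis (off by default; can stabilize knockoff covariance
#'   estimation).
#' @param max_iter,tol IRLS controls passed to \code{\link{gts_glm_fit}}.
#' @return Object of class \code{"gts"}; see Details.  Key components:
#'   \code{decision} (\code{rejected}, \code{screened}), \code{pvalues}
#'   (\code{p1}, \code{p2}, \code{ptilde}), \code{paired} (\code{beta1},
#'   \code{beta2}), \code{transform}, \code{fit}.
#' @examples
#' set.seed(7)
#' n <- 300; d <- 8
#' X <- matrix(rnorm(n * d), n, d)
#' beta <- c(rep(1.2, 2), rep(0, d - 2))
#' y <- rbinom(n, 1, plogis(X %*% beta))
#' res <- gts(X, y, family = "binomial", alpha = 0.2, seed = 1)
#' res$decision$rejected
#' @seealso \code{\link{gts_two_step}}, \code{\link{run_gts_study}}
#' @export
gts <- function(x, y, family = "binomial", alpha = 0.1,
                method = c("gts", "agts", "beta2_only", "gts_lambda"),
                regen = c("row_permutation", "full_permutation",
                          "column_permutation", "model_x_gaussian"),
                delta_c = 1.1, lam = NULL, lambda0 = 0.5, seed = NULL,
                standardize = FALSE, max_iter = 100L, tol = 1e-8) {
  method <- match.arg(method)
  regen <- match.arg(regen)
  stopifnot(alpha > 0, alpha < 1)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  if (standardize) x <- scale(x)

  aug <- augment_design(x, regen, seed)
  fit <- gts_glm_fit(aug$augmented, y, family,
                     max_iter = max_iter, tol = tol)
  blocks <- split_omega(fit$covariance)
  transform <- build_transform(blocks, delta_c)
  paired <- apply_transform(fit$coefficients, transform, blocks)
  pvalues <- paired_pvalues(paired)

  decision <- switch(method,
    gts = gts_two_step(pvalues, alpha),
    agts = adaptive_gts(pvalues, alpha, lambda0),
    beta2_only = beta2_only(pvalues, alpha),
    gts_lambda = {
      if (is.null(lam)) {
        stop("method = 'gts_lambda' requires 'lam'", call. = FALSE)
      }
      gts_lambda(pvalues, alpha, lam)
    }
  )

  structure(list(
    decision = decision,
    pvalues = pvalues,
    paired = paired,
    transform = transform,
    blocks = blocks,
    fit = fit,
    regen = aug$regen,
    names = colnames(x),
    alpha = alpha, method = method, delta_c = delta_c,
    lam = lam, seed = seed,
    call = match.call()
  ), class = "gts")
}

#' @export
print.gts <- function(x, ...) {
  cat("Generalized two-step multiple testing\n")
  cat("  family:", x$fit$family$name,
      "| regeneration:", x$regen$strategy,
      "| method:", x$method, "\n")
  cat("  n =", x$fit$n, ", d =", length(x$pvalues$p1),
      ", alpha =", x$alpha, "\n")
  cat("  screened:", length(x$decision$screened),
      "| rejected:", length(x$decision$rejected), "\n")
  if (length(x$decision$rejected)) {
    cat("  selected:", paste(x$names[x$decision$rejected], collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
coef.gts <- function(object, ...) {
  cbind(beta1 = object$paired$beta1, beta2 = object$paired$beta2)
}

#' Summary table of a generalized two-step analysis
#'
#' @param object a \code{"gts"} object.
#' @param ... unused.
#' @return A data frame with one row per coefficient: paired estimates,
#'   standard errors, the three p-values, and screening/rejection flags.
#' @export
summary.gts <- function(object, ...) {
  d <- length(object$pvalues$p1)
  out <- data.frame(
    index = seq_len(d),
    name = object$names,
    beta1 = object$paired$beta1,
    beta2 = object$paired$beta2,
    se1 = object$pvalues$se1,
    se2 = object$pvalues$se2,
    p1 = object$pvalues$p1,
    p2 = object$pvalues$p2,
    ptilde = object$pvalues$ptilde,
    screened = as.integer(seq_len(d) %in% object$decision$screened),
    rejected = as.integer(seq_len(d) %in% object$decision$rejected),
    stringsAsFactors = FALSE
  )
  class(out) <- c("summary.gts", "data.frame")
  attr(out, "header") <- list(
    alpha = object$alpha, method = object$method,
    delta_c = object$delta_c, lam = object$lam,
    strategy = object$regen$strategy, seed = object$seed,
    pi0_hat = object$decision$pi0_hat,
    care_residual = object$transform$care_residual
  )
  out
}

#' @export
print.summary.gts <- function(x, digits = 4, ...) {
  h <- attr(x, "header")
  cat("alpha =", h$alpha, "| method =", h$method,
      "| strategy =", h$strategy, "| delta_c =", h$delta_c, "\n")
  if (!is.null(h$pi0_hat)) {
    cat("pi0_hat =", format(h$pi0_hat, digits = 3), "\n")
  }
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Paired p-value diagnostic plot
#'
#' Plots \eqn{P^{(1)}} against \eqn{P^{(2)}} on the -log10 scale with the
#' screening cutoff and BH level marked; rejected coefficients are filled.
#'
#' @param x a \code{"gts"} object.
#' @param ... passed to \code{plot.default}.
#' @export
plot.gts <- function(x, ...) {
  p1 <- x$pvalues$p1
  p2 <- x$pvalues$p2
  rej <- seq_along(p1) %in% x$decision$rejected
  graphics::plot(-log10(p1), -log10(p2),
                 pch = ifelse(rej, 19, 1),
                 col = ifelse(rej, "firebrick", "grey30"),
                 xlab = expression(-log[10] ~ P^{(1)}),
                 ylab = expression(-log[10] ~ P^{(2)}), ...)
  graphics::abline(v = -log10(x$decision$lambda_cutoff), lty = 2,
                   col = "grey60")
  graphics::legend("topright", pch = c(19, 1),
                   col = c("firebrick", "grey30"),
                   legend = c("rejected", "not rejected"), bty = "n")
  invisible(x)
}

#' @export
residuals.gts <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  fit <- object$fit
  res <- fit$y - fit$fitted_means
  if (type == "pearson") {
    res <- res / sqrt(fit$family$variance(fit$fitted_means) *
                        fit$dispersion)
  }
  res
}
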