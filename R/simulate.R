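#' Synthetic GLM data for the two-step procedure
#'
#' Generators reproducing the simulation design the package is calibrated
#' against: Gaussian AR(1) covariates \eqn{\Sigma_{ij} = \rho^{|i-j|}},
#' sparse coefficients of magnitude \eqn{\mathrm{amplitude}/\sqrt n} with
#' random signs on a random support, and responses drawn from the stated
#' family.
#'
#' @param n sample size.
#' @param d number of covariates.
#' @param rho AR(1) correlation, \eqn{0 \le \rho < 1}.
#' @param seed optional RNG seed.
#' @return \code{gts_sim_design}: an \eqn{n \times d} matrix whose rows are
#'   i.i.d. \eqn{N(0, \Sigma)}, generated by the AR(1) recursion
#'   \eqn{X_{i,j+1} = \rho X_{i,j} + \sqrt{1-\rho^2}\,\varepsilon}.
#' @name gts_simulate
#' @export
gts_sim_design <- function(n, d, rho = 0.5, seed = NULL) {
  stopifnot(rho >= 0, rho < 1, n >= 1, d >= 1)
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(0, n, d)
  x[, 1] <- stats::rnorm(n)
  if (d > 1) {
    sd_innov <- sqrt(1 - rho^2)
    for (j in 2:d) {
      x[, j] <- rho * x[, j - 1] + sd_innov * stats::rnorm(n)
    }
  }
  x
}

#' @rdname gts_simulate
#' @param k number of nonzero coefficients, \eqn{k < d} (0 for a global
#'   null).
#' @param amplitude signal scalar; each nonzero entry is
#'   \eqn{\pm\,\mathrm{amplitude}/\sqrt n} with an independent fair-coin
#'   sign.
#' @return \code{gts_sim_coefficients}: numeric vector of length \code{d}
#'   with attribute \code{"support"} (the nonzero indices).
#' @export
gts_sim_coefficients <- function(d, k, amplitude, n, seed = NULL) {
  stopifnot(k >= 0, k < d)
  if (!is.null(seed)) set.seed(seed)
  beta <- numeric(d)
  support <- integer(0)
  if (k > 0 && amplitude != 0) {
    support <- sort(sample.int(d, k))
    signs <- sample(c(-1, 1), k, replace = TRUE)
    beta[support] <- signs * abs(amplitude) / sqrt(n)
  }
  attr(beta, "support") <- support
  beta
}

#' @rdname gts_simulate
#' @param x design matrix.
#' @param beta coefficient vector.
#' @param family family name or \code{\link{gts_family}} object.
#' @return \code{gts_sim_response}: response vector of length
#'   \code{nrow(x)}; Bernoulli for binomial, Poisson counts for poisson,
#'   unit-variance Gaussian noise for gaussian.
#' @export
gts_sim_response <- function(x, beta, family, seed = NULL) {
  family <- as_gts_family(family)
  if (!is.null(seed)) set.seed(seed)
  eta <- drop(as.matrix(x) %*% beta)
  if (family$name == "poisson" && any(eta > 30)) {
    stop("poisson linear predictor exceeds 30 (mean overflow); ",
         "use a smaller amplitude", call. = FALSE)
  }
  mu <- family$linkinv(eta)
  n <- length(mu)
  switch(family$name,
    gaussian = mu + stats::rnorm(n),
    binomial = stats::rbinom(n, 1, mu),
    poisson  = stats::rpois(n, mu)
  )
}

#' Study configuration for the replication harness
#'
#' Bundles a full simulation scenario.  Defaults follow the calibration
#' design of the package: logistic responses, \eqn{n = 800}, \eqn{d = 40},
#' \eqn{k = 10}, \eqn{\rho = 0.5}, \eqn{\alpha = 0.1}, 100 replications.
#'
#' @param n,d,k,rho,amplitude,alpha,seed,delta_c,lam see
#'   \code{\link{gts_simulate}} and \code{\link{gts}}.
#' @param family family name.
#' @param reps number of Monte-Carlo replications.
#' @param method decision rule, as in \code{\link{gts}}.
#' @param regen regeneration strategy.
#' @param lambda0 null-proportion tuning constant (adaptive method).
#' @param strict error (rather than warn) when more than 10\% of replicates
#'   fail to converge.
#' @return A \code{"gts_study_config"} list.
#' @export
gts_study_config <- function(n = 800, d = 40, k = 10, rho = 0.5,
                             amplitude = 6, family = "binomial",
                             alpha = 0.1, reps = 100, method = "gts",
                             regen = "row_permutation", seed = 1,
                             delta_c = 1.1, lam = NULL, lambda0 = 0.5,
                             strict = FALSE) {
  stopifnot(n > 2 * d, rho >= 0, rho < 1, k < d, reps >= 1)
  structure(list(n = n, d = d, k = k, rho = rho, amplitude = amplitude,
                 family = family, alpha = alpha, reps = reps,
                 method = method, regen = regen, seed = seed,
                 delta_c = delta_c, lam = lam, lambda0 = lambda0,
                 strict = strict),
            class = "gts_study_config")
}

# Counter-based child seed so replicates are independent and reorderable.
child_seed <- function(base, r, stream = 0L) {
  (as.integer(base) + 104729L * as.integer(r) + 7919L * as.integer(stream)) %%
    2147483647L
}

#' Run a Monte-Carlo study of empirical FDR and power
#'
#' For each replicate: generate the AR(1) design, the sparse coefficient
#' vector, and the response; run the full pipeline (regeneration, augmented
#' fit, transformation, paired p-values, the configured decision rule); and
#' record the false discovery proportion and true positive proportion.
#' Replicates whose fit fails are recorded and excluded from the rates (with
#' an escalating warning above 10\% failures).
#'
#' @param config a \code{\link{gts_study_config}}.
#' @return Object of class \code{"gts_study"}: list with \code{fdr_hat},
#'   \code{power_hat}, Monte-Carlo standard errors \code{fdr_se} and
#'   \code{power_se}, \code{n_failed}, the \code{config}, and \code{per_rep}
#'   (data frame of per-replicate \code{fdp}, \code{tpp}, \code{n_rejected},
#'   \code{converged}).
#' @examples
#' cfg <- gts_study_config(n = 200, d = 8, k = 2, amplitude = 8, reps = 3)
#' run_gts_study(cfg)
#' @export
run_gts_study <- function(config) {
  stopifnot(inherits(config, "gts_study_config"))
  reps <- config$reps
  fdp <- tpp <- rep(NA_real_, reps)
  nrej <- integer(reps)
  converged <- logical(reps)

  for (r in seq_len(reps)) {
    x <- gts_sim_design(config$n, config$d, config$rho,
                        seed = child_seed(config$seed, r, 1L))
    beta <- gts_sim_coefficients(config$d, config$k, config$amplitude,
                                 config$n,
                                 seed = child_seed(config$seed, r, 2L))
    y <- gts_sim_response(x, beta, config$family,
                          seed = child_seed(config$seed, r, 3L))
    support <- attr(beta, "support")
    nulls <- setdiff(seq_len(config$d), support)

    res <- tryCatch(
      gts(x, y, family = config$family, alpha = config$alpha,
          method = config$method, regen = config$regen,
          delta_c = config$delta_c, lam = config$lam,
          lambda0 = config$lambda0,
          seed = child_seed(config$seed, r, 4L)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    converged[r] <- TRUE
    rej <- res$decision$rejected
    nrej[r] <- length(rej)
    fdp[r] <- length(intersect(rej, nulls)) / max(length(rej), 1)
    tpp[r] <- if (length(support)) {
      length(intersect(rej, support)) / length(support)
    } else 0
  }

  n_failed <- sum(!converged)
  if (n_failed > 0.1 * reps) {
    msg <- paste0(n_failed, " of ", reps, " replicates failed to converge")
    if (isTRUE(config$strict)) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  ok <- converged
  m <- sum(ok)
  se <- function(v) if (m > 1) stats::sd(v[ok]) / sqrt(m) else NA_real_

  structure(list(
    fdr_hat = mean(fdp[ok]),
    power_hat = mean(tpp[ok]),
    fdr_se = se(fdp),
    power_se = se(tpp),
    n_failed = n_failed,
    config = config,
    per_rep = data.frame(fdp = fdp, tpp = tpp, n_rejected = nrej,
                         converged = converged)
  ), class = "gts_study")
}

#' @export
print.gts_study <- function(x, ...) {
  cfg <- x$config
  cat("GTS simulation study: ", cfg$method, ", ", cfg$family,
      ", n = ", cfg$n, ", d = ", cfg$d, ", k = ", cfg$k,
      ", rho = ", cfg$rho, ", amplitude = ", cfg$amplitude,
      ", alpha = ", cfg$alpha, "\n", sep = "")
  cat(sprintf("  empirical FDR  : %.4f (MC se %.4f)\n", x$fdr_hat, x$fdr_se))
  cat(sprintf("  empirical power: %.4f (MC se %.4f)\n",
              x$power_hat, x$power_se))
  cat("  replicates:", sum(x$per_rep$converged), "converged,",
      x$n_failed, "failed\n")
  invisible(x)
}
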