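#' Paired p-values from the transformed estimators
#'
#' Converts the paired estimators into two-sided z-test p-values against the
#' limiting normal reference: \eqn{P^{(1)}_j = 2\{1 -
#' \Phi(|\hat\beta_{1j}| / \sqrt{(\mathrm{var}_1)_{jj}})\}} and
#' \eqn{P^{(2)}_j = 2\{1 - \Phi(|\hat\beta_{2j}| / \sqrt{D_{jj}})\}}, plus the
#' step-2 p-values \eqn{\tilde P_j = \max(P^{(1)}_j, P^{(2)}_j)}.  The normal
#' (not t) reference follows from the fixed-d, large-n asymptotics the
#' procedure relies on.
#'
#' @param paired a \code{"gts_paired"} object from
#'   \code{\link{apply_transform}}.
#' @return Object of class \code{"gts_pvalues"}: list with \code{p1},
#'   \code{p2}, \code{ptilde}, and the standard errors \code{se1},
#'   \code{se2}.
#' @export
paired_pvalues <- function(paired) {
  stopifnot(inherits(paired, "gts_paired"))
  v1 <- diag(paired$var1)
  v2 <- diag(paired$var2)
  if (any(v1 <= 0) || any(v2 <= 0)) {
    stop("invalid covariance: nonpositive variance entry", call. = FALSE)
  }
  se1 <- sqrt(v1)
  se2 <- sqrt(v2)
  p1 <- 2 * stats::pnorm(abs(paired$beta1) / se1, lower.tail = FALSE)
  p2 <- 2 * stats::pnorm(abs(paired$beta2) / se2, lower.tail = FALSE)
  structure(list(p1 = p1, p2 = p2, ptilde = pmax(p1, p2),
                 se1 = se1, se2 = se2),
            class = "gts_pvalues")
}

#' Benjamini-Hochberg step-up rejections
#'
#' Step-up rule: with order statistics \eqn{p_{(1)} \le \dots \le p_{(m)}},
#' reject the \eqn{k^*} smallest where \eqn{k^* = \max\{k : p_{(k)} \le
#' k\,\mathrm{level}/m\}}.  Implemented through \code{\link[stats]{p.adjust}};
#' tied p-values share a fate.
#'
#' @param pvals p-value vector.
#' @param level BH level in (0, 1].
#' @return Integer vector of rejected indices (possibly empty).
#' @export
bh_procedure <- function(pvals, level) {
  stopifnot(level > 0, level <= 1, all(pvals >= 0 & pvals <= 1))
  if (length(pvals) == 0) return(integer(0))
  which(stats::p.adjust(pvals, method = "BH") <= level)
}

#' Two-step and related decision procedures on paired p-values
#'
#' \code{gts_two_step} is the core rule: screen on the first p-value vector
#' at cutoff \eqn{\sqrt\alpha} (step 1, non-strict inequality), then apply
#' Benjamini-Hochberg at level \eqn{\sqrt\alpha} to the step-2 p-values of
#' the survivors (step 2); the product of the two cutoffs is \eqn{\alpha} and
#' the procedure asymptotically controls the FDR at \eqn{\pi_0\alpha}.
#'
#' \code{gts_lambda} generalizes the common \eqn{\sqrt\alpha} threshold:
#' screen at \eqn{\lambda \in (\alpha, 1]}, then BH at level
#' \eqn{\alpha/\lambda}.  At \eqn{\lambda = \sqrt\alpha} it reproduces
#' \code{gts_two_step} exactly; at \eqn{\lambda = 1} screening passes
#' everything and the rule is BH at level \eqn{\alpha} on the step-2
#' p-values.
#'
#' \code{adaptive_gts} plugs the Storey-type null-proportion estimate
#' \eqn{\hat\pi_0} into the two-step rule, running it at the working level
#' \eqn{\alpha/\hat\pi_0} for asymptotic FDR control at \eqn{\alpha} (and
#' more power whenever \eqn{\hat\pi_0 < 1}).
#'
#' \code{beta2_only} skips screening and applies BH at level \eqn{\alpha}
#' directly to the second p-value vector, whose components are asymptotically
#' mutually independent.
#'
#' @param p a \code{"gts_pvalues"} object.
#' @param alpha target FDR level in (0, 1).
#' @return Object of class \code{"gts_decision"}: list with \code{rejected}
#'   and \code{screened} index sets, \code{alpha}, \code{lambda_cutoff},
#'   \code{bh_level}, \code{method}, and \code{pi0_hat} (adaptive only).
#' @examples
#' p <- structure(list(p1 = c(0.1, 0.5), p2 = c(0.01, 0.001),
#'                     ptilde = c(0.1, 0.5)), class = "gts_pvalues")
#' gts_two_step(p, alpha = 0.09)$rejected   # 1
#' @export
gts_two_step <- function(p, alpha) {
  stopifnot(inherits(p, "gts_pvalues"), alpha > 0, alpha < 1)
  two_step_at(p, cutoff = sqrt(alpha), bh_level = sqrt(alpha),
              alpha = alpha, method = "gts")
}

two_step_at <- function(p, cutoff, bh_level, alpha, method,
                        pi0_hat = NULL) {
  screened <- which(p$p1 <= cutoff)
  rejected <- screened[bh_procedure(p$ptilde[screened], bh_level)]
  structure(list(rejected = rejected, screened = screened, alpha = alpha,
                 lambda_cutoff = cutoff, bh_level = bh_level,
                 method = method, pi0_hat = pi0_hat),
            class = "gts_decision")
}

#' @rdname gts_two_step
#' @param lam screening cutoff \eqn{\lambda \in (\alpha, 1]} on the first
#'   p-value vector; the BH level becomes \eqn{\alpha/\lambda}.
#' @export
gts_lambda <- function(p, alpha, lam) {
  stopifnot(inherits(p, "gts_pvalues"), alpha > 0, alpha < 1)
  if (lam <= alpha || lam > 1) {
    stop("lam must lie in (alpha, 1]", call. = FALSE)
  }
  two_step_at(p, cutoff = lam, bh_level = alpha / lam, alpha = alpha,
              method = "gts_lambda")
}

#' Storey-type estimate of the null proportion
#'
#' \eqn{\hat\pi_0 = \min\{1, (1 + \#\{j : P^{(2)}_j > \lambda_0\}) /
#' (d(1-\lambda_0))\}}.  The second p-value vector is used because its
#' components are asymptotically mutually independent.
#'
#' @param p2 vector of step-2 marginal p-values.
#' @param lambda0 tuning constant in (0, 1); default 0.5.
#' @return Scalar estimate in (0, 1].
#' @export
estimate_pi0 <- function(p2, lambda0 = 0.5) {
  stopifnot(lambda0 > 0, lambda0 < 1)
  d <- length(p2)
  min(1, (1 + sum(p2 > lambda0)) / (d * (1 - lambda0)))
}

#' @rdname gts_two_step
#' @param lambda0 tuning constant for \code{\link{estimate_pi0}}.
#' @export
adaptive_gts <- function(p, alpha, lambda0 = 0.5) {
  stopifnot(inherits(p, "gts_pvalues"), alpha > 0, alpha < 1)
  pi0_hat <- estimate_pi0(p$p2, lambda0)
  alpha_work <- min(1 - 1e-12, alpha / pi0_hat)
  out <- two_step_at(p, cutoff = sqrt(alpha_work),
                     bh_level = sqrt(alpha_work), alpha = alpha,
                     method = "agts", pi0_hat = pi0_hat)
  out
}

#' @rdname gts_two_step
#' @export
beta2_only <- function(p, alpha) {
  stopifnot(inherits(p, "gts_pvalues"), alpha > 0, alpha < 1)
  d <- length(p$p2)
  structure(list(rejected = bh_procedure(p$p2, alpha),
                 screened = seq_len(d), alpha = alpha,
                 lambda_cutoff = 1, bh_level = alpha,
                 method = "beta2_only", pi0_hat = NULL),
            class = "gts_decision")
}

#' @export
print.gts_decision <- function(x, ...) {
  cat("GTS decision (", x$method, "), alpha = ", x$alpha, "\n",
      "  screened: ", length(x$screened), " | rejected: ",
      length(x$rejected), sep = "")
  if (length(x$rejected)) {
    cat(" [", paste(x$rejected, collapse = ", "), "]", sep = "")
  }
  cat("\n")
  if (!is.null(x$pi0_hat)) {
    cat("  estimated null proportion:", format(x$pi0_hat, digits = 3), "\n")
  }
  invisible(x)
}
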