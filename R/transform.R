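#' Decorrelating transformation of the augmented-fit estimator
#'
#' From the estimated covariance \eqn{\hat\Omega} of the augmented-model
#' estimator \eqn{\hat\theta = (\hat\theta_1^T, \hat\theta_2^T)^T}, these
#' functions construct the block transformation
#' \deqn{Z = \begin{bmatrix} I & P \\ I & V \end{bmatrix}}
#' such that the paired estimators \eqn{\hat\beta_1 = \hat\theta_1 +
#' P\hat\theta_2} and \eqn{\hat\beta_2 = \hat\theta_1 + V\hat\theta_2} are
#' asymptotically independent (the off-diagonal block of
#' \eqn{Z\hat\Omega Z^T} vanishes) and the components of \eqn{\hat\beta_2}
#' are asymptotically mutually independent (its covariance equals a diagonal
#' matrix \eqn{D}).
#'
#' Writing \eqn{\hat\Omega = [[J, K], [K^T, N]]} in \eqn{d \times d} blocks,
#' the diagonal target is \eqn{D = \delta_c \lambda_{\max}(J) I} with
#' \eqn{\delta_c \ge 1} (so \eqn{H = D - J} is positive semi-definite), the
#' symmetric \eqn{V} solves the continuous algebraic Riccati equation with
#' \eqn{F = -K^T}, \eqn{G = N}, \eqn{H = D - J}, and then
#' \eqn{P = -(J + KV^T)(K^T + NV^T)^{-1}}.
#'
#' @param omega symmetric positive-definite \eqn{2d \times 2d} covariance.
#' @return \code{split_omega}: list of class \code{"gts_omega_blocks"} with
#'   \eqn{J}, \eqn{K}, \eqn{N}.
#' @name gts_transform
NULL

#' @rdname gts_transform
#' @export
split_omega <- function(omega) {
  omega <- as.matrix(omega)
  m <- nrow(omega)
  if (m != ncol(omega) || m %% 2 != 0) {
    stop("omega must be square with even dimension", call. = FALSE)
  }
  if (max(abs(omega - t(omega))) > 1e-8 * (1 + max(abs(omega)))) {
    stop("invalid covariance: omega is not symmetric within tolerance",
         call. = FALSE)
  }
  d <- m %/% 2
  J <- omega[seq_len(d), seq_len(d), drop = FALSE]
  K <- omega[seq_len(d), d + seq_len(d), drop = FALSE]
  N <- omega[d + seq_len(d), d + seq_len(d), drop = FALSE]
  structure(list(J = (J + t(J)) / 2, K = K, N = (N + t(N)) / 2, d = d),
            class = "gts_omega_blocks")
}

#' @rdname gts_transform
#' @param J symmetric \eqn{d \times d} top-left block of \eqn{\hat\Omega}.
#' @param delta_c multiplicative constant \eqn{\delta_c \ge 1} scaling the
#'   largest eigenvalue of \eqn{J}; default 1.1, which keeps the variance of
#'   the second estimator low (higher power) while leaving \eqn{D - J}
#'   strictly positive definite.
#' @export
choose_D <- function(J, delta_c = 1.1) {
  if (delta_c < 1) {
    stop("delta_c must be >= 1 so that D - J is positive semi-definite",
         call. = FALSE)
  }
  J <- as.matrix(J)
  lam_max <- max(eigen((J + t(J)) / 2, symmetric = TRUE,
                       only.values = TRUE)$values)
  diag(delta_c * lam_max, nrow(J), nrow(J))
}

#' @rdname gts_transform
#' @param blocks result of \code{split_omega}.
#' @return \code{build_transform}: object of class \code{"gts_transform"}
#'   with \code{P}, \code{V}, \code{D}, \code{delta_c} and
#'   \code{care_residual}.
#' @export
build_transform <- function(blocks, delta_c = 1.1) {
  stopifnot(inherits(blocks, "gts_omega_blocks"))
  J <- blocks$J; K <- blocks$K; N <- blocks$N
  D <- choose_D(J, delta_c)
  V <- solve_care(-t(K), N, D - J)
  B <- t(K) + N %*% t(V)
  if (rcond_of(B) < 1e-12) {
    stop("transform failure: K' + N V' is numerically singular; ",
         "a larger delta_c may help", call. = FALSE)
  }
  # P = -(J + K V') (K' + N V')^{-1} via factorized solve
  P <- -t(solve(t(B), t(J + K %*% t(V))))
  structure(list(P = P, V = unclass_matrix(V), D = D, delta_c = delta_c,
                 care_residual = attr(V, "residual")),
            class = "gts_transform")
}

unclass_matrix <- function(v) {
  attr(v, "residual") <- NULL
  attr(v, "closed_loop_eigenvalues") <- NULL
  v
}

#' @export
print.gts_transform <- function(x, ...) {
  cat("GTS transform: d = ", nrow(x$P), ", delta_c = ", x$delta_c,
      ", D = ", format(x$D[1, 1], digits = 4), " * I, CARE residual = ",
      format(x$care_residual, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @rdname gts_transform
#' @param theta_hat augmented-fit coefficient vector of length \eqn{2d}.
#' @param transform a \code{"gts_transform"} object.
#' @return \code{apply_transform}: object of class \code{"gts_paired"} with
#'   \code{beta1}, \code{beta2}, \code{var1} (covariance of
#'   \eqn{\hat\beta_1}) and \code{var2} (\eqn{= D}, diagonal).
#' @export
apply_transform <- function(theta_hat, transform, blocks) {
  stopifnot(inherits(transform, "gts_transform"),
            inherits(blocks, "gts_omega_blocks"))
  d <- blocks$d
  if (length(theta_hat) != 2 * d) {
    stop("theta_hat must have length 2d = ", 2 * d, call. = FALSE)
  }
  th1 <- theta_hat[seq_len(d)]
  th2 <- theta_hat[d + seq_len(d)]
  P <- transform$P; V <- transform$V
  J <- blocks$J; K <- blocks$K; N <- blocks$N
  var1 <- J + P %*% t(K) + K %*% t(P) + P %*% N %*% t(P)
  structure(list(
    beta1 = drop(th1 + P %*% th2),
    beta2 = drop(th1 + V %*% th2),
    var1 = (var1 + t(var1)) / 2,
    var2 = transform$D
  ), class = "gts_paired")
}
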