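#' Stabilizing solution of a continuous algebraic Riccati equation
#'
#' Solves \eqn{F^T V + V F - V G V + H = 0} for the stabilizing solution
#' \eqn{V} (the one making \eqn{F - GV} stable, i.e. all eigenvalues with
#' negative real part) by the Schur method: form the Hamiltonian
#' \deqn{\Phi = \begin{bmatrix} F & -G \\ -H & -F^T \end{bmatrix},}
#' compute a real Schur factorization with the \eqn{d} stable eigenvalues
#' ordered to the leading block (LAPACK \code{dgees} with sorting), and read
#' the solution off the stable invariant subspace as
#' \eqn{V = U_{21} U_{11}^{-1}}, symmetrized as \eqn{(V + V^T)/2}.
#'
#' @param F,G,H numeric \eqn{d \times d} matrices; \code{G} and \code{H} must
#'   be symmetric positive semi-definite.
#' @return The symmetric stabilizing solution \eqn{V}, with attributes
#'   \code{residual} (Frobenius norm of the equation residual) and
#'   \code{closed_loop_eigenvalues} (eigenvalues of \eqn{F - GV}).
#' @examples
#' solve_care(matrix(0), matrix(1), matrix(1))   # scalar: V = 1
#' @export
solve_care <- function(F, G, H) {
  F <- as.matrix(F); G <- as.matrix(G); H <- as.matrix(H)
  d <- nrow(F)
  stopifnot(ncol(F) == d, all(dim(G) == d), all(dim(H) == d))
  if (max(abs(G - t(G))) > 1e-8 * (1 + max(abs(G))) ||
      max(abs(H - t(H))) > 1e-8 * (1 + max(abs(H)))) {
    stop("G and H must be symmetric", call. = FALSE)
  }

  Phi <- rbind(cbind(F, -G), cbind(-H, -t(F)))
  sc <- .Call(C_schur_ordered, Phi)
  if (sc$info > 2L * d) {
    # dgees info in (n, n+1]: reordering failed; <= n: QR failure
    stop("Schur reordering failed (LAPACK info = ", sc$info, ")",
         call. = FALSE)
  }
  if (sc$info > 0L) {
    stop("Schur decomposition did not converge (LAPACK info = ", sc$info,
         ")", call. = FALSE)
  }
  if (any(abs(sc$wr) < 1e-10)) {
    stop("no stabilizing solution: Hamiltonian has eigenvalues on the ",
         "imaginary axis", call. = FALSE)
  }
  if (sc$sdim != d) {
    stop("no stabilizing solution: Hamiltonian has ", sc$sdim,
         " stable eigenvalues, expected ", d, call. = FALSE)
  }

  U11 <- sc$vs[seq_len(d), seq_len(d), drop = FALSE]
  U21 <- sc$vs[d + seq_len(d), seq_len(d), drop = FALSE]
  if (rcond_of(U11) < 1e-12) {
    stop("ill-conditioned invariant subspace: U11 is numerically singular",
         call. = FALSE)
  }
  V <- t(solve(t(U11), t(U21)))
  asym <- max(abs(V - t(V)))
  if (asym > 1e-6 * (1 + norm(V, "F"))) {
    warning("CARE solution asymmetry ", format(asym, digits = 3),
            " before symmetrization; solver quality may be poor",
            call. = FALSE)
  }
  V <- (V + t(V)) / 2

  resid <- t(F) %*% V + V %*% F - V %*% G %*% V + H
  res_norm <- norm(resid, "F")
  if (res_norm > 1e-6 * (1 + norm(H, "F"))) {
    stop("CARE residual ", format(res_norm, digits = 3),
         " exceeds tolerance; no acceptable stabilizing solution",
         call. = FALSE)
  }
  cl_eig <- eigen(F - G %*% V, only.values = TRUE)$values
  if (any(Re(cl_eig) >= 0)) {
    stop("computed solution is not stabilizing: F - GV has a nonnegative ",
         "closed-loop eigenvalue", call. = FALSE)
  }
  attr(V, "residual") <- res_norm
  attr(V, "closed_loop_eigenvalues") <- cl_eig
  V
}

# reciprocal 1-norm condition estimate; 0 for exactly singular input
rcond_of <- function(a) {
  out <- tryCatch(rcond(a), error = function(e) 0)
  if (!is.finite(out)) 0 else out
}
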