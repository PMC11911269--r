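#' GLM family descriptors for the generalized two-step procedure
#'
#' Constructs the family object used throughout the package: the inverse link,
#' the mean-variance relationship, and the derived iteratively-reweighted
#' least squares weight \eqn{w_i = (d\mu_i/d\eta_i)^2 / \mathrm{var}(Y_i)}.
#' Three canonical-link families are supported: gaussian/identity,
#' binomial/logit and poisson/log.
#'
#' For the gaussian family the weights are constant \eqn{1/\sigma^2}; the
#' dispersion \eqn{\sigma^2} is estimated from Pearson residuals at fit time
#' (rule \code{"pearson_estimate"}).  Binomial and poisson dispersion is fixed
#' at 1 (rule \code{"fixed_one"}).
#'
#' @param family character, one of \code{"gaussian"}, \code{"binomial"},
#'   \code{"poisson"}.  Partial matching is not performed.
#' @return An object of class \code{"gts_family"}: a list with elements
#'   \code{name}, \code{linkfun} (\eqn{\mu \to \eta}), \code{linkinv}
#'   (\eqn{\eta \to \mu}), \code{mu.eta} (\eqn{d\mu/d\eta}), \code{variance}
#'   (\eqn{\mu \to \mathrm{var}(Y)} up to dispersion), \code{dispersion_rule},
#'   \code{validmu}, \code{validy} and \code{initialize} (starting means).
#' @examples
#' fam <- gts_family("binomial")
#' fam$variance(0.5)        # 0.25
#' gts_weights(fam, 0.5)    # 0.25
#' @export
gts_family <- function(family = c("gaussian", "binomial", "poisson")) {
  family <- match.arg(family)
  fam <- switch(family,
    gaussian = list(
      name = "gaussian",
      linkfun = function(mu) mu,
      linkinv = function(eta) eta,
      mu.eta = function(eta) rep.int(1, length(eta)),
      variance = function(mu) rep.int(1, length(mu)),
      dispersion_rule = "pearson_estimate",
      validmu = function(mu) all(is.finite(mu)),
      validy = function(y) is.numeric(y) && all(is.finite(y)),
      initialize = function(y) y
    ),
    binomial = list(
      name = "binomial",
      linkfun = function(mu) log(mu / (1 - mu)),
      linkinv = function(eta) 1 / (1 + exp(-eta)),
      mu.eta = function(eta) {
        p <- 1 / (1 + exp(-eta))
        p * (1 - p)
      },
      variance = function(mu) mu * (1 - mu),
      dispersion_rule = "fixed_one",
      validmu = function(mu) all(is.finite(mu)) && all(mu > 0 & mu < 1),
      validy = function(y) all(y %in% c(0, 1)),
      initialize = function(y) (y + 0.5) / 2
    ),
    poisson = list(
      name = "poisson",
      linkfun = function(mu) log(mu),
      linkinv = function(eta) exp(eta),
      mu.eta = function(eta) exp(eta),
      variance = function(mu) mu,
      dispersion_rule = "fixed_one",
      validmu = function(mu) all(is.finite(mu)) && all(mu > 0),
      validy = function(y) {
        all(y >= 0) && all(abs(y - round(y)) < sqrt(.Machine$double.eps))
      },
      initialize = function(y) y + 0.1
    )
  )
  structure(fam, class = "gts_family")
}

#' @rdname gts_family
#' @param object a \code{"gts_family"} object.
#' @param mu vector of fitted means, inside the family's valid mean range.
#' @param dispersion dispersion parameter; only the gaussian family uses it
#'   (weights are \code{1/dispersion}).
#' @details \code{gts_weights} returns the per-observation IRLS weight
#'   evaluated at the fitted means: \eqn{\mu(1-\mu)} for binomial/logit,
#'   \eqn{\mu} for poisson/log (canonical links make
#'   \eqn{(d\mu/d\eta)^2/\mathrm{var}} collapse to the variance function),
#'   and the constant \eqn{1/\sigma^2} for gaussian/identity.
#' @export
gts_weights <- function(object, mu, dispersion = 1) {
  stopifnot(inherits(object, "gts_family"))
  if (!object$validmu(mu)) {
    stop("fitted means outside the valid range for the ", object$name,
         " family", call. = FALSE)
  }
  switch(object$name,
    gaussian = rep.int(1 / dispersion, length(mu)),
    binomial = mu * (1 - mu),
    poisson  = mu
  )
}

#' @export
print.gts_family <- function(x, ...) {
  link <- switch(x$name, gaussian = "identity", binomial = "logit",
                 poisson = "log")
  cat("GTS family:", x$name, "(", link, "link ), dispersion:",
      x$dispersion_rule, "\n")
  invisible(x)
}

# Accepts a name or an already-built family; used by user-facing entry points.
as_gts_family <- function(family) {
  if (inherits(family, "gts_family")) return(family)
  if (is.character(family) && length(family) == 1) {
    if (family == "logistic") family <- "binomial"  # common alias
    return(gts_family(family))
  }
  stop("'family' must be a family name or a 'gts_family' object",
       call. = FALSE)
}
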