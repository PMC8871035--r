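## Observed Fisher information by the missing-information principle:
## I_obs = m * I_A + n * I_B - sum_i [ s_i * I_{U|w_i} + t_i * I_{V|w_i} ],
## where I_A, I_B are per-unit expected informations under the full IERD and
## the subtracted blocks are expected informations of the truncated
## (missing) lifetimes given survival past the censoring time.
##
## All second partials of log f are analytic. Writing a = 1/x^2 and
## t = 1 - e^(-lambda * a) (so t ~ theta * t^(theta-1) on (0,1) under the
## model):
##   d2/dtheta2          = -1/theta^2
##   d2/dtheta dlambda   =  a (1-t)/t
##   d2/dlambda2         = -1/lambda^2 - (theta-1) a^2 (1-t)/t^2
## The (theta1, theta2) cross-entries vanish: each unit's density involves
## only its own sample's shape.

info_quad <- function(f, quad_tol = 1e-10, upper = 1) {
  out <- stats::integrate(f, 0, upper, rel.tol = quad_tol,
                          stop.on.error = FALSE)
  if (!is.finite(out$value)) {
    stop("information-matrix quadrature failed: ", out$message, call. = FALSE)
  }
  out$value
}

## Per-unit expected information under the full IERD, entries (theta,theta),
## (theta,lambda), (lambda,lambda)
full_unit_info <- function(theta, lambda, quad_tol = 1e-10) {
  a_of <- function(t) -log1p(-t) / lambda
  i_tl <- -info_quad(function(t) {
    theta * t^(theta - 1) * a_of(t) * (1 - t) / t
  }, quad_tol)
  i_ll <- 1 / lambda^2 + (theta - 1) * info_quad(function(t) {
    theta * t^(theta - 1) * a_of(t)^2 * (1 - t) / t^2
  }, quad_tol)
  c(tt = 1 / theta^2, tl = i_tl, ll = i_ll)
}

## Expected information of a lifetime truncated to (w, Inf): conditional
## density adds -theta * log(tau) to log f, tau = 1 - e^(-lambda/w^2).
## Quadrature runs over y = lambda/u^2 in (0, lambda/w^2) with the
## truncated density in log space, stable for any tau. In y terms
##   E[a (1-t)/t]     = (1/lambda)   E[Y e^{-Y} / (1-e^{-Y})]
##   E[a^2 (1-t)/t^2] = (1/lambda^2) E[Y^2 e^{-Y} / (1-e^{-Y})^2]
cond_unit_info <- function(w, theta, lambda, quad_tol = 1e-10) {
  aw <- 1 / w^2
  yw <- lambda * aw
  log_tau <- log1mexp(yw)
  tau <- exp(log_tau)
  hw <- exp(-yw)  # 1 - tau
  ldens <- function(y) {
    log(theta) + (theta - 1) * log1mexp(y) - y - theta * log_tau
  }
  e_cross <- info_quad(function(y) {
    y / lambda * exp(ldens(y) - y - log1mexp(y))
  }, quad_tol, upper = yw)
  e_ll <- info_quad(function(y) {
    (y / lambda)^2 * exp(ldens(y) - y - 2 * log1mexp(y))
  }, quad_tol, upper = yw)
  c(tt = 1 / theta^2,
    tl = -e_cross + aw * hw / tau,
    ll = 1 / lambda^2 + (theta - 1) * e_ll - theta * aw^2 * hw / tau^2)
}

#' Observed Fisher information for the two-sample IERD JPC model
#'
#' Computes the 3x3 observed information matrix (parameter order `theta1`,
#' `theta2`, `lambda`) by the missing-information principle: the expected
#' complete-data information of all `m + n` units minus the expected
#' information carried by the censored lifetimes, each conditional on
#' survival past its withdrawal time. Expectations are one-dimensional
#' adaptive quadratures over the probability-scale substitution
#' \eqn{t = 1 - e^{-\lambda/u^2}}.
#'
#' @param data a [jpc_data()] record.
#' @param theta1,theta2,lambda evaluation point, typically the MLE.
#' @param quad_tol relative quadrature tolerance.
#' @return An object of class `observed_info`: the symmetric matrix with a
#'   `params` attribute.
#' @seealso [estimate_covariance()]
#' @export
observed_info <- function(data, theta1, theta2, lambda, quad_tol = 1e-10) {
  stopifnot(inherits(data, "jpc_data"))
  check_ierd_params(theta1, lambda)
  check_ierd_params(theta2, lambda)
  m <- data$design$m; n <- data$design$n
  w <- data$w; s <- data$s; t <- data$t
  iA <- full_unit_info(theta1, lambda, quad_tol)
  iB <- full_unit_info(theta2, lambda, quad_tol)
  M <- matrix(0, 3, 3, dimnames = list(c("theta1", "theta2", "lambda"),
                                       c("theta1", "theta2", "lambda")))
  M[1, 1] <- m * iA["tt"]; M[1, 3] <- M[3, 1] <- m * iA["tl"]
  M[2, 2] <- n * iB["tt"]; M[2, 3] <- M[3, 2] <- n * iB["tl"]
  M[3, 3] <- m * iA["ll"] + n * iB["ll"]
  for (i in which(s > 0)) {
    ci <- cond_unit_info(w[i], theta1, lambda, quad_tol)
    M[1, 1] <- M[1, 1] - s[i] * ci["tt"]
    M[1, 3] <- M[3, 1] <- M[1, 3] - s[i] * ci["tl"]
    M[3, 3] <- M[3, 3] - s[i] * ci["ll"]
  }
  for (i in which(t > 0)) {
    ci <- cond_unit_info(w[i], theta2, lambda, quad_tol)
    M[2, 2] <- M[2, 2] - t[i] * ci["tt"]
    M[2, 3] <- M[3, 2] <- M[2, 3] - t[i] * ci["tl"]
    M[3, 3] <- M[3, 3] - t[i] * ci["ll"]
  }
  if (any(!is.finite(M))) {
    stop("non-finite entry in the observed information matrix", call. = FALSE)
  }
  structure(M, class = c("observed_info", "matrix"),
            params = c(theta1 = theta1, theta2 = theta2, lambda = lambda))
}

#' Estimator covariance matrix
#'
#' Inverts the observed information matrix; the diagonal supplies the
#' per-parameter variances used by the Bootstrap-t pivots. A matrix that is
#' not numerically positive definite raises a conditioning error reporting
#' the eigenvalues (callers such as the Bootstrap-t loop drop the offending
#' replicate); no silent pseudo-inverse is substituted.
#'
#' @param data a [jpc_data()] record.
#' @param theta1,theta2,lambda evaluation point, typically the MLE.
#' @param quad_tol relative quadrature tolerance.
#' @return The symmetric 3x3 covariance matrix.
#' @export
estimate_covariance <- function(data, theta1, theta2, lambda,
                                quad_tol = 1e-10) {
  M <- observed_info(data, theta1, theta2, lambda, quad_tol)
  ev <- eigen(unclass(M), symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0) || min(ev) / max(ev) < 1e-12) {
    stop("observed information matrix is not positive definite ",
         "(eigenvalues: ", paste(signif(ev, 4), collapse = ", "), ")",
         call. = FALSE)
  }
  V <- solve(unclass(M))
  dimnames(V) <- dimnames(M)
  V
}
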