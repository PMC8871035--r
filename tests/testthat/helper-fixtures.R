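# Shared fixtures, built in code.

rel_err <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.eps)

# A small deterministic JPC record (k = 5, one withdrawal pattern) used by
# likelihood and Bayes unit tests.
toy_jpc <- function() {
  design <- jpc_design(m = 6, n = 5, k = 5, removals = c(2, 0, 1, 0, 3))
  jpc_data(w = c(0.6, 0.8, 1.1, 1.5, 2.2),
           s = c(1L, 0L, 1L, 0L, 1L),
           t = c(1L, 0L, 0L, 0L, 2L),
           z = c(1L, 0L, 1L, 1L, 0L),
           design = design)
}

# A slightly larger toy (k = 8) for posterior-oracle comparisons.
toy_jpc8 <- function() {
  design <- jpc_design(m = 8, n = 7, k = 8, removals = c(3, 0, 0, 2, 0, 0, 0, 2))
  jpc_data(w = c(0.5, 0.7, 0.9, 1.0, 1.3, 1.6, 2.0, 2.6),
           s = c(1L, 0L, 0L, 1L, 0L, 0L, 0L, 1L),
           t = c(2L, 0L, 0L, 1L, 0L, 0L, 0L, 1L),
           z = c(1L, 0L, 1L, 1L, 0L, 1L, 0L, 1L),
           design = design)
}

# Designs spanning the simulation study's sample sizes, used by the
# EM-vs-direct agreement battery.
battery_designs <- function() {
  list(
    jpc_design(25, 20, 20, "(0^9,25,0^10)"),
    jpc_design(25, 20, 20, "(10,0^18,15)"),
    jpc_design(25, 20, 30, "(5,0^28,10)"),
    jpc_design(25, 20, 30, "(0^12,3^5,0^13)"),
    jpc_design(45, 40, 40, "(0^17,9^5,0^18)")
  )
}

# Simulate one non-degenerate dataset for a design (test-local helper).
sim_nondeg <- function(design, theta1 = 3, theta2 = 2, lambda = 2,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    x <- simulate_jpc(design, theta1, theta2, lambda)
    if (!is_degenerate(x)) return(x)
  }
}

# Observed-data likelihood evaluated independently as the raw product form
# (density and survival factors), for cross-checking observed_loglik.
product_loglik <- function(data, theta1, theta2, lambda) {
  w <- data$w; z <- data$z; s <- data$s; t <- data$t
  th <- ifelse(z == 1, theta1, theta2)
  sum(log(2 * lambda) + log(th) - 3 * log(w) - lambda / w^2 +
        (th - 1) * log(1 - exp(-lambda / w^2))) +
    sum((theta1 * s + theta2 * t) * log(1 - exp(-lambda / w^2)))
}

# Deterministic grid-quadrature oracle for posterior means on a small
# record: integrates the marginal scale posterior (gamma kernel times the
# weight correction) and the conditional gamma means of the shapes.
posterior_oracle <- function(data, prior) {
  w <- data$w; s <- data$s; t <- data$t; z <- data$z
  k <- length(w); kk1 <- sum(z); kk2 <- k - kk1
  B1 <- function(l) prior$b1 - sum((s + z) * log(1 - exp(-l / w^2)))
  B2 <- function(l) prior$b2 - sum((t + 1 - z) * log(1 - exp(-l / w^2)))
  log_kernel <- function(l) {
    (prior$c + k - 1) * log(l) - (prior$d + sum(1 / w^2)) * l -
      (prior$a1 + kk1) * log(B1(l)) - (prior$a2 + kk2) * log(B2(l)) -
      sum(log(1 - exp(-l / w^2)))
  }
  shift <- optimize(log_kernel, c(1e-3, 100), maximum = TRUE)$objective
  f0 <- function(l) exp(vapply(l, log_kernel, 0) - shift)
  Z <- integrate(f0, 0, Inf, rel.tol = 1e-10)$value
  mean_of <- function(h) {
    integrate(function(l) vapply(l, h, 0) * f0(l), 0, Inf,
              rel.tol = 1e-10)$value / Z
  }
  c(theta1 = mean_of(function(l) (prior$a1 + kk1) / B1(l)),
    theta2 = mean_of(function(l) (prior$a2 + kk2) / B2(l)),
    lambda = mean_of(identity))
}
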