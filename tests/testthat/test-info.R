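# Finite-difference + quadrature oracle for the information matrix:
# expectations of numeric second differences of the log-density (full or
# truncated), integrated on the lifetime domain.
fd_hessian_expect <- function(logf, dens, lower, theta, lam, h = 1e-4) {
  d2 <- function(f2) {
    # central second differences in (theta, lambda)
    list(
      tt = function(x) (f2(x, theta + h, lam) - 2 * f2(x, theta, lam) +
                          f2(x, theta - h, lam)) / h^2,
      tl = function(x) (f2(x, theta + h, lam + h) - f2(x, theta + h, lam - h) -
                          f2(x, theta - h, lam + h) + f2(x, theta - h, lam - h)) /
        (4 * h^2),
      ll = function(x) (f2(x, theta, lam + h) - 2 * f2(x, theta, lam) +
                          f2(x, theta, lam - h)) / h^2
    )
  }
  ds <- d2(logf)
  vapply(ds, function(g) {
    -integrate(function(x) g(x) * dens(x), lower, Inf, rel.tol = 1e-8,
               stop.on.error = FALSE)$value
  }, numeric(1))
}

test_that("information entries match the finite-difference oracle", {
  d <- jpc_design(3, 3, 2, c(2, 2))
  x <- jpc_data(w = c(0.8, 1.4), s = c(1L, 1L), t = c(1L, 1L),
                z = c(1L, 0L), design = d)
  th1 <- 2.5; th2 <- 1.5; lam <- 1.8
  M <- observed_info(x, th1, th2, lam)

  full_blk <- function(theta) {
    fd_hessian_expect(function(u, a, b) dierd(u, a, b, log = TRUE),
                      function(u) dierd(u, theta, lam),
                      0, theta, lam)
  }
  cond_blk <- function(w, theta) {
    fd_hessian_expect(
      function(u, a, b) dierd(u, a, b, log = TRUE) -
        pierd(w, a, b, lower.tail = FALSE, log.p = TRUE),
      function(u) dierd(u, theta, lam) /
        pierd(w, theta, lam, lower.tail = FALSE),
      w, theta, lam)
  }
  iA <- full_blk(th1); iB <- full_blk(th2)
  cA <- lapply(x$w, cond_blk, theta = th1)
  cB <- lapply(x$w, cond_blk, theta = th2)
  oracle <- matrix(0, 3, 3)
  oracle[1, 1] <- 3 * iA["tt"] - sum(x$s * vapply(cA, `[[`, 0, "tt"))
  oracle[2, 2] <- 3 * iB["tt"] - sum(x$t * vapply(cB, `[[`, 0, "tt"))
  oracle[1, 3] <- oracle[3, 1] <-
    3 * iA["tl"] - sum(x$s * vapply(cA, `[[`, 0, "tl"))
  oracle[2, 3] <- oracle[3, 2] <-
    3 * iB["tl"] - sum(x$t * vapply(cB, `[[`, 0, "tl"))
  oracle[3, 3] <- 3 * iA["ll"] + 3 * iB["ll"] -
    sum(x$s * vapply(cA, `[[`, 0, "ll")) -
    sum(x$t * vapply(cB, `[[`, 0, "ll"))
  expect_equal(unclass(M), oracle, tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("structure: symmetry, zero shape cross-entry, exact shape diagonal", {
  x <- toy_jpc()
  M <- observed_info(x, 2, 1.5, 1.2)
  expect_identical(M[1, 2], 0)
  expect_identical(M[2, 1], 0)
  expect_equal(unclass(M), t(unclass(M)), ignore_attr = TRUE)
  ## d2 log f / d theta2 = -1/theta^2 for full and truncated units alike,
  ## so the shape diagonal is exactly (m - sum(s)) / theta^2
  expect_equal(M[1, 1], (x$design$m - sum(x$s)) / 2^2, tolerance = 1e-12)
  expect_equal(M[2, 2], (x$design$n - sum(x$t)) / 1.5^2, tolerance = 1e-12)
})

test_that("with no withdrawals the matrix is the full-sample information", {
  d <- jpc_design(4, 3, 7, rep(0, 7))
  set.seed(3)
  x <- apply_jpc(rierd(4, 3, 2), rierd(3, 2, 2), d)
  M <- observed_info(x, 3, 2, 2)
  # information of one A unit plus one B unit scales linearly: the same
  # evaluation on a doubled design must double every entry
  d2 <- jpc_design(8, 6, 14, rep(0, 14))
  set.seed(3)
  x2 <- apply_jpc(rierd(8, 3, 2), rierd(6, 2, 2), d2)
  M2 <- observed_info(x2, 3, 2, 2)
  expect_equal(unclass(M2), 2 * unclass(M), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("covariance is a genuine inverse and positive definite at the MLE", {
  d <- jpc_design(40, 40, 30, "(10,0^28,40)")
  x <- sim_nondeg(d, seed = 12)
  f <- direct_fit(x, init = c(3, 2, 2))
  e <- f$estimates
  M <- observed_info(x, e[[1]], e[[2]], e[[3]])
  V <- estimate_covariance(x, e[[1]], e[[2]], e[[3]])
  expect_equal(unclass(M) %*% V, diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diag(V) > 0))
})

test_that("more observed failures mean smaller estimator variances", {
  d20 <- jpc_design(25, 20, 20, "(0^9,25,0^10)")
  d40 <- jpc_design(25, 20, 40, "(0^19,5,0^20)")
  v <- lapply(list(d20, d40), function(d) {
    vs <- vapply(1:10, function(s) {
      x <- sim_nondeg(d, seed = 400 + s)
      f <- direct_fit(x, init = c(3, 2, 2))
      e <- f$estimates
      diag(estimate_covariance(x, e[[1]], e[[2]], e[[3]]))
    }, numeric(3))
    rowMeans(vs)
  })
  expect_true(all(v[[2]] < v[[1]]))
})

test_that("covariance diagonals track the sampling variance of the MLE", {
  d <- jpc_design(25, 20, 30, "(0^12,3^5,0^13)")
  n_sim <- 300
  est <- matrix(NA_real_, n_sim, 3)
  vars <- matrix(NA_real_, n_sim, 3)
  for (i in seq_len(n_sim)) {
    x <- sim_nondeg(d, seed = 5000 + i)
    f <- direct_fit(x, init = c(3, 2, 2))
    est[i, ] <- f$estimates
    e <- f$estimates
    vars[i, ] <- tryCatch(
      diag(estimate_covariance(x, e[[1]], e[[2]], e[[3]])),
      error = function(err) rep(NA_real_, 3))
  }
  emp <- apply(est, 2, var)
  avg <- colMeans(vars, na.rm = TRUE)
  ## expected-information approximation: agree within a factor of two
  expect_true(all(emp / avg < 2 & emp / avg > 0.5))
})
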