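test_that("observed log-likelihood reduces to complete-data form without censoring", {
  d <- jpc_design(4, 3, 7, rep(0, 7))
  set.seed(21)
  a <- rierd(4, 3, 2); b <- rierd(3, 2, 2)
  x <- apply_jpc(a, b, d)
  ll <- observed_loglik(x, 3.1, 1.9, 2.2)
  direct <- sum(dierd(a, 3.1, 2.2, log = TRUE)) +
    sum(dierd(b, 1.9, 2.2, log = TRUE))
  expect_equal(ll, direct, tolerance = 1e-10)
})

test_that("log-likelihood differences match the raw product form", {
  x <- toy_jpc()
  pts <- list(c(2, 1.5, 1), c(3, 2, 2), c(0.8, 4, 0.5), c(1, 1, 1))
  for (i in 1:3) {
    p <- pts[[i]]; q <- pts[[i + 1]]
    d1 <- observed_loglik(x, p[1], p[2], p[3]) -
      observed_loglik(x, q[1], q[2], q[3])
    d2 <- product_loglik(x, p[1], p[2], p[3]) -
      product_loglik(x, q[1], q[2], q[3])
    expect_equal(d1, d2, tolerance = 1e-9)
  }
})

test_that("with no failures from one sample the likelihood decreases in its shape", {
  d <- jpc_design(2, 4, 3, c(1, 0, 2))
  x <- jpc_data(w = c(0.5, 0.8, 1.2), s = c(1L, 0L, 1L), t = c(0L, 0L, 1L),
                z = c(0L, 0L, 0L), design = d)  # k1 = 0
  th1_grid <- c(0.5, 1, 2, 4, 8)
  ll <- vapply(th1_grid, function(th1) observed_loglik(x, th1, 2, 2),
               numeric(1))
  expect_true(all(diff(ll) < 0))
  expect_error(em_fit(x), "no MLE")
  expect_error(direct_fit(x), "no MLE")
})

test_that("the closed-form E-step expectation matches raw quadrature", {
  for (p in list(c(0.7, 1.5, 2), c(2.0, 3, 0.8), c(1.2, 0.6, 5))) {
    w <- p[1]; th <- p[2]; lam <- p[3]
    cm <- conditional_moments(w, th, lam)
    ## oracle: quadrature of the raw truncated density on the u-domain
    surv <- pierd(w, th, lam, lower.tail = FALSE)
    orc <- integrate(function(u) log(1 - exp(-lam / u^2)) *
                       dierd(u, th, lam) / surv,
                     w, Inf, rel.tol = 1e-10,
                     stop.on.error = FALSE)$value
    expect_equal(cm$e_log_g, orc, tolerance = 1e-8)
    expect_equal(cm$e_log_g, log(1 - exp(-lam / w^2)) - 1 / th,
                 tolerance = 1e-12)
  }
})

test_that("truncated second-moment expectations match their closed forms", {
  # theta = 1 admits a closed form for E[U^-2 | U > w]
  for (p in list(c(0.9, 2), c(1.5, 1), c(0.4, 3))) {
    w <- p[1]; lam <- p[2]
    cm <- conditional_moments(w, 1, lam)
    e <- exp(-lam / w^2)
    closed <- (1 - e - (lam / w^2) * e) / (lam * (1 - e))
    expect_equal(cm$e_inv_u2, closed, tolerance = 1e-8)
  }
  # support bound: the truncated lifetime exceeds w
  for (p in list(c(0.7, 1.5, 2), c(2.0, 3, 0.8))) {
    cm <- conditional_moments(p[1], p[2], p[3])
    expect_lt(cm$e_inv_u2, 1 / p[1]^2)
    expect_gt(cm$e_inv_u2, 0)
    expect_gt(cm$e_log_u, log(p[1]))
  }
})

test_that("EM and the direct optimizer find the same maximum", {
  designs <- battery_designs()
  for (seed in 1:20) {
    d <- designs[[(seed %% length(designs)) + 1]]
    x <- sim_nondeg(d, seed = seed)
    fe <- em_fit(x, init = c(3, 2, 2))
    fd <- direct_fit(x, init = c(3, 2, 2))
    expect_true(all(rel_err(fe$estimates, fd$estimates) < 1e-3),
                info = paste("seed", seed))
    expect_gte(fd$loglik, fe$loglik - 1e-6)
  }
})

test_that("EM ascends the observed likelihood and reports convergence", {
  d <- jpc_design(25, 20, 30, "(5,0^28,10)")
  x <- sim_nondeg(d, seed = 99)
  fit <- em_fit(x, init = c(3, 2, 2))
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$estimates)) && all(fit$estimates > 0))
  ll0 <- observed_loglik(x, 3, 2, 2)
  expect_gte(fit$loglik, ll0 - 1e-6)
  ## trace records every iterate, ending at the estimates
  expect_identical(nrow(fit$trace), fit$iterations + 1L)
  expect_equal(unname(fit$trace[nrow(fit$trace), ]),
               unname(fit$estimates), tolerance = 1e-12)
})

test_that("the complete coating record reproduces the joint MLE", {
  cw <- coating_weights()
  k <- length(cw$tcs) + length(cw$bcs)
  d <- jpc_design(72, 72, k, rep(0, k))
  x <- apply_jpc(cw$tcs, cw$bcs, d)
  fe <- em_fit(x)
  jm <- joint_complete_mle(cw$tcs, cw$bcs)
  expect_equal(unname(fe$estimates),
               c(jm$theta1, jm$theta2, jm$lambda), tolerance = 1e-4)
  fd <- direct_fit(x)
  expect_equal(unname(fd$estimates), unname(fe$estimates), tolerance = 1e-3)
})

test_that("estimation error shrinks as more failures are observed", {
  ## same truth and sample sizes, k = 20 vs k = 40
  d20 <- jpc_design(45, 40, 20, "(30,0^18,35)")
  d40 <- jpc_design(45, 40, 40, "(0^17,9^5,0^18)")
  truth <- c(3, 2, 2)
  se <- matrix(0, 2, 3)
  for (j in 1:2) {
    d <- list(d20, d40)[[j]]
    est <- t(vapply(1:40, function(s) {
      direct_fit(sim_nondeg(d, seed = 1000 + s), init = truth)$estimates
    }, numeric(3)))
    se[j, ] <- colMeans((est - matrix(truth, 40, 3, byrow = TRUE))^2)
  }
  ## MSE of the scale estimate decreases with k
  expect_lt(se[2, 3], se[1, 3])
})
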