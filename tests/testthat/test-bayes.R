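test_that("importance weights are a normalized, finite distribution", {
  x <- toy_jpc8()
  dr <- importance_sample(x, informative_prior(), n_draws = 2000, seed = 1)
  expect_equal(sum(dr$weights), 1, tolerance = 1e-12)
  expect_true(all(is.finite(dr$weights)) && all(dr$weights >= 0))
  expect_true(all(dr$theta1 > 0) && all(dr$theta2 > 0) && all(dr$lambda > 0))
  expect_gt(dr$ess, 0.05 * dr$n_draws)
  ## reproducible
  dr2 <- importance_sample(x, informative_prior(), n_draws = 2000, seed = 1)
  expect_identical(dr$weights, dr2$weights)
})

test_that("posterior means match the grid-quadrature oracle on a small record", {
  ## the conjugate (textbook-decomposition) proposal still mixes on a
  ## record this small; the Laplace default is checked just below
  x <- toy_jpc8()
  for (prior in list(informative_prior(), noninformative_prior())) {
    orc <- posterior_oracle(x, prior)
    dr <- importance_sample(x, prior, n_draws = 40000, seed = 5,
                            proposal = "conjugate")
    est <- c(estimate_square(dr, "theta1"),
             estimate_square(dr, "theta2"),
             estimate_square(dr, "lambda"))
    expect_true(all(rel_err(est, orc) < 0.02),
                info = paste("rel err:",
                             paste(signif(rel_err(est, orc), 3),
                                   collapse = " ")))
  }
})

test_that("loss-function estimators honor their algebraic identities", {
  x <- toy_jpc8()
  dr <- importance_sample(x, informative_prior(), n_draws = 3000, seed = 9)
  kappa <- function(t1, t2, l) rep(4.2, length(t1))
  expect_equal(estimate_square(dr, kappa), 4.2, tolerance = 1e-12)
  expect_equal(estimate_linex(dr, kappa, delta = 2), 4.2, tolerance = 1e-10)
  expect_equal(estimate_linex(dr, kappa, delta = -1.3), 4.2,
               tolerance = 1e-10)
  ## delta -> 0 limit recovers the posterior mean
  for (g in c("theta1", "theta2", "lambda")) {
    expect_equal(estimate_linex(dr, g, delta = 1e-6),
                 estimate_square(dr, g), tolerance = 1e-4)
    ## Jensen direction for positive delta
    expect_lte(estimate_linex(dr, g, delta = 2), estimate_square(dr, g))
  }
  expect_error(estimate_linex(dr, "lambda", delta = 0), "nonzero")
})

test_that("credible intervals follow the weighted-quantile walk rule", {
  ## uniform weights: plain order statistics
  dr <- structure(list(theta1 = 1:100, theta2 = 1:100, lambda = 1:100,
                       weights = rep(0.01, 100), n_draws = 100),
                  class = "ierd_isdraws")
  ci <- credible_interval(dr, "lambda", alpha = 0.10)
  ## walk rule: first cumulative weight >= 0.05, last < 0.95 (the exact
  ## boundary index depends on floating-point cumsum ties)
  expect_true(ci$lower %in% c(5, 6))
  expect_true(ci$upper %in% c(94, 95))
  ## nesting: wider credibility gives a (weakly) wider interval
  x <- toy_jpc8()
  d2 <- importance_sample(x, informative_prior(), n_draws = 4000, seed = 3)
  ci10 <- credible_interval(d2, "theta1", alpha = 0.10)
  ci02 <- credible_interval(d2, "theta1", alpha = 0.02)
  expect_lte(ci02$lower, ci10$lower)
  expect_gte(ci02$upper, ci10$upper)
  ## all weight on one atom degenerates to a point
  one <- structure(list(theta1 = c(2, 3), theta2 = c(2, 3),
                        lambda = c(2, 3), weights = c(1, 0), n_draws = 2),
                   class = "ierd_isdraws")
  ci1 <- credible_interval(one, "lambda", alpha = 0.1)
  expect_identical(ci1$lower, ci1$upper)
})

test_that("credible intervals usually contain the posterior mean", {
  x <- toy_jpc8()
  hits <- 0L
  for (s in 1:50) {
    dr <- importance_sample(x, informative_prior(), n_draws = 800, seed = s)
    ci <- credible_interval(dr, "lambda", alpha = 0.10)
    mu <- estimate_square(dr, "lambda")
    if (ci$lower <= mu && mu <= ci$upper) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.95)
})

test_that("both proposals target the same posterior on a small record", {
  x <- toy_jpc8()
  orc <- posterior_oracle(x, informative_prior())
  dr <- importance_sample(x, informative_prior(), n_draws = 40000,
                          seed = 7, proposal = "laplace")
  est <- c(estimate_square(dr, "theta1"), estimate_square(dr, "theta2"),
           estimate_square(dr, "lambda"))
  expect_true(all(rel_err(est, orc) < 0.02))
  expect_gt(dr$ess, 0.5 * dr$n_draws)
})

test_that("flat-prior posterior agrees with the MLE on the full coating record", {
  ## the fitted shapes are large here, which pushes the scale posterior far
  ## from the conjugate gamma proposal; the mode-matched proposal is the
  ## supported route for this regime
  cw <- coating_weights()
  k <- 144
  d <- jpc_data(w = sort(c(cw$tcs, cw$bcs)), s = rep(0L, k), t = rep(0L, k),
                z = as.integer(order(c(cw$tcs, cw$bcs)) <= 72),
                design = jpc_design(72, 72, k, rep(0L, k)))
  jm <- joint_complete_mle(cw$tcs, cw$bcs)
  dr <- importance_sample(d, noninformative_prior(), n_draws = 5000,
                          seed = 2, proposal = "laplace")
  expect_gt(dr$ess, 0.05 * dr$n_draws)
  mle <- c(jm$theta1, jm$theta2, jm$lambda)
  post <- c(estimate_square(dr, "theta1"), estimate_square(dr, "theta2"),
            estimate_square(dr, "lambda"))
  expect_true(all(rel_err(post, mle) < 0.10))
  ## the conjugate proposal's collapse is detectable from its ESS
  drc <- importance_sample(d, noninformative_prior(), n_draws = 5000,
                           seed = 2, proposal = "conjugate")
  expect_lt(drc$ess, 0.01 * drc$n_draws)
})
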