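## Parametric Bootstrap-p and Bootstrap-t confidence intervals.

boot_order_index <- function(frac, n_boot) {
  ## largest integer not exceeding frac * N, clamped into 1..N; the small
  ## offset keeps binary fractions like (1 - 0.9)/2 from flooring one low
  min(max(floor(frac * n_boot + 1e-9), 1L), n_boot)
}

refit_one <- function(data, init, fit_method) {
  if (fit_method == "em") em_fit(data, init = init) else
    direct_fit(data, init = init)
}

## Simulate and refit n_boot parametric replicates from a parent fit.
## Degenerate draws (k1 or k2 = 0, no MLE) are redrawn from the running RNG
## stream, counted against max_redraws. When with_cov is TRUE, each
## replicate's estimator variances (inverse observed information at its own
## estimates) are recorded; replicates whose information matrix fails the
## conditioning check are dropped.
boot_replicates <- function(data, est, n_boot, max_redraws, fit_method,
                            with_cov = FALSE) {
  design <- data$design
  out <- matrix(NA_real_, n_boot, 3,
                dimnames = list(NULL, c("theta1", "theta2", "lambda")))
  vars <- if (with_cov) matrix(NA_real_, n_boot, 3,
                               dimnames = dimnames(out)) else NULL
  redraws <- 0L; dropped <- 0L
  for (i in seq_len(n_boot)) {
    repeat {
      rep_data <- simulate_jpc(design, est[["theta1"]], est[["theta2"]],
                               est[["lambda"]])
      if (!is_degenerate(rep_data)) break
      redraws <- redraws + 1L
      if (redraws > max_redraws) {
        stop("too many degenerate bootstrap replicates (", redraws,
             " redraws); the fitted parameters give one sample almost no ",
             "chance to fail within the scheme", call. = FALSE)
      }
    }
    fit_i <- refit_one(rep_data, init = est, fit_method = fit_method)
    out[i, ] <- fit_i$estimates
    if (with_cov) {
      v <- tryCatch(diag(estimate_covariance(rep_data,
                                             fit_i$estimates[["theta1"]],
                                             fit_i$estimates[["theta2"]],
                                             fit_i$estimates[["lambda"]])),
                    error = function(e) NULL)
      if (is.null(v)) dropped <- dropped + 1L else vars[i, ] <- v
    }
  }
  list(estimates = out, vars = vars, redraws = redraws, dropped = dropped)
}

make_intervals <- function(lower, upper, level, method) {
  data.frame(parameter = c("theta1", "theta2", "lambda"),
             lower = lower, upper = upper,
             level = level, method = method,
             row.names = NULL)
}

#' Parametric Bootstrap-p confidence intervals
#'
#' Fits the model, simulates `n_boot` new jointly censored datasets from the
#' fitted parameters under the same design, refits each, and returns the
#' percentile (Bootstrap-p) intervals: for each parameter the
#' \eqn{\lfloor \alpha N/2 \rfloor}-th and
#' \eqn{\lfloor (1-\alpha/2) N \rfloor}-th order statistics of the replicate
#' estimates (indices clamped into `1..N`). Replicates in which every
#' failure comes from one sample have no MLE and are redrawn, up to
#' `max_redraws` in total.
#'
#' @param data a [jpc_data()] record.
#' @param n_boot number of bootstrap replicates N.
#' @param level confidence level 1 - alpha (default 0.90).
#' @param seed optional integer seed.
#' @param max_redraws cap on redraws of degenerate replicates
#'   (default `10 * n_boot`).
#' @param fit_method `"em"` (default) or `"direct"`: estimator used for the
#'   parent fit and each replicate refit. Replicate refits start from the
#'   parent estimates.
#' @param init optional starting values for the parent fit.
#' @return An object of class `ierd_boot`: list with `intervals` (a
#'   data frame with one row per parameter), `fit` (the parent `ierd_fit`),
#'   `replicates` (the N x 3 matrix of replicate estimates), `redraws`,
#'   `level` and `method`.
#' @examples
#' d <- jpc_design(25, 20, 30, "(5,0^28,10)")
#' x <- simulate_jpc(d, 3, 2, 2, seed = 5)
#' bootstrap_p(x, n_boot = 50, seed = 1, fit_method = "direct")
#' @export
bootstrap_p <- function(data, n_boot = 1000, level = 0.90, seed = NULL,
                        max_redraws = 10 * n_boot,
                        fit_method = c("em", "direct"), init = NULL) {
  stopifnot(inherits(data, "jpc_data"), n_boot >= 2, level > 0, level < 1)
  fit_method <- match.arg(fit_method)
  if (!is.null(seed)) set.seed(seed)
  fit <- refit_one(data, init = init, fit_method = fit_method)
  reps <- boot_replicates(data, fit$estimates, n_boot, max_redraws,
                          fit_method)
  alpha <- 1 - level
  lb <- boot_order_index(alpha / 2, n_boot)
  hb <- boot_order_index(1 - alpha / 2, n_boot)
  sorted <- apply(reps$estimates, 2, sort)
  structure(list(
    intervals = make_intervals(sorted[lb, ], sorted[hb, ], level, "boot-p"),
    fit = fit, replicates = reps$estimates, redraws = reps$redraws,
    level = level, method = "boot-p"
  ), class = "ierd_boot")
}

#' Parametric Bootstrap-t confidence intervals
#'
#' As [bootstrap_p()], but each replicate is studentized:
#' \eqn{T^{(i)} = (\hat\vartheta^{(i)} - \hat\vartheta) /
#' \sqrt{\widehat{Var}(\hat\vartheta^{(i)})}}, with the replicate variance
#' taken from the inverse observed information at the replicate's own
#' estimates. The interval for each parameter is
#' \eqn{[\hat\vartheta - \hat\sigma T_{(hb)},\;
#'       \hat\vartheta - \hat\sigma T_{(lb)}]},
#' where \eqn{\hat\sigma} is the original fit's standard error. Replicates
#' whose information matrix fails the positive-definiteness check are
#' dropped; more than 20% dropped is an error.
#'
#' @inheritParams bootstrap_p
#' @return An `ierd_boot` object; `replicates` carries the estimates and
#'   `pivots` the studentized statistics actually used (dropped replicates
#'   excluded), `dropped` their count.
#' @export
bootstrap_t <- function(data, n_boot = 1000, level = 0.90, seed = NULL,
                        max_redraws = 10 * n_boot,
                        fit_method = c("em", "direct"), init = NULL) {
  stopifnot(inherits(data, "jpc_data"), n_boot >= 2, level > 0, level < 1)
  fit_method <- match.arg(fit_method)
  if (!is.null(seed)) set.seed(seed)
  fit <- refit_one(data, init = init, fit_method = fit_method)
  est <- fit$estimates
  se0 <- sqrt(diag(estimate_covariance(data, est[["theta1"]],
                                       est[["theta2"]], est[["lambda"]])))
  reps <- boot_replicates(data, est, n_boot, max_redraws, fit_method,
                          with_cov = TRUE)
  keep <- stats::complete.cases(reps$vars)
  if (sum(!keep) > 0.2 * n_boot) {
    stop(sum(!keep), " of ", n_boot, " bootstrap replicates had an ",
         "ill-conditioned information matrix (> 20%); Bootstrap-t is not ",
         "reliable here", call. = FALSE)
  }
  pivots <- (reps$estimates[keep, , drop = FALSE] -
               matrix(est, sum(keep), 3, byrow = TRUE)) /
    sqrt(reps$vars[keep, , drop = FALSE])
  n_eff <- nrow(pivots)
  alpha <- 1 - level
  lb <- boot_order_index(alpha / 2, n_eff)
  hb <- boot_order_index(1 - alpha / 2, n_eff)
  sorted <- apply(pivots, 2, sort)
  structure(list(
    intervals = make_intervals(est - se0 * sorted[hb, ],
                               est - se0 * sorted[lb, ], level, "boot-t"),
    fit = fit, replicates = reps$estimates[keep, , drop = FALSE],
    pivots = pivots, se = se0,
    redraws = reps$redraws, dropped = reps$dropped,
    level = level, method = "boot-t"
  ), class = "ierd_boot")
}

#' @export
print.ierd_boot <- function(x, ...) {
  cat("Parametric bootstrap intervals (", x$method, "), level ",
      x$level, ", N = ", nrow(x$replicates), "\n", sep = "")
  print(transform(x$intervals, lower = round(lower, 4),
                  upper = round(upper, 4)))
  invisible(x)
}
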