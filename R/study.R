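## Packaged real data and the Monte Carlo study driver.

#' Coating-weight datasets
#'
#' The two 72-observation coating-weight samples (mg/m2, chemical
#' procedure) measured on the top center side (TCS) and bottom center side
#' (BCS) of galvanized iron sheets from the ALAF industry, Tanzania. For
#' analysis the raw values are conventionally divided by 10, which is the
#' default here.
#'
#' @param scaled logical; divide the raw values by 10 (default `TRUE`).
#' @return A list with numeric vectors `tcs` and `bcs`, each of length 72.
#' @examples
#' cw <- coating_weights()
#' sapply(cw, length)
#' cw$tcs[1]   # 3.68
#' @export
coating_weights <- function(scaled = TRUE) {
  read_one <- function(name) {
    path <- system.file("extdata", name, package = "ierdjpc",
                        mustWork = TRUE)
    scan(path, comment.char = "#", quiet = TRUE)
  }
  out <- list(tcs = read_one("coating_tcs.txt"),
              bcs = read_one("coating_bcs.txt"))
  if (scaled) out <- lapply(out, function(v) v / 10)
  out
}

## Order-independent per-replicate seed fan-out from a master seed
replicate_seed <- function(seed, r) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) + 104729 * r) %% 2147483647L)
}

## Simulate one non-degenerate dataset, counting redraws
simulate_nondegenerate <- function(design, truth, seed, max_redraws = 1000) {
  if (!is.null(seed)) set.seed(seed)
  redraws <- 0L
  repeat {
    x <- simulate_jpc(design, truth[["theta1"]], truth[["theta2"]],
                      truth[["lambda"]])
    if (!is_degenerate(x)) return(list(data = x, redraws = redraws))
    redraws <- redraws + 1L
    if (redraws > max_redraws) {
      stop("could not draw a non-degenerate dataset in ", max_redraws,
           " attempts", call. = FALSE)
    }
  }
}

#' Monte Carlo study of the point estimators
#'
#' Simulates `n_reps` jointly censored datasets from known parameters, runs
#' each requested estimator, and summarizes the average value (AV) and mean
#' squared error (MSE) of each parameter estimate. Degenerate draws (all
#' failures from one sample, no MLE) are redrawn and counted.
#'
#' Estimators:
#' \describe{
#'   \item{`mle-true-init`}{EM algorithm started at the true parameters.}
#'   \item{`mle-7-init`}{EM started at (7, 7, 7).}
#'   \item{`bayes-square`, `bayes-linex`}{importance-sampling posterior
#'     estimates under squared-error / linex loss with the given prior.}
#' }
#'
#' @param design a [jpc_design()].
#' @param truth named vector `c(theta1=, theta2=, lambda=)` of true values.
#' @param n_reps number of Monte Carlo replicates.
#' @param estimators subset of
#'   `c("mle-true-init", "mle-7-init", "bayes-square", "bayes-linex")`.
#' @param prior a [gamma_prior()] for the Bayes estimators.
#' @param n_draws importance-sample size per replicate.
#' @param delta linex constant.
#' @param seed master seed; per-replicate seeds are derived from it
#'   independently of execution order.
#' @param max_fail_frac error out if more than this fraction of replicate
#'   fits fail.
#' @return An object of class `jpc_study`: list with `summary` (data frame
#'   of AV and MSE by estimator and parameter), `estimates` (list of
#'   `n_reps` x 3 matrices, one per estimator, from which the summary is
#'   recomputable), `degenerate` (redraw count), `failures`, `truth`,
#'   `design`, `n_reps`.
#' @examples
#' d <- jpc_design(25, 20, 30, "(5,0^28,10)")
#' s <- run_point_study(d, c(theta1 = 3, theta2 = 2, lambda = 2),
#'                      n_reps = 5, estimators = "mle-true-init", seed = 1)
#' s$summary
#' @export
run_point_study <- function(design,
                            truth = c(theta1 = 3, theta2 = 2, lambda = 2),
                            n_reps = 1000,
                            estimators = "mle-true-init",
                            prior = informative_prior(),
                            n_draws = 5000, delta = 2, seed = NULL,
                            max_fail_frac = 0.05) {
  stopifnot(inherits(design, "jpc_design"), n_reps >= 1)
  estimators <- match.arg(estimators,
                          c("mle-true-init", "mle-7-init",
                            "bayes-square", "bayes-linex"),
                          several.ok = TRUE)
  truth <- truth[c("theta1", "theta2", "lambda")]
  store <- lapply(estimators, function(e)
    matrix(NA_real_, n_reps, 3,
           dimnames = list(NULL, c("theta1", "theta2", "lambda"))))
  names(store) <- estimators
  degenerate <- 0L; failures <- 0L
  needs_bayes <- any(startsWith(estimators, "bayes"))
  for (r in seq_len(n_reps)) {
    sim <- simulate_nondegenerate(design, truth, replicate_seed(seed, r))
    degenerate <- degenerate + sim$redraws
    dat <- sim$data
    dr <- if (needs_bayes) importance_sample(dat, prior, n_draws) else NULL
    for (e in estimators) {
      est <- tryCatch(switch(e,
        "mle-true-init" = em_fit(dat, init = as.numeric(truth))$estimates,
        "mle-7-init"    = em_fit(dat, init = c(7, 7, 7))$estimates,
        "bayes-square"  = vapply(c("theta1", "theta2", "lambda"),
                                 function(p) estimate_square(dr, p),
                                 numeric(1)),
        "bayes-linex"   = vapply(c("theta1", "theta2", "lambda"),
                                 function(p) estimate_linex(dr, p, delta),
                                 numeric(1))),
        error = function(err) NULL)
      if (is.null(est)) failures <- failures + 1L
      else store[[e]][r, ] <- est
    }
  }
  if (failures > max_fail_frac * n_reps * length(estimators)) {
    stop(failures, " replicate fits failed (more than ",
         100 * max_fail_frac, "% of the study)", call. = FALSE)
  }
  summary <- do.call(rbind, lapply(estimators, function(e) {
    est <- store[[e]]
    data.frame(estimator = e,
               parameter = colnames(est),
               av = colMeans(est, na.rm = TRUE),
               mse = colMeans((est - matrix(truth, n_reps, 3,
                                            byrow = TRUE))^2, na.rm = TRUE),
               row.names = NULL)
  }))
  structure(list(summary = summary, estimates = store,
                 degenerate = degenerate, failures = failures,
                 truth = truth, design = design, n_reps = n_reps),
            class = "jpc_study")
}

#' Monte Carlo study of the interval estimators
#'
#' Simulates `n_reps` datasets and computes the requested intervals on
#' each, summarizing the average length (AL) and empirical coverage
#' percentage (CP) per parameter.
#'
#' Methods: `"boot-p"`, `"boot-t"` (parametric bootstrap with `n_boot`
#' replicates each), `"credible-IP"` (importance-sampling credible interval
#' under the informative prior preset), `"credible-NIP"` (under the
#' non-informative preset).
#'
#' @inheritParams run_point_study
#' @param methods subset of
#'   `c("boot-p", "boot-t", "credible-IP", "credible-NIP")`.
#' @param level confidence/credibility level.
#' @param n_boot bootstrap replicates per dataset.
#' @param fit_method estimator used inside the bootstrap
#'   (see [bootstrap_p()]).
#' @return A `jpc_study` object whose `summary` holds `al` and `cp` per
#'   method and parameter, and whose `intervals` element stores the raw
#'   per-replicate bounds.
#' @export
run_interval_study <- function(design,
                               truth = c(theta1 = 3, theta2 = 2, lambda = 2),
                               n_reps = 1000,
                               methods = "boot-p",
                               level = 0.90, n_boot = 1000, n_draws = 5000,
                               fit_method = "em",
                               seed = NULL, max_fail_frac = 0.05) {
  stopifnot(inherits(design, "jpc_design"), n_reps >= 1)
  methods <- match.arg(methods,
                       c("boot-p", "boot-t", "credible-IP", "credible-NIP"),
                       several.ok = TRUE)
  truth <- truth[c("theta1", "theta2", "lambda")]
  store <- lapply(methods, function(m)
    array(NA_real_, c(n_reps, 3, 2),
          dimnames = list(NULL, c("theta1", "theta2", "lambda"),
                          c("lower", "upper"))))
  names(store) <- methods
  degenerate <- 0L; failures <- 0L
  for (r in seq_len(n_reps)) {
    sim <- simulate_nondegenerate(design, truth, replicate_seed(seed, r))
    degenerate <- degenerate + sim$redraws
    dat <- sim$data
    for (mth in methods) {
      iv <- tryCatch(switch(mth,
        "boot-p" = bootstrap_p(dat, n_boot = n_boot, level = level,
                               fit_method = fit_method)$intervals,
        "boot-t" = bootstrap_t(dat, n_boot = n_boot, level = level,
                               fit_method = fit_method)$intervals,
        "credible-IP" = {
          dr <- importance_sample(dat, informative_prior(), n_draws)
          do.call(rbind, lapply(c("theta1", "theta2", "lambda"),
                                function(p)
                                  credible_interval(dr, p, 1 - level)))
        },
        "credible-NIP" = {
          dr <- importance_sample(dat, noninformative_prior(), n_draws)
          do.call(rbind, lapply(c("theta1", "theta2", "lambda"),
                                function(p)
                                  credible_interval(dr, p, 1 - level)))
        }),
        error = function(err) NULL)
      if (is.null(iv)) failures <- failures + 1L
      else {
        store[[mth]][r, , "lower"] <- iv$lower
        store[[mth]][r, , "upper"] <- iv$upper
      }
    }
  }
  if (failures > max_fail_frac * n_reps * length(methods)) {
    stop(failures, " replicate interval fits failed (more than ",
         100 * max_fail_frac, "% of the study)", call. = FALSE)
  }
  summary <- do.call(rbind, lapply(methods, function(mth) {
    lo <- store[[mth]][, , "lower", drop = FALSE][, , 1]
    hi <- store[[mth]][, , "upper", drop = FALSE][, , 1]
    lo <- matrix(lo, n_reps, 3); hi <- matrix(hi, n_reps, 3)
    tr <- matrix(truth, n_reps, 3, byrow = TRUE)
    data.frame(method = mth,
               parameter = c("theta1", "theta2", "lambda"),
               al = colMeans(hi - lo, na.rm = TRUE),
               cp = colMeans(lo <= tr & tr <= hi, na.rm = TRUE),
               row.names = NULL)
  }))
  structure(list(summary = summary, intervals = store,
                 degenerate = degenerate, failures = failures,
                 truth = truth, design = design, n_reps = n_reps,
                 level = level),
            class = "jpc_study")
}

#' @export
print.jpc_study <- function(x, ...) {
  cat("Monte Carlo study:", x$n_reps, "replicates, design m =",
      x$design$m, "n =", x$design$n, "k =", x$design$k, "\n")
  cat("truth:", paste(names(x$truth), "=", x$truth, collapse = ", "), "\n")
  if (x$degenerate > 0)
    cat("degenerate draws redrawn:", x$degenerate, "\n")
  df <- x$summary
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 4)
  print(df)
  invisible(x)
}
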