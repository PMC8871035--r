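#' JSON emission for fitted objects
#'
#' Serializes results in a stable, flat JSON layout suitable for the
#' command-line tools and downstream pipelines: fits as
#' `{estimates, loglik, iterations, converged}`, information matrices as a
#' labelled 3x3 array, bootstrap results as their interval table, and
#' importance draws as their posterior summary.
#'
#' @param x an `ierd_fit`, `observed_info`, `ierd_boot` or `ierd_isdraws`
#'   object.
#' @param ... passed on to methods (`bayes_summary()` arguments for
#'   `ierd_isdraws`).
#' @return A JSON string (class `json`).
#' @examples
#' d <- jpc_design(25, 20, 30, "(5,0^28,10)")
#' x <- simulate_jpc(d, 3, 2, 2, seed = 2)
#' as_json(direct_fit(x, init = c(3, 2, 2)))
#' @export
as_json <- function(x, ...) UseMethod("as_json")

#' @export
as_json.ierd_fit <- function(x, ...) {
  jsonlite::toJSON(list(estimates = as.list(x$estimates),
                        loglik = x$loglik,
                        iterations = x$iterations,
                        converged = x$converged,
                        method = x$method),
                   auto_unbox = TRUE, digits = NA)
}

#' @export
as_json.observed_info <- function(x, ...) {
  jsonlite::toJSON(list(parameters = rownames(x),
                        matrix = unclass(x)),
                   auto_unbox = TRUE, digits = NA)
}

#' @export
as_json.ierd_boot <- function(x, ...) {
  jsonlite::toJSON(list(method = x$method, level = x$level,
                        estimates = as.list(x$fit$estimates),
                        intervals = x$intervals),
                   auto_unbox = TRUE, digits = NA)
}

#' @export
as_json.ierd_isdraws <- function(x, ...) {
  jsonlite::toJSON(list(n_draws = x$n_draws, ess = x$ess,
                        summary = bayes_summary(x, ...)),
                   auto_unbox = TRUE, digits = NA)
}
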