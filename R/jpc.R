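#' Joint progressive type-II censoring designs
#'
#' A joint progressive type-II censoring (JPC) design pools two samples --
#' sample A with `m` units and sample B with `n` units -- on one life test.
#' At the i-th observed failure, `removals[i]` of the surviving units are
#' withdrawn from the pooled risk set; the test stops at the `k`-th failure,
#' when all remaining survivors are withdrawn. The removal counts must
#' satisfy `sum(removals + 1) == m + n`, which guarantees the design is
#' feasible at every stage.
#'
#' @param m number of units in sample A.
#' @param n number of units in sample B.
#' @param k number of failures to observe.
#' @param removals either an integer vector `r[1..k]` of withdrawal counts,
#'   or a compact scheme string such as `"(0^9,25,0^10)"` (see
#'   [parse_scheme()]).
#'
#' @return An object of class `jpc_design`: a list with elements `m`, `n`,
#'   `k` and `removals`.
#' @seealso [parse_scheme()], [apply_jpc()], [simulate_jpc()]
#' @examples
#' jpc_design(m = 25, n = 20, k = 20, removals = "(0^9,25,0^10)")
#' @export
jpc_design <- function(m, n, k, removals) {
  stopifnot(length(m) == 1, length(n) == 1, length(k) == 1)
  m <- as.integer(m); n <- as.integer(n); k <- as.integer(k)
  if (m < 1 || n < 1 || k < 1) {
    stop("'m', 'n' and 'k' must be positive integers", call. = FALSE)
  }
  if (is.character(removals)) removals <- parse_scheme(removals, k)
  removals <- as.integer(removals)
  if (length(removals) != k || any(removals < 0)) {
    stop("'removals' must be a vector of ", k, " non-negative integers",
         call. = FALSE)
  }
  if (k > m + n) stop("'k' cannot exceed m + n", call. = FALSE)
  if (sum(removals + 1L) != m + n) {
    stop("infeasible design: sum(removals + 1) must equal m + n (got ",
         sum(removals + 1L), ", need ", m + n, ")", call. = FALSE)
  }
  structure(list(m = m, n = n, k = k, removals = removals),
            class = "jpc_design")
}

#' Expand a compact removal-scheme string
#'
#' Censoring schemes are conventionally written in a run-length form such as
#' `"(0^5,5^5,0^10)"`, meaning: no withdrawals at the first 5 failures, 5
#' units withdrawn at each of the next 5, none at the last 10. The
#' parenthesised repeat form `"(0(5),5(5),0(10))"` is accepted as a synonym.
#'
#' @param text a scheme string.
#' @param k the expected number of failures; the expansion must have exactly
#'   this length.
#' @return An integer vector of length `k`.
#' @examples
#' parse_scheme("(0^5,5^5,0^10)", k = 20)
#' parse_scheme("(10,0(18),15)", k = 20)
#' @export
parse_scheme <- function(text, k) {
  stopifnot(is.character(text), length(text) == 1)
  s <- gsub("\\s", "", text)
  s <- sub("^\\(", "", sub("\\)$", "", s))
  tokens <- strsplit(s, ",", fixed = TRUE)[[1]]
  out <- integer(0)
  for (tok in tokens) {
    hit <- regmatches(tok, regexec("^([0-9]+)(?:\\^([0-9]+)|\\(([0-9]+)\\))?$",
                                   tok))[[1]]
    if (length(hit) == 0) {
      stop("malformed scheme token '", tok, "' in '", text, "'",
           call. = FALSE)
    }
    val <- as.integer(hit[2])
    rep_n <- if (nzchar(hit[3])) as.integer(hit[3])
             else if (nzchar(hit[4])) as.integer(hit[4]) else 1L
    out <- c(out, rep(val, rep_n))
  }
  if (length(out) != k) {
    stop("scheme '", text, "' expands to length ", length(out),
         ", expected k = ", k, call. = FALSE)
  }
  out
}

#' Construct a JPC data record
#'
#' Bundles the observed record of a jointly progressively censored
#' experiment: the ordered failure times `w`, the per-failure withdrawal
#' counts from samples A (`s`) and B (`t`), and the source indicators `z`
#' (1 if the failure came from sample A).
#'
#' @param w strictly increasing vector of the `k` observed failure times.
#' @param s,t integer vectors: withdrawals from samples A and B at each
#'   failure; `s + t` must reproduce the design's removal vector.
#' @param z 0/1 indicators of each failure's source sample.
#' @param design a [jpc_design()].
#' @return An object of class `jpc_data`.
#' @export
jpc_data <- function(w, s, t, z, design) {
  stopifnot(inherits(design, "jpc_design"))
  k <- design$k
  if (length(w) != k || length(s) != k || length(t) != k || length(z) != k) {
    stop("'w', 's', 't', 'z' must all have length k = ", k, call. = FALSE)
  }
  if (any(w <= 0) || is.unsorted(w)) {
    stop("'w' must be positive and non-decreasing", call. = FALSE)
  }
  s <- as.integer(s); t <- as.integer(t); z <- as.integer(z)
  if (any(s < 0) || any(t < 0) || !all(z %in% c(0L, 1L))) {
    stop("'s', 't' must be non-negative and 'z' must be 0/1", call. = FALSE)
  }
  if (!all(s + t == design$removals)) {
    stop("s + t must equal the design removal vector at every failure",
         call. = FALSE)
  }
  if (sum(z + s) > design$m || sum(1L - z + t) > design$n) {
    stop("withdrawals and failures exceed a sample size", call. = FALSE)
  }
  structure(list(w = as.numeric(w), s = s, t = t, z = z, design = design),
            class = "jpc_data")
}

#' @rdname jpc_data
#' @param data a `jpc_data` object.
#' @export
k1 <- function(data) { stopifnot(inherits(data, "jpc_data")); sum(data$z) }

#' @rdname jpc_data
#' @export
k2 <- function(data) { stopifnot(inherits(data, "jpc_data")); sum(1L - data$z) }

#' @rdname jpc_data
#' @details `is_degenerate` flags records with `k1 == 0` or `k2 == 0`: when
#'   every observed failure comes from one sample, the likelihood is strictly
#'   decreasing in the other sample's shape parameter and its MLE does not
#'   exist. Such records are returned as data, never silently re-drawn;
#'   callers that need an MLE must handle or redraw them.
#' @export
is_degenerate <- function(data) {
  k1(data) == 0L || k2(data) == 0L
}

#' @export
print.jpc_design <- function(x, ...) {
  cat("JPC design: m =", x$m, ", n =", x$n, ", k =", x$k, "\n")
  cat("removals:", paste(x$removals, collapse = " "), "\n")
  invisible(x)
}

#' @export
print.jpc_data <- function(x, ...) {
  print(x$design)
  cat("k1 =", k1(x), "(failures from A), k2 =", k2(x), "(from B)\n")
  cat("w:", paste(signif(x$w, 4), collapse = " "), "\n")
  invisible(x)
}

#' Apply a JPC scheme to two complete samples
#'
#' Runs the joint progressive censoring mechanism on two fully observed
#' lifetime vectors. At each failure the smallest remaining lifetime fails;
#' its source is recorded; then `removals[i]` surviving units are withdrawn
#' uniformly at random, without replacement, from the pooled survivors, which
#' splits the removal count hypergeometrically between the two samples. At
#' the k-th failure all survivors are withdrawn. Ties in lifetimes are broken
#' by stable position, sample A before sample B, independent of the seed.
#'
#' @param lifetimesA,lifetimesB complete lifetime vectors of lengths `m`
#'   and `n`.
#' @param design a [jpc_design()].
#' @param seed optional integer seed for the random withdrawals.
#' @return A [jpc_data()] record.
#' @export
apply_jpc <- function(lifetimesA, lifetimesB, design, seed = NULL) {
  stopifnot(inherits(design, "jpc_design"))
  if (length(lifetimesA) != design$m || length(lifetimesB) != design$n) {
    stop("lifetime vectors must have lengths m and n", call. = FALSE)
  }
  if (any(c(lifetimesA, lifetimesB) <= 0)) {
    stop("lifetimes must be positive", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  k <- design$k
  life <- c(lifetimesA, lifetimesB)
  src <- rep(c(1L, 0L), c(design$m, design$n))  # 1 = sample A
  ## stable order: by lifetime, then A before B, then input position
  ord <- order(life, -src, seq_along(life))
  life <- life[ord]; src <- src[ord]
  alive <- rep(TRUE, length(life))
  w <- numeric(k); s <- integer(k); t <- integer(k); z <- integer(k)
  for (i in seq_len(k)) {
    idx <- which(alive)
    fail <- idx[1]  # smallest remaining lifetime (list is sorted)
    w[i] <- life[fail]; z[i] <- src[fail]
    alive[fail] <- FALSE
    r_i <- if (i < k) design$removals[i] else sum(alive)
    if (r_i > 0) {
      pool <- which(alive)
      drop <- if (length(pool) == 1) pool else sample(pool, r_i)
      alive[drop] <- FALSE
      s[i] <- sum(src[drop] == 1L)
      t[i] <- r_i - s[i]
    }
  }
  jpc_data(w, s, t, z, design)
}

#' Simulate a jointly progressively censored experiment
#'
#' Draws `m` lifetimes from IERD(`theta1`, `lambda`) and `n` from
#' IERD(`theta2`, `lambda`) and censors them with [apply_jpc()].
#'
#' @param design a [jpc_design()].
#' @param theta1,theta2 shape parameters of samples A and B.
#' @param lambda common scale parameter.
#' @param seed optional integer seed (drives both the lifetimes and the
#'   random withdrawals).
#' @return A [jpc_data()] record; check [is_degenerate()] before fitting.
#' @examples
#' d <- jpc_design(25, 20, 30, "(5,0^28,10)")
#' x <- simulate_jpc(d, theta1 = 3, theta2 = 2, lambda = 2, seed = 7)
#' @export
simulate_jpc <- function(design, theta1, theta2, lambda, seed = NULL) {
  stopifnot(inherits(design, "jpc_design"))
  check_ierd_params(theta1, lambda)
  check_ierd_params(theta2, lambda)
  if (!is.null(seed)) set.seed(seed)
  xa <- qierd(stats::runif(design$m), theta1, lambda)
  xb <- qierd(stats::runif(design$n), theta2, lambda)
  apply_jpc(xa, xb, design)
}

#' Read and write JPC records as TSV
#'
#' The on-disk dialect is a plain TSV whose first line is a header comment
#' `#JPC m=<m> n=<n> k=<k> r=<comma-separated removals>` followed by one
#' `w<TAB>s<TAB>t<TAB>z` row per failure.
#'
#' @param data a [jpc_data()] record.
#' @param path file path.
#' @return `read_jpc` returns a [jpc_data()]; `write_jpc` invisibly returns
#'   `path`.
#' @export
write_jpc <- function(data, path) {
  stopifnot(inherits(data, "jpc_data"))
  d <- data$design
  header <- sprintf("#JPC m=%d n=%d k=%d r=%s", d$m, d$n, d$k,
                    paste(d$removals, collapse = ","))
  body <- sprintf("%.17g\t%d\t%d\t%d", data$w, data$s, data$t, data$z)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_jpc
#' @export
read_jpc <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || !startsWith(lines[1], "#JPC")) {
    stop("not a JPC TSV: missing '#JPC ...' header line", call. = FALSE)
  }
  get_field <- function(name) {
    hit <- regmatches(lines[1],
                      regexec(paste0("\\b", name, "=([0-9,]+)"), lines[1]))[[1]]
    if (length(hit) < 2) stop("header missing field '", name, "'",
                              call. = FALSE)
    hit[2]
  }
  m <- as.integer(get_field("m")); n <- as.integer(get_field("n"))
  k <- as.integer(get_field("k"))
  removals <- as.integer(strsplit(get_field("r"), ",")[[1]])
  design <- jpc_design(m, n, k, removals)
  rows <- utils::read.table(text = lines[-1], sep = "\t",
                            col.names = c("w", "s", "t", "z"))
  jpc_data(rows$w, rows$s, rows$t, rows$z, design)
}
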