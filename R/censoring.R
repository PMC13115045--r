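#' Progressive Type-II censoring schemes
#'
#' A progressive Type-II censoring scheme places \code{n} units on test and
#' observes \code{m} failures; at the i-th failure, \code{removals[i]}
#' surviving units are withdrawn, so that \code{n = m + sum(removals)}.
#'
#' Three stock layouts mirror the designs commonly used in life-testing
#' studies:
#' \describe{
#'   \item{\code{early}}{all \code{n - m} removals at the first failure,
#'     \code{R = (n-m, 0, ..., 0)} (burn-in screening).}
#'   \item{\code{late}}{all removals at the terminal failure,
#'     \code{R = (0, ..., 0, n-m)}; this is conventional Type-II right
#'     censoring.}
#'   \item{\code{uniform}}{single removals spread evenly,
#'     \code{R = (1, 0, 1, 0, ...)} with \code{n - m} ones; requires
#'     \code{n - m <= m}.}
#' }
#'
#' @param kind one of \code{"early"}, \code{"late"}, \code{"uniform"},
#'   \code{"custom"}.
#' @param n initial number of units on test.
#' @param m number of failures to observe (\code{m <= n}).
#' @param removals removal vector for \code{kind = "custom"}; recycled with
#'   trailing zeros up to length \code{m} if shorter.
#' @return An object of class \code{"prog_scheme"}: a list with elements
#'   \code{n}, \code{m} and the integer vector \code{removals}.
#' @examples
#' prog_scheme("early", 75, 50)
#' prog_scheme("custom", 128, 64, removals = c(20, 15, 15, 10, 4))
#' @export
prog_scheme <- function(kind = c("early", "late", "uniform", "custom"),
                        n, m, removals = NULL) {
  kind <- match.arg(kind)
  if (length(n) != 1L || length(m) != 1L || n < 1 || m < 1 ||
      n != round(n) || m != round(m)) {
    stop("'n' and 'm' must be positive integers", call. = FALSE)
  }
  if (m > n) stop("'m' must not exceed 'n'", call. = FALSE)
  d <- n - m
  r <- switch(kind,
    early = c(d, rep(0L, m - 1L)),
    late = c(rep(0L, m - 1L), d),
    uniform = {
      if (d > m) {
        stop("uniform scheme needs n - m <= m (one removal per stage)",
             call. = FALSE)
      }
      r <- rep(0L, m)
      odd <- seq(1L, m, by = 2L)
      even <- seq.int(2L, m, by = 2L)
      take <- c(odd, even)[seq_len(d)]   # (1,0,1,0,...), then fill evens
      r[take] <- 1L
      r
    },
    custom = {
      if (is.null(removals)) {
        stop("'removals' is required for kind = \"custom\"", call. = FALSE)
      }
      if (length(removals) > m) {
        stop("'removals' longer than m", call. = FALSE)
      }
      r <- c(removals, rep(0L, m - length(removals)))
      if (any(r < 0) || any(r != round(r))) {
        stop("'removals' must be nonnegative integers", call. = FALSE)
      }
      r
    })
  if (sum(r) + m != n) {
    stop(sprintf("invalid scheme: m + sum(removals) = %d != n = %d",
                 m + sum(r), n), call. = FALSE)
  }
  structure(list(n = as.integer(n), m = as.integer(m),
                 removals = as.integer(r)),
            class = "prog_scheme")
}

#' @export
print.prog_scheme <- function(x, ...) {
  cat(sprintf("Progressive Type-II censoring scheme: n = %d, m = %d\n",
              x$n, x$m))
  nz <- which(x$removals > 0)
  if (length(nz)) {
    cat("  removals:", paste(sprintf("r[%d]=%d", nz, x$removals[nz]),
                             collapse = ", "), "\n")
  } else {
    cat("  removals: none (complete sample)\n")
  }
  invisible(x)
}

#' Read or write a censoring scheme as JSON
#'
#' Schemes serialize to a JSON object with fields \code{n}, \code{m},
#' \code{removals}.
#'
#' @param scheme a \code{prog_scheme}.
#' @param path file path.
#' @return \code{read_scheme} returns a \code{prog_scheme};
#'   \code{write_scheme} returns \code{path} invisibly.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "prog_scheme"))
  jsonlite::write_json(list(n = scheme$n, m = scheme$m,
                            removals = scheme$removals),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  prog_scheme("custom", n = x$n, m = x$m, removals = x$removals)
}

#' Progressively censored sample container
#'
#' Binds the ordered observed failure times to the scheme under which they
#' arose.  \code{latent} optionally carries the lifetimes of the withdrawn
#' units (known in simulations), as a list with one vector per stage.
#'
#' @param times strictly increasing vector of \code{scheme$m} positive
#'   failure times.
#' @param scheme a \code{prog_scheme}.
#' @param latent optional list of withdrawn-unit lifetimes per stage.
#' @return An object of class \code{"prog_sample"}.
#' @export
prog_sample <- function(times, scheme, latent = NULL) {
  stopifnot(inherits(scheme, "prog_scheme"))
  if (length(times) != scheme$m) {
    stop("length(times) must equal scheme$m", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop("failure times must be positive and finite", call. = FALSE)
  }
  if (is.unsorted(times)) {
    stop("failure times must be nondecreasing", call. = FALSE)
  }
  structure(list(times = as.numeric(times), scheme = scheme,
                 latent = latent),
            class = "prog_sample")
}

#' @export
print.prog_sample <- function(x, ...) {
  cat(sprintf(
    "Progressively Type-II censored sample: m = %d failures out of n = %d\n",
    x$scheme$m, x$scheme$n))
  cat(sprintf("  range: [%.4g, %.4g]\n", min(x$times), max(x$times)))
  invisible(x)
}

#' Simulate a progressively Type-II censored Log-Logistic sample
#'
#' Uses the uniform-spacings construction: independent uniforms are powered
#' by the reversed cumulative effective sample sizes, cumulated into
#' progressively censored uniform order statistics, and mapped through the
#' Log-Logistic quantile function.  With all removals zero the output is
#' distributed as the ordinary order statistics of \code{n} iid draws.
#'
#' @param alpha,beta Log-Logistic parameters.
#' @param scheme a \code{prog_scheme}.
#' @return A \code{prog_sample} (without latent withdrawn lifetimes).
#' @seealso [sim_experiment()] for the mechanism-level simulation that also
#'   retains the withdrawn units' lifetimes.
#' @export
rprogressive <- function(alpha, beta, scheme) {
  stopifnot(inherits(scheme, "prog_scheme"))
  check_ll_params(alpha, beta)
  m <- scheme$m
  r <- scheme$removals
  w <- stats::runif(m)
  # gamma_i = i + r_m + r_{m-1} + ... + r_{m-i+1}
  gam <- seq_len(m) + cumsum(rev(r))
  v <- w^(1 / gam)
  # u_i = 1 - v_m v_{m-1} ... v_{m-i+1}
  u <- 1 - cumprod(rev(v))
  prog_sample(qloglogis(u, alpha, beta), scheme)
}

#' Impose a progressive censoring scheme on a complete dataset
#'
#' Replays the progressive Type-II mechanism over a fully observed sample:
#' at the i-th smallest remaining value the unit fails and is recorded, then
#' \code{scheme$removals[i]} of the still-surviving units are withdrawn
#' uniformly at random without replacement.  The first observed failure is
#' always \code{min(data)}.  Withdrawn values are retained as latent
#' lifetimes, so realized future order statistics are available for
#' validating predictions.
#'
#' @param data complete sample of length \code{scheme$n}.
#' @param scheme a \code{prog_scheme}.
#' @return A \code{prog_sample} with \code{latent} filled in.
#' @export
censor_complete <- function(data, scheme) {
  stopifnot(inherits(scheme, "prog_scheme"))
  if (length(data) != scheme$n) {
    stop("length(data) must equal scheme$n", call. = FALSE)
  }
  if (any(!is.finite(data)) || any(data <= 0)) {
    stop("'data' must be positive and finite", call. = FALSE)
  }
  pool <- sort(as.numeric(data))
  m <- scheme$m
  times <- numeric(m)
  latent <- vector("list", m)
  for (i in seq_len(m)) {
    times[i] <- pool[1L]
    pool <- pool[-1L]
    ri <- scheme$removals[i]
    if (ri > 0) {
      idx <- sample.int(length(pool), ri)
      latent[[i]] <- sort(pool[idx])
      pool <- pool[-idx]
    } else {
      latent[[i]] <- numeric(0)
    }
  }
  prog_sample(times, scheme, latent = latent)
}
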