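#' Fit a one- or two-component Gaussian mixture by EM
#'
#' The single-component fit is the closed-form Gaussian MLE. The
#' two-component fit runs EM from a below/above-median split plus
#' `n_restarts - 1` random-quantile splits, keeping the best log-likelihood.
#' Component variances are unequal by default and floored at `var_floor`
#' (degenerate spikes on small probe samples are thereby avoided);
#' convergence is a relative log-likelihood change below `tol`.
#'
#' @param x numeric vector of biases (degrees); needs `length(x) >= 3 * k`.
#' @param k number of components, 1 or 2.
#' @param n_restarts number of EM initialisations for `k = 2`; default 10.
#' @param seed optional integer seed for the restart draws.
#' @param var_floor variance floor in squared degrees; default 0.25.
#' @param tol relative log-likelihood convergence tolerance; default 1e-8.
#' @param max_iter EM iteration cap per restart; default 300.
#' @param equal_var constrain the two component variances to be equal.
#' @return an object of class `udl_gmm`: list with `k`, `weights`, `means`,
#'   `sds`, `loglik`, `n_iter`, `converged`, `degenerate`, `loglik_trace`
#'   (of the winning restart) and `n`.
#' @export
fit_gmm <- function(x, k, n_restarts = 10, seed = NULL, var_floor = 0.25,
                    tol = 1e-8, max_iter = 300, equal_var = FALSE) {
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("biases must be finite")
  if (!k %in% c(1L, 2L)) stop("k must be 1 or 2")
  n <- length(x)
  if (n < 3 * k) stop("need at least 3k observations")

  if (k == 1L) {
    mu <- mean(x)
    v <- max(sum((x - mu)^2) / n, var_floor)
    ll <- sum(stats::dnorm(x, mu, sqrt(v), log = TRUE))
    return(structure(list(k = 1L, weights = 1, means = mu, sds = sqrt(v),
                          loglik = ll, n_iter = 0L, converged = TRUE,
                          degenerate = FALSE, loglik_trace = ll, n = n),
                     class = "udl_gmm"))
  }

  if (stats::sd(x) < 1e-12) {
    # all-identical data: return a degenerate-safe fit
    warning("k = 2 requested on (near-)constant data; degenerate fit")
    mu <- mean(x)
    sd0 <- sqrt(var_floor)
    ll <- sum(stats::dnorm(x, mu, sd0, log = TRUE)) # weights cancel
    return(structure(list(k = 2L, weights = c(0.5, 0.5), means = c(mu, mu),
                          sds = c(sd0, sd0), loglik = ll, n_iter = 0L,
                          converged = TRUE, degenerate = TRUE,
                          loglik_trace = ll, n = n),
                     class = "udl_gmm"))
  }

  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  qs <- c(0.5, stats::runif(max(n_restarts - 1L, 0L), 0.2, 0.8))
  best <- NULL
  for (q in qs[seq_len(max(n_restarts, 1L))]) {
    split <- x <= stats::quantile(x, q)
    if (sum(split) < 2 || sum(!split) < 2) split <- x <= stats::median(x)
    init <- list(
      w = c(mean(split), 1 - mean(split)),
      mu = c(mean(x[split]), mean(x[!split])),
      v = pmax(c(stats::var(x[split]), stats::var(x[!split])), var_floor)
    )
    fit <- em_two_gaussians(x, init, var_floor, tol, max_iter, equal_var)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  structure(c(best, list(n = n)), class = "udl_gmm")
}

# EM for a two-component univariate Gaussian mixture (compiled kernel).
em_two_gaussians <- function(x, init, var_floor, tol, max_iter, equal_var) {
  fit <- .em2_cpp(as.numeric(x), init$w, init$mu, init$v, var_floor, tol,
                  as.integer(max_iter), isTRUE(equal_var))
  c(list(k = 2L), fit[c("weights", "means", "sds", "loglik", "n_iter",
                        "converged")],
    list(degenerate = FALSE, loglik_trace = fit$loglik_trace))
}

#' @export
print.udl_gmm <- function(x, ...) {
  cat(sprintf("Gaussian mixture (k = %d, n = %d): loglik %.3f%s\n",
              x$k, x$n, x$loglik,
              if (x$converged) "" else " [not converged]"))
  for (j in seq_len(x$k)) {
    cat(sprintf("  comp %d: weight %.3f, mean %7.2f deg, sd %6.2f deg\n",
                j, x$weights[j], x$means[j], x$sds[j]))
  }
  invisible(x)
}
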