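#' Fit the MGPS two-component gamma mixture prior
#'
#' The multi-item gamma-Poisson shrinker models each observed cell count
#' as a ~ Poisson(lambda E), with the relative reporting rate lambda drawn
#' from a two-component gamma mixture prior
#' w Gamma(alpha1, beta1) + (1 - w) Gamma(alpha2, beta2) (rate
#' parameterisation). Marginally a follows a mixture of negative
#' binomials; the five hyperparameters are estimated by maximising the
#' marginal log-likelihood over all (drug, term) cells with a quasi-Newton
#' search on the unconstrained scale (log for the gamma parameters, logit
#' for w), started from DuMouchel's canonical values
#' (0.2, 0.1, 2, 4, 1/3).
#'
#' @param tables contingency tables from [build_contingency_tables()]
#'   (columns `a`, `b`, `c`, `d`), or a tibble/data.frame with columns `a`
#'   and `e` giving observed and expected counts directly.
#' @param start numeric vector (alpha1, beta1, alpha2, beta2, w) of
#'   starting values.
#' @param tol relative convergence tolerance on the log-likelihood.
#' @return An object of class `mgps_prior`: list with `alpha1`, `beta1`,
#'   `alpha2`, `beta2`, `w`, `loglik`, `converged`, `n_cells`.
#' @export
mgps_fit <- function(tables, start = c(0.2, 0.1, 2, 4, 1 / 3), tol = 1e-8) {
  if (all(c("a", "e") %in% names(tables))) {
    a <- tables$a
    e <- tables$e
  } else {
    stopifnot(all(c("a", "b", "c", "d") %in% names(tables)))
    a <- tables$a
    n <- tables$a + tables$b + tables$c + tables$d
    e <- (tables$a + tables$b) * (tables$a + tables$c) / n
  }
  keep <- is.finite(a) & is.finite(e) & e > 0
  a <- a[keep]; e <- e[keep]
  if (length(a) < 50) {
    warn(sprintf("MGPS prior fitted on only %d cells; estimates may be unstable.",
                 length(a)))
  }
  nll <- function(theta) {
    al1 <- exp(theta[1]); be1 <- exp(theta[2])
    al2 <- exp(theta[3]); be2 <- exp(theta[4])
    w <- stats::plogis(theta[5])
    l1 <- dnbinom(a, size = al1, prob = be1 / (be1 + e), log = TRUE)
    l2 <- dnbinom(a, size = al2, prob = be2 / (be2 + e), log = TRUE)
    m <- pmax(l1, l2)
    ll <- m + log(w * exp(l1 - m) + (1 - w) * exp(l2 - m))
    -sum(ll)
  }
  theta0 <- c(log(start[1:4]), stats::qlogis(start[5]))
  opt <- optim(theta0, nll, method = "BFGS",
               control = list(maxit = 500, reltol = tol))
  th <- opt$par
  structure(
    list(alpha1 = exp(th[1]), beta1 = exp(th[2]),
         alpha2 = exp(th[3]), beta2 = exp(th[4]),
         w = stats::plogis(th[5]),
         loglik = -opt$value,
         converged = opt$convergence == 0,
         n_cells = length(a)),
    class = "mgps_prior"
  )
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat("MGPS gamma-mixture prior\n")
  cat(sprintf("  component 1: Gamma(%.4g, %.4g), weight %.3f\n",
              x$alpha1, x$beta1, x$w))
  cat(sprintf("  component 2: Gamma(%.4g, %.4g), weight %.3f\n",
              x$alpha2, x$beta2, 1 - x$w))
  cat(sprintf("  log-likelihood %.3f over %d cells (converged: %s)\n",
              x$loglik, x$n_cells, x$converged))
  invisible(x)
}

#' @export
tidy.mgps_prior <- function(x, ...) {
  tibble::tibble(
    term = c("alpha1", "beta1", "alpha2", "beta2", "w"),
    estimate = c(x$alpha1, x$beta1, x$alpha2, x$beta2, x$w)
  )
}

#' @export
glance.mgps_prior <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_cells = x$n_cells,
                 converged = x$converged)
}

# Posterior mixture for lambda given (a, E): component j becomes
# Gamma(alpha_j + a, beta_j + E) with weight proportional to
# w_j * NB marginal of a.
mgps_posterior <- function(a, e, prior) {
  l1 <- dnbinom(a, size = prior$alpha1, prob = prior$beta1 / (prior$beta1 + e),
                log = TRUE) + log(prior$w)
  l2 <- dnbinom(a, size = prior$alpha2, prob = prior$beta2 / (prior$beta2 + e),
                log = TRUE) + log(1 - prior$w)
  m <- pmax(l1, l2)
  q1 <- exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
  list(q1 = q1,
       shape1 = prior$alpha1 + a, rate1 = prior$beta1 + e,
       shape2 = prior$alpha2 + a, rate2 = prior$beta2 + e)
}

#' Empirical-Bayes geometric mean and its 5th percentile
#'
#' Given the fitted mixture prior, the posterior of lambda for a cell with
#' observed count a and expectation E is again a two-component gamma
#' mixture. EBGM is the posterior geometric mean
#' 2^(E\[log2 lambda | a, E\]), computed in closed form via
#' E\[ln lambda\] = digamma(shape) - ln(rate) per component; EBGM05 is the
#' 5th percentile of the posterior mixture, found by root-finding on the
#' mixture CDF.
#'
#' @param a observed counts (vectorised).
#' @param e expected counts under independence.
#' @param prior an `mgps_prior`.
#' @param p lower-tail probability for the percentile (default 0.05).
#' @return A tibble with `ebgm`, `ebgm05`.
#' @export
ebgm_stats <- function(a, e, prior, p = 0.05) {
  post <- mgps_posterior(a, e, prior)
  mean_log <- post$q1 * (digamma(post$shape1) - log(post$rate1)) +
    (1 - post$q1) * (digamma(post$shape2) - log(post$rate2))
  ebgm <- exp(mean_log)
  ebgm05 <- purrr::map_dbl(seq_along(a), function(i) {
    cdf <- function(x) {
      post$q1[i] * pgamma(x, post$shape1[i], rate = post$rate1[i]) +
        (1 - post$q1[i]) * pgamma(x, post$shape2[i], rate = post$rate2[i]) - p
    }
    q1 <- qgamma(p, post$shape1[i], rate = post$rate1[i])
    q2 <- qgamma(p, post$shape2[i], rate = post$rate2[i])
    if (post$q1[i] > 1 - 1e-12) return(q1)
    if (post$q1[i] < 1e-12) return(q2)
    lo <- min(q1, q2) * (1 - 1e-9)
    hi <- max(q1, q2) * (1 + 1e-9)
    if (hi - lo < 1e-12) return((lo + hi) / 2)
    stats::uniroot(cdf, c(lo, hi), extendInt = "upX", tol = 1e-10)$root
  })
  tibble::tibble(ebgm = ebgm, ebgm05 = ebgm05)
}
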