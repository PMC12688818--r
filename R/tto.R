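#' Extract time-to-onset samples with an exclusion tally
#'
#' Time to onset is the interval from therapy start (START_DT) to event
#' occurrence (EVENT_DT) in whole days, counted inclusively:
#' tto = (event - start) + 1, so a same-day onset is 1 day. Reports are
#' excluded — and tallied by reason — when either date is missing, either
#' date is partial (YYYY or YYYYMM) or invalid, or the event precedes the
#' therapy start.
#'
#' @param reports deduplicated target-case tibble with `event_dt`,
#'   `start_dt` (YYYYMMDD strings, possibly partial or blank) and `sex`.
#' @return A list with `samples` (tibble: `primaryid`, `tto_days`, `sex`)
#'   and `exclusions` (tibble: `reason`, `n`).
#' @export
extract_tto <- function(reports) {
  ev <- parse_faers_date(reports$event_dt)
  st <- parse_faers_date(reports$start_dt)
  reason <- dplyr::case_when(
    ev$precision == "missing" ~ "missing event date",
    st$precision == "missing" ~ "missing start date",
    ev$precision %in% c("partial", "invalid") ~ "partial or invalid event date",
    st$precision %in% c("partial", "invalid") ~ "partial or invalid start date",
    ev$date < st$date ~ "event precedes start",
    TRUE ~ "included"
  )
  keep <- reason == "included"
  samples <- tibble::tibble(
    primaryid = reports$primaryid[keep],
    tto_days = as.integer(ev$date[keep] - st$date[keep]) + 1L,
    sex = reports$sex[keep]
  )
  exclusions <- tibble::tibble(reason = reason[!keep]) |>
    dplyr::count(.data$reason, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n))
  list(samples = samples, exclusions = exclusions)
}

#' Fit a Weibull distribution to onset times
#'
#' Maximum-likelihood fit of the two-parameter Weibull to the onset
#' intervals, reported in the pharmacovigilance convention: alpha = scale
#' (days), beta = shape (dimensionless). 95% Wald confidence intervals are
#' computed on the log-parameter scale and back-transformed, keeping the
#' bounds positive. The failure type follows from the shape CI: beta with
#' CI entirely below 1 means the hazard decreases with time ("early
#' failure"), a CI containing 1 a constant hazard ("random failure"), and
#' a CI entirely above 1 an increasing hazard ("wear-out failure").
#'
#' @param tto_days positive onset intervals in days.
#' @param conf_level confidence level.
#' @param ci `"wald"` (default) or `"bootstrap"` (seeded nonparametric
#'   bootstrap of the MLE).
#' @param boot_n bootstrap resamples when `ci = "bootstrap"`.
#' @param boot_seed seed for the bootstrap resampling.
#' @return Object of class `weibull_tto_fit`: list with `alpha`,
#'   `alpha_ci`, `beta`, `beta_ci`, `n`, `failure_type`, `median`, `iqr`,
#'   `range`, `loglik`.
#' @export
weibull_tto_fit <- function(tto_days, conf_level = 0.95,
                            ci = c("wald", "bootstrap"),
                            boot_n = 1000, boot_seed = 1L) {
  ci <- match.arg(ci)
  x <- as.numeric(tto_days[!is.na(tto_days)])
  if (length(x) == 0) abort("No onset times supplied.")
  if (any(x <= 0)) abort("Onset times must be positive.")
  if (length(unique(x)) == 1) {
    abort("All onset times are identical; the Weibull fit is degenerate.")
  }
  if (length(x) < 10) {
    warn(sprintf("Only %d onset times; the Weibull fit will be unstable.",
                 length(x)))
  }
  fit <- fitdistrplus::fitdist(x, "weibull")
  beta <- unname(fit$estimate["shape"])
  alpha <- unname(fit$estimate["scale"])
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (ci == "wald") {
    se_b <- unname(fit$sd["shape"])
    se_a <- unname(fit$sd["scale"])
    beta_ci <- exp(log(beta) + c(-1, 1) * z * se_b / beta)
    alpha_ci <- exp(log(alpha) + c(-1, 1) * z * se_a / alpha)
  } else {
    old <- .Random.seed %||% NULL
    set.seed(boot_seed)
    est <- purrr::map(seq_len(boot_n), function(i) {
      xs <- sample(x, replace = TRUE)
      tryCatch(fitdistrplus::fitdist(xs, "weibull")$estimate,
               error = function(e) c(shape = NA_real_, scale = NA_real_))
    })
    est <- do.call(rbind, est)
    qs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
    beta_ci <- unname(quantile(est[, "shape"], qs, na.rm = TRUE))
    alpha_ci <- unname(quantile(est[, "scale"], qs, na.rm = TRUE))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  fn <- fivenum(x)
  structure(
    list(alpha = alpha, alpha_ci = alpha_ci,
         beta = beta, beta_ci = beta_ci,
         n = length(x),
         failure_type = classify_failure_type(beta, beta_ci),
         median = fn[3], iqr = fn[c(2, 4)], range = range(x),
         loglik = fit$loglik),
    class = "weibull_tto_fit"
  )
}

#' Classify hazard behaviour from the Weibull shape parameter
#'
#' @param beta fitted shape parameter.
#' @param ci length-2 confidence interval for `beta`.
#' @return `"early failure"` when the CI lies entirely below 1, `"wear-out
#'   failure"` when entirely above 1, else `"random failure"`.
#' @export
classify_failure_type <- function(beta, ci) {
  stopifnot(length(ci) == 2, ci[1] <= ci[2])
  if (ci[2] < 1) "early failure"
  else if (ci[1] > 1) "wear-out failure"
  else "random failure"
}

#' @export
print.weibull_tto_fit <- function(x, ...) {
  cat(sprintf("Weibull time-to-onset fit (n = %d)\n", x$n))
  cat(sprintf("  median %.1f d (IQR %.1f-%.1f), range %d-%d d\n",
              x$median, x$iqr[1], x$iqr[2], x$range[1], x$range[2]))
  cat(sprintf("  scale alpha = %.2f d (95%% CI %.2f-%.2f)\n",
              x$alpha, x$alpha_ci[1], x$alpha_ci[2]))
  cat(sprintf("  shape beta  = %.2f   (95%% CI %.2f-%.2f)\n",
              x$beta, x$beta_ci[1], x$beta_ci[2]))
  cat(sprintf("  failure type: %s\n", x$failure_type))
  invisible(x)
}

#' @export
tidy.weibull_tto_fit <- function(x, ...) {
  tibble::tibble(
    term = c("scale", "shape"),
    estimate = c(x$alpha, x$beta),
    conf.low = c(x$alpha_ci[1], x$beta_ci[1]),
    conf.high = c(x$alpha_ci[2], x$beta_ci[2])
  )
}

#' @export
glance.weibull_tto_fit <- function(x, ...) {
  tibble::tibble(n = x$n, median = x$median, iqr_low = x$iqr[1],
                 iqr_high = x$iqr[2], min = x$range[1], max = x$range[2],
                 failure_type = x$failure_type, logLik = x$loglik)
}

#' Kaplan-Meier cumulative incidence of onset
#'
#' Product-limit estimator over the onset times, optionally per group.
#' Spontaneous-report onset data carry no censoring mechanism, so all
#' samples are events and the curve equals the empirical CDF; the
#' estimator is kept for its at-risk bookkeeping and to admit censoring
#' should a source supply it.
#'
#' @param tto_days onset intervals in days.
#' @param group optional grouping factor (e.g. sex).
#' @return Tibble of class `km_curve`: `group`, `time`, `n_risk`,
#'   `n_event`, `surv`, `cuminc`.
#' @export
km_curve <- function(tto_days, group = NULL) {
  x <- as.numeric(tto_days)
  if (length(x) == 0) abort("No onset times supplied.")
  g <- if (is.null(group)) rep("all", length(x)) else as.character(group)
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- g[keep]
  out <- purrr::map_dfr(unique(g), function(gr) {
    sf <- survival::survfit(survival::Surv(x[g == gr]) ~ 1)
    tibble::tibble(group = gr, time = sf$time, n_risk = sf$n.risk,
                   n_event = sf$n.event, surv = sf$surv,
                   cuminc = 1 - sf$surv)
  })
  class(out) <- c("km_curve", class(out))
  out
}

#' Two-group log-rank test of onset-time distributions
#'
#' Standard 1-df log-rank chi-squared comparing the onset distributions of
#' two groups, all observations treated as events.
#'
#' @param tto_a,tto_b onset intervals for the two groups.
#' @return Tibble with `statistic`, `df`, `p.value`, `n_a`, `n_b`.
#' @export
logrank_test <- function(tto_a, tto_b) {
  tto_a <- tto_a[!is.na(tto_a)]
  tto_b <- tto_b[!is.na(tto_b)]
  if (length(tto_a) == 0 || length(tto_b) == 0) {
    abort("Both groups must be non-empty.")
  }
  time <- c(tto_a, tto_b)
  grp <- rep(c("A", "B"), c(length(tto_a), length(tto_b)))
  sd <- survival::survdiff(survival::Surv(time) ~ grp)
  tibble::tibble(statistic = unname(sd$chisq), df = 1,
                 p.value = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
                 n_a = length(tto_a), n_b = length(tto_b))
}

#' Full time-to-onset analysis, overall and by sex
#'
#' Runs [weibull_tto_fit()] on all samples and within each sex stratum,
#' builds KM cumulative-incidence curves, and compares sexes with a
#' log-rank test. Strata below `min_n` samples are skipped.
#'
#' @param samples tibble from [extract_tto()] (`tto_days`, `sex`).
#' @param min_n minimum stratum size for a Weibull fit.
#' @return List of class `tto_analysis`: `fits` (named list of
#'   `weibull_tto_fit`), `summary` (tibble mirroring the usual onset-table
#'   layout), `km` (a `km_curve`), `logrank` (tibble or NULL).
#' @export
tto_analysis <- function(samples, min_n = 10) {
  strata <- list(all = samples$tto_days,
                 F = samples$tto_days[!is.na(samples$sex) & samples$sex == "F"],
                 M = samples$tto_days[!is.na(samples$sex) & samples$sex == "M"])
  fits <- purrr::map(purrr::keep(strata, ~ length(.x) >= min_n),
                     weibull_tto_fit)
  summary <- purrr::imap_dfr(fits, function(f, nm) {
    tibble::tibble(
      stratum = nm, n = f$n,
      median = f$median, iqr_low = f$iqr[1], iqr_high = f$iqr[2],
      min = f$range[1], max = f$range[2],
      alpha = f$alpha, alpha_lo = f$alpha_ci[1], alpha_hi = f$alpha_ci[2],
      beta = f$beta, beta_lo = f$beta_ci[1], beta_hi = f$beta_ci[2],
      failure_type = f$failure_type
    )
  })
  km <- km_curve(samples$tto_days,
                 group = dplyr::coalesce(samples$sex, "missing"))
  lr <- NULL
  if (length(strata$F) > 0 && length(strata$M) > 0) {
    lr <- logrank_test(strata$F, strata$M)
  }
  structure(list(fits = fits, summary = summary, km = km, logrank = lr),
            class = "tto_analysis")
}

#' @export
print.tto_analysis <- function(x, ...) {
  cat("Time-to-onset analysis\n")
  print(x$summary)
  if (!is.null(x$logrank)) {
    cat(sprintf("Log-rank F vs M: chi2 = %.2f, p = %.4g\n",
                x$logrank$statistic, x$logrank$p.value))
  }
  invisible(x)
}
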