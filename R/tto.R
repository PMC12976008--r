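# Time-to-onset (TTO) of adverse events and Weibull failure-pattern
# modelling.  TTO is the gap in days between the earliest primary-suspect
# therapy start and the event onset date; the Weibull shape parameter
# classifies the hazard as early-failure (decreasing), random (constant) or
# wear-out (increasing).

#' Compute time-to-onset for a cohort
#'
#' For each report, TTO = event onset date minus the earliest therapy start
#' date across the report's primary-suspect drug records, in days.  Only
#' day-precision dates are used (partial dates are excluded, not imputed)
#' and non-positive gaps are dropped; the attrition is reported in
#' attributes.
#'
#' @param cohort a PS-filtered [faers_data()] object whose DEMO table
#'   carries `event_dt`.
#' @param dict optional [drug_dictionary()]; when given, only PS records
#'   matching the target names anchor the exposure start.
#' @return object of class `onset_sample`: numeric vector of positive TTO
#'   days with attributes `n_reports`, `n_eligible`, `excluded` (a named
#'   breakdown).
#' @export
compute_tto <- function(cohort, dict = NULL) {
  stopifnot(inherits(cohort, "faers_data"))
  demo <- cohort$demo
  drug <- cohort$drug
  ther <- cohort$ther

  ps <- drug[toupper(trimws(drug$role_cod)) == "PS", , drop = FALSE]
  if (!is.null(dict)) {
    ps <- ps[normalize_name(ps$drugname) %in% dict$target, , drop = FALSE]
  }
  th <- merge(ther, ps[, c("primaryid", "drug_seq")],
              by.x = c("primaryid", "dsg_drug_seq"),
              by.y = c("primaryid", "drug_seq"))
  st <- parse_partial_date(th$start_dt)
  th$start <- st$date
  th$ok <- st$precision == "day"
  th <- th[th$ok, , drop = FALSE]
  start_by_id <- tapply(as.numeric(th$start), th$primaryid, min)

  ev <- parse_partial_date(demo$event_dt)
  ev_ok <- ev$precision == "day"
  start <- start_by_id[demo$primaryid]

  tto <- as.numeric(ev$date) - as.numeric(start)
  eligible <- ev_ok & !is.na(start) & !is.na(tto) & tto > 0

  excluded <- c(no_day_precision_event = sum(!ev_ok),
                no_day_precision_start = sum(ev_ok & is.na(start)),
                nonpositive = sum(ev_ok & !is.na(start) & !is.na(tto) &
                                    tto <= 0))
  structure(as.numeric(tto[eligible]),
            n_reports = nrow(demo),
            n_eligible = sum(eligible),
            excluded = excluded,
            class = "onset_sample")
}

#' Summary quantiles of an onset sample
#'
#' @param tto an `onset_sample` or numeric vector of positive days.
#' @return data.frame with `n`, `median`, `q1`, `q3` (type-7 quantiles).
#' @export
onset_summary <- function(tto) {
  x <- as.numeric(tto)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(n = length(x), median = q[2], q1 = q[1], q3 = q[3])
}

#' Fit a Weibull model to onset times and classify the failure pattern
#'
#' Maximum-likelihood fit of the two-parameter Weibull density
#' `f(t) = (beta/alpha) (t/alpha)^(beta-1) exp(-(t/alpha)^beta)` on the log
#' scale of both parameters, with 95% confidence intervals from the
#' observed Fisher information (normal approximation on
#' `(log alpha, log beta)`).  The hazard classification follows the shape
#' CI: upper bound below 1 is `early_failure`, an interval containing 1 is
#' `random_failure`, lower bound above 1 is `wear_out`.
#'
#' @param tto numeric vector of positive onset days (n >= 10).
#' @return object of class `weibull_fit`: list with `alpha`, `alpha_lo`,
#'   `alpha_hi` (scale, days), `beta`, `beta_lo`, `beta_hi` (shape),
#'   `classification`, `loglik`, `n`.
#' @export
fit_weibull_tto <- function(tto) {
  x <- as.numeric(tto)
  if (length(x) < 10) stop("Weibull fit needs at least 10 onset times")
  if (any(x <= 0)) stop("onset times must be positive")
  if (stats::sd(x) == 0) stop("degenerate sample: all onset times equal")

  nll <- function(par) {
    v <- suppressWarnings(
      -sum(stats::dweibull(x, shape = exp(par[2]), scale = exp(par[1]),
                           log = TRUE)))
    if (!is.finite(v)) 1e10 else v
  }
  p0 <- c(log(mean(x)), 0)
  fit <- stats::optim(p0, nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  vc <- solve(fit$hessian)
  se <- sqrt(diag(vc))
  log_alpha <- fit$par[1]; log_beta <- fit$par[2]
  alpha <- exp(log_alpha); beta <- exp(log_beta)
  alpha_ci <- exp(log_alpha + c(-1, 1) * 1.96 * se[1])
  beta_ci <- exp(log_beta + c(-1, 1) * 1.96 * se[2])

  classification <- if (beta_ci[2] < 1) "early_failure"
  else if (beta_ci[1] > 1) "wear_out"
  else "random_failure"

  structure(list(alpha = alpha, alpha_lo = alpha_ci[1], alpha_hi = alpha_ci[2],
                 beta = beta, beta_lo = beta_ci[1], beta_hi = beta_ci[2],
                 classification = classification,
                 loglik = -fit$value, n = length(x)),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("Weibull time-to-onset fit (n = %d)\n", x$n))
  cat(sprintf("  scale alpha = %.2f days (95%% CI %.2f-%.2f)\n",
              x$alpha, x$alpha_lo, x$alpha_hi))
  cat(sprintf("  shape beta  = %.3f      (95%% CI %.3f-%.3f)\n",
              x$beta, x$beta_lo, x$beta_hi))
  cat("  pattern:", x$classification, "\n")
  invisible(x)
}

#' Onset-time histogram counts in 30-day bins
#'
#' @param tto numeric vector of positive onset days.
#' @param bin_width bin width in days (default 30).
#' @param max_days right edge of the last closed bin; later onsets pool
#'   into an overflow bin.
#' @return data.frame with `bin` labels and `count`.
#' @export
tto_histogram <- function(tto, bin_width = 30, max_days = 360) {
  x <- as.numeric(tto)
  edges <- seq(0, max_days, by = bin_width)
  labels <- paste0(utils::head(edges, -1) + 1, "-", edges[-1])
  idx <- findInterval(x, edges, left.open = TRUE, rightmost.closed = FALSE)
  idx[x > max_days] <- length(labels) + 1
  counts <- tabulate(idx, nbins = length(labels) + 1)
  data.frame(bin = c(labels, paste0(">", max_days)), count = counts,
             stringsAsFactors = FALSE)
}
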