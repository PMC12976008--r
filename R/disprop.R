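# The four disproportionality statistics: ROR, PRR + chi-square, the BCPNN
# information component, and the MGPS empirical-Bayes geometric mean.
#
# All four read the same 2x2 table per (drug, event) pair:
#
#                 event   other events
#   study drug      a          b
#   other drugs     c          d        N = a + b + c + d
#
# Zero cells make ROR and PRR undefined; in that case all cells receive the
# Haldane-Anscombe +0.5 continuity correction and the row is flagged.

.haldane <- function(a, b, c, d) {
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  list(a = a + 0.5 * zero, b = b + 0.5 * zero,
       c = c + 0.5 * zero, d = d + 0.5 * zero, corrected = zero)
}

#' Reporting odds ratio with Wald confidence interval
#'
#' `ROR = ad/(bc)` with the 95% CI
#' `exp(log ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`.  Tables containing
#' a zero cell are continuity-corrected (+0.5 to every cell) and flagged.
#'
#' @param a,b,c,d integer vectors of 2x2 cells (recycled to common length).
#' @return data.frame with columns `ror`, `ror_lo`, `ror_hi`, `corrected`.
#' @export
ror_stat <- function(a, b, c, d) {
  h <- .haldane(a, b, c, d)
  ror <- h$a * h$d / (h$b * h$c)
  se <- sqrt(1 / h$a + 1 / h$b + 1 / h$c + 1 / h$d)
  data.frame(ror = ror,
             ror_lo = exp(log(ror) - 1.96 * se),
             ror_hi = exp(log(ror) + 1.96 * se),
             corrected = h$corrected)
}

#' Proportional reporting ratio and chi-square statistic
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the accompanying Pearson statistic is
#' `chi2 = N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` without Yates correction.
#' Zero-cell tables are continuity-corrected as in [ror_stat()].
#'
#' @inheritParams ror_stat
#' @return data.frame with columns `prr`, `chi2`, `corrected`.
#' @export
prr_stat <- function(a, b, c, d) {
  h <- .haldane(a, b, c, d)
  a2 <- h$a; b2 <- h$b; c2 <- h$c; d2 <- h$d
  prr <- (a2 / (a2 + b2)) / (c2 / (c2 + d2))
  n <- a2 + b2 + c2 + d2
  chi2 <- n * (a2 * d2 - b2 * c2)^2 /
    ((a2 + b2) * (c2 + d2) * (a2 + c2) * (b2 + d2))
  data.frame(prr = prr, chi2 = chi2, corrected = h$corrected)
}

# BCPNN prior constants (Bate 1998): uniform Beta(1, .) marginals and a
# joint prior calibrated to independence.
.bcpnn_prior <- list(alpha1 = 1, beta1 = 1, alpha = 2, beta = 2, gamma11 = 1)

#' BCPNN information component with lower credibility bound
#'
#' Closed-form posterior moments of the information component
#' `IC = log2 p11/(p1. p.1)` under the Bate-1998 Beta priors
#' (`alpha1 = beta1 = 1`, `alpha = beta = 2`, `gamma11 = 1`, with the joint
#' prior parameter `gamma` tied to the margins so that independence gives
#' IC = 0).  `ic025 = E(IC) - 1.96 sqrt(V(IC))` is the conventional lower
#' bound; `ic025 > 0` is the signal criterion.
#'
#' @inheritParams ror_stat
#' @return data.frame with columns `ic`, `ic025`, `ic_var`.
#' @export
bcpnn_stat <- function(a, b, c, d) {
  p <- .bcpnn_prior
  n <- a + b + c + d
  a1 <- p$alpha1; b1 <- p$beta1; al <- p$alpha; be <- p$beta; g11 <- p$gamma11
  gam <- g11 * (n + al) * (n + be) / ((a + b + a1) * (a + c + b1))
  ic <- log2((a + g11) * (n + al) * (n + be) /
               ((n + gam) * (a + b + a1) * (a + c + b1)))
  vic <- ((n - a + gam - g11) / ((a + g11) * (1 + n + gam)) +
            (n - (a + b) + al - a1) / ((a + b + a1) * (1 + n + al)) +
            (n - (a + c) + be - b1) / ((a + c + b1) * (1 + n + be))) / log(2)^2
  data.frame(ic = ic, ic025 = ic - 1.96 * sqrt(vic), ic_var = vic)
}

.mgps_start <- c(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2.0, beta2 = 4.0, P = 1 / 3)

# mixture log-likelihood of observed counts a with expected counts E under
# the gamma-mixture prior; marginally each component is negative binomial
# with size alpha_j and probability beta_j/(beta_j + E).
.mgps_loglik <- function(par, a, E, truncated) {
  l1 <- stats::dnbinom(a, size = par[1], prob = par[2] / (par[2] + E), log = TRUE)
  l2 <- stats::dnbinom(a, size = par[3], prob = par[4] / (par[4] + E), log = TRUE)
  lp <- log(par[5]); lq <- log1p(-par[5])
  hi <- pmax(l1 + lp, l2 + lq)
  ll <- hi + log(exp(l1 + lp - hi) + exp(l2 + lq - hi))
  if (truncated) {
    z1 <- par[1] * log(par[2] / (par[2] + E))
    z2 <- par[3] * log(par[4] / (par[4] + E))
    zh <- pmax(z1 + lp, z2 + lq)
    lz <- zh + log(exp(z1 + lp - zh) + exp(z2 + lq - zh))  # log P(a = 0)
    ll <- ll - log1p(-exp(lz))
  }
  sum(ll)
}

#' Fit the MGPS two-component gamma prior
#'
#' Maximum-likelihood fit of the five hyperparameters
#' `(alpha1, beta1, alpha2, beta2, P)` of the DuMouchel gamma-mixture prior
#' on the relative reporting rate `lambda`, from database-wide `(a, E)`
#' cells.  Marginally each count is a mixture of two negative binomials.
#' By default cells with `a = 0` are dropped and the likelihood is
#' zero-truncated accordingly; set `include_zeros = TRUE` to fit all
#' supplied cells with the untruncated likelihood.
#'
#' Optimization runs on log/logit-transformed parameters (Nelder-Mead
#' polished by BFGS) from the conventional start `(0.2, 0.1, 2, 4, 1/3)`.
#'
#' @param a integer vector of observed counts.
#' @param E numeric vector of expected counts (same length, all > 0).
#' @param include_zeros keep `a = 0` cells and skip truncation?
#' @param start named numeric start vector (see default above).
#' @return object of class `mgps_prior`: list with the five hyperparameters,
#'   `loglik`, `convergence`, and `n_cells`.
#' @export
fit_mgps_prior <- function(a, E, include_zeros = FALSE, start = .mgps_start) {
  stopifnot(length(a) == length(E), all(E > 0), all(a >= 0))
  if (!include_zeros) {
    keep <- a >= 1
    a <- a[keep]; E <- E[keep]
  }
  if (sum(a >= 1) < 100) {
    stop("MGPS prior fit needs at least 100 cells with a >= 1")
  }
  truncated <- !include_zeros

  to_par <- function(th) c(exp(th[1:4]), stats::plogis(th[5]))
  nll <- function(th) {
    par <- to_par(th)
    val <- -.mgps_loglik(par, a, E, truncated)
    if (!is.finite(val)) 1e12 else val
  }
  th0 <- c(log(start[1:4]), stats::qlogis(start[5]))
  fit <- stats::optim(th0, nll, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
  fit <- stats::optim(fit$par, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  par <- to_par(fit$par)
  if (fit$convergence != 0) {
    stop(errorCondition(
      paste0("MGPS prior fit did not converge (optim code ", fit$convergence, ")"),
      class = "mgps_nonconvergence",
      params = par, value = -fit$value))
  }
  structure(list(alpha1 = par[1], beta1 = par[2], alpha2 = par[3],
                 beta2 = par[4], P = par[5],
                 loglik = -fit$value, convergence = fit$convergence,
                 truncated = truncated, n_cells = length(a)),
            class = "mgps_prior")
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat("MGPS gamma-mixture prior\n")
  cat(sprintf("  alpha1 = %.4f  beta1 = %.4f\n", x$alpha1, x$beta1))
  cat(sprintf("  alpha2 = %.4f  beta2 = %.4f\n", x$alpha2, x$beta2))
  cat(sprintf("  P = %.4f   (fit on %d cells, loglik %.2f)\n",
              x$P, x$n_cells, x$loglik))
  invisible(x)
}

#' Construct an MGPS prior from known hyperparameters
#'
#' @param alpha1,beta1,alpha2,beta2,P the five hyperparameters.
#' @return an `mgps_prior` object (no fit diagnostics).
#' @export
mgps_prior <- function(alpha1, beta1, alpha2, beta2, P) {
  stopifnot(alpha1 > 0, beta1 > 0, alpha2 > 0, beta2 > 0, P > 0, P < 1)
  structure(list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                 beta2 = beta2, P = P, loglik = NA_real_,
                 convergence = NA_integer_, truncated = NA,
                 n_cells = NA_integer_),
            class = "mgps_prior")
}

#' EBGM and its lower posterior bound
#'
#' Given the fitted prior, the posterior of the relative reporting rate
#' `lambda` for a cell `(a, E)` is a two-component gamma mixture with
#' weights updated by the negative-binomial marginals.  `EBGM =
#' exp(E[log lambda])` (the empirical-Bayes geometric mean) and `EBGM05` is
#' the posterior 5th percentile, found by bisection on the mixture CDF to
#' `|deltaCDF| < 1e-9`.  `EBGM05 > 2` is the signal criterion.
#'
#' @param a integer vector of observed counts.
#' @param E numeric vector of expected counts (> 0).
#' @param prior an `mgps_prior`.
#' @return data.frame with columns `ebgm`, `ebgm05`.
#' @export
ebgm_stat <- function(a, E, prior) {
  stopifnot(inherits(prior, "mgps_prior"), all(E > 0))
  n <- max(length(a), length(E))
  a <- rep_len(a, n); E <- rep_len(E, n)
  s1 <- prior$alpha1 + a; r1 <- prior$beta1 + E
  s2 <- prior$alpha2 + a; r2 <- prior$beta2 + E
  l1 <- stats::dnbinom(a, size = prior$alpha1,
                       prob = prior$beta1 / (prior$beta1 + E), log = TRUE) +
    log(prior$P)
  l2 <- stats::dnbinom(a, size = prior$alpha2,
                       prob = prior$beta2 / (prior$beta2 + E), log = TRUE) +
    log1p(-prior$P)
  Q <- 1 / (1 + exp(l2 - l1))

  elog <- Q * (digamma(s1) - log(r1)) + (1 - Q) * (digamma(s2) - log(r2))
  ebgm <- exp(elog)

  ebgm05 <- vapply(seq_len(n), function(i) {
    cdf <- function(x) {
      Q[i] * stats::pgamma(x, shape = s1[i], rate = r1[i]) +
        (1 - Q[i]) * stats::pgamma(x, shape = s2[i], rate = r2[i])
    }
    lo <- min(stats::qgamma(0.05, shape = s1[i], rate = r1[i]),
              stats::qgamma(0.05, shape = s2[i], rate = r2[i]))
    hi <- max(stats::qgamma(0.05, shape = s1[i], rate = r1[i]),
              stats::qgamma(0.05, shape = s2[i], rate = r2[i]))
    if (hi - lo < .Machine$double.eps) return(lo)
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      f <- cdf(mid)
      if (abs(f - 0.05) < 1e-9) return(mid)
      if (f > 0.05) hi <- mid else lo <- mid
      if (hi - lo < 1e-15 * max(1, hi)) break
    }
    (lo + hi) / 2
  }, numeric(1))

  data.frame(ebgm = ebgm, ebgm05 = ebgm05)
}

#' Default signal thresholds
#'
#' The field-standard quartet: ROR flags when `a >= 3` and the CI lower
#' bound exceeds 1; PRR when `a >= 3`, `PRR >= 2` and `chi2 >= 4`; BCPNN
#' when `IC025 > 0`; MGPS when `EBGM05 > 2`.
#'
#' @return named list of threshold constants.
#' @export
signal_thresholds <- function() {
  list(min_a = 3, ror_lo = 1, prr = 2, chi2 = 4, ic025 = 0, ebgm05 = 2)
}

#' Run all four disproportionality statistics over a contingency set
#'
#' Computes ROR, PRR + chi-square, IC, and EBGM per event term, applies the
#' signal thresholds, and sorts by `a` descending (reporting-frequency
#' order).  `any_signal` is the disjunction of the four per-method flags: a
#' term is a potential signal if at least one method exceeds its threshold.
#'
#' @param tables a `contingency_set` from [count_pairs()].
#' @param prior an `mgps_prior`; fit one with [fit_mgps_prior()] on
#'   database-wide cells ([mgps_cells()]).
#' @param thresholds list as returned by [signal_thresholds()].
#' @return data.frame of class `signal_table`: one row per term with all
#'   point estimates, interval bounds, per-method flags and `any_signal`.
#' @export
detect_signals <- function(tables, prior, thresholds = signal_thresholds()) {
  stopifnot(inherits(prior, "mgps_prior"))
  a <- tables$a; b <- tables$b; c <- tables$c; d <- tables$d
  n <- a + b + c + d
  E <- (a + b) * (a + c) / n

  ror <- ror_stat(a, b, c, d)
  prr <- prr_stat(a, b, c, d)
  ic <- bcpnn_stat(a, b, c, d)
  eb <- ebgm_stat(a, E, prior)

  th <- thresholds
  ror_signal <- a >= th$min_a & ror$ror_lo > th$ror_lo
  prr_signal <- a >= th$min_a & prr$prr >= th$prr & prr$chi2 >= th$chi2
  ic_signal <- ic$ic025 > th$ic025
  ebgm_signal <- eb$ebgm05 > th$ebgm05

  out <- data.frame(term = tables$term, level = tables$level,
                    a = a, b = b, c = c, d = d, expected = E,
                    ror = ror$ror, ror_lo = ror$ror_lo, ror_hi = ror$ror_hi,
                    prr = prr$prr, chi2 = prr$chi2,
                    ic = ic$ic, ic025 = ic$ic025,
                    ebgm = eb$ebgm, ebgm05 = eb$ebgm05,
                    corrected = ror$corrected,
                    ror_signal = ror_signal, prr_signal = prr_signal,
                    ic_signal = ic_signal, ebgm_signal = ebgm_signal,
                    any_signal = ror_signal | prr_signal | ic_signal |
                      ebgm_signal,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$a, out$term), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("signal_table", "data.frame"))
}
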