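# Independent oracles used across the suite.  These deliberately avoid the
# package's own computational paths: hand-written formulas, brute-force
# loops, numerical quadrature and Monte-Carlo sampling.

# random 2x2 tables with all-positive cells
random_tables <- function(n, seed = 1, amax = 200) {
  set.seed(seed)
  data.frame(a = sample(1:amax, n, TRUE),
             b = sample(1:2000, n, TRUE),
             c = sample(1:2000, n, TRUE),
             d = sample(100:50000, n, TRUE))
}

# hand-formula recomputation of ROR / PRR / chi2 (no shared code);
# doubles throughout to avoid integer overflow in (ad - bc)^2
hand_ror <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c)
  d <- as.numeric(d)
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ror = ror, lo = exp(log(ror) - 1.96 * se),
       hi = exp(log(ror) + 1.96 * se))
}
hand_prr <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c)
  d <- as.numeric(d)
  n <- a + b + c + d
  list(prr = (a / (a + b)) / (c / (c + d)),
       chi2 = n * (a * d - b * c)^2 /
         ((a + b) * (c + d) * (a + c) * (b + d)))
}

# Monte-Carlo estimate of the information component: the IC is defined
# through posterior expectations of p11, p1., p.1 (independent Beta
# posteriors under the standard priors); the oracle estimates those three
# means by sampling and plugs them into log2 p11/(p1. p.1).
mc_ic_oracle <- function(a, b, c, d, ndraw = 2e5) {
  n <- a + b + c + d
  gam <- (n + 2) * (n + 2) / ((a + b + 1) * (a + c + 1))
  p11 <- rbeta(ndraw, a + 1, n - a + gam - 1)
  p1. <- rbeta(ndraw, a + b + 1, n - (a + b) + 1)
  p.1 <- rbeta(ndraw, a + c + 1, n - (a + c) + 1)
  log2(mean(p11) / (mean(p1.) * mean(p.1)))
}

# numerical-quadrature oracle for the EBGM posterior: integrates the
# unnormalized posterior density of lambda on the log scale (no conjugate
# shortcut).  Composite Simpson on an adaptive window around the posterior
# mode; the 5th percentile comes from the cumulative rule refined with
# integrate() + uniroot on the bracketing subinterval.
quad_ebgm_oracle <- function(a, E, prior) {
  f <- function(u) {
    lam <- exp(u)
    dens <- prior$P * dgamma(lam, prior$alpha1, rate = prior$beta1) +
      (1 - prior$P) * dgamma(lam, prior$alpha2, rate = prior$beta2)
    dens * dpois(a, lam * E) * lam       # Jacobian of u = log(lambda)
  }
  # locate the support: coarse scan, keep where logf within 70 nats of max
  uc <- seq(-200, 60, by = 0.1)
  lf <- suppressWarnings(log(f(uc)))
  lf[!is.finite(lf)] <- -Inf
  sup <- uc[lf > max(lf) - 70]
  lo <- min(sup) - 1; hi <- max(sup) + 1
  if (a == 0) lo <- min(lo, -140)        # slow e^(alpha1 u) left tail

  m <- 200001L                           # odd node count for Simpson
  u <- seq(lo, hi, length.out = m)
  h <- u[2] - u[1]
  fu <- f(u)
  w <- rep(c(2, 4), length.out = m); w[1] <- 1; w[m] <- 1
  Z <- sum(w * fu) * h / 3
  elog <- sum(w * u * fu) * h / 3 / Z

  # cumulative Simpson at odd-indexed nodes (pairs of intervals)
  idx <- seq(1, m - 2, by = 2)
  seg <- (fu[idx] + 4 * fu[idx + 1] + fu[idx + 2]) * h / 3
  cum <- c(0, cumsum(seg))               # CDF at nodes u[seq(1, m, 2)]
  nodes <- u[seq(1, m, by = 2)]
  target <- 0.05 * Z
  k <- findInterval(target, cum)         # bracket [nodes[k], nodes[k+1]]
  G <- function(x) {
    cum[k] + integrate(f, nodes[k], x, rel.tol = 1e-13,
                       subdivisions = 200L)$value - target
  }
  root <- uniroot(G, lower = nodes[k], upper = nodes[k + 1], tol = 1e-13)$root
  list(ebgm = exp(elog), q05 = exp(root))
}

# brute-force deduplication: explicit per-case loop applying the stated
# rule (latest fda_dt, ties by highest primaryid; primaryid-only when any
# version's date fails to parse)
brute_dedup <- function(demo) {
  keep <- character(0)
  for (cid in unique(demo$caseid)) {
    g <- demo[demo$caseid == cid, , drop = FALSE]
    fda <- suppressWarnings(as.numeric(g$fda_dt))
    fda[nchar(g$fda_dt) != 8 | is.na(fda)] <- NA
    pid <- as.numeric(g$primaryid)
    if (anyNA(fda)) {
      keep <- c(keep, g$primaryid[which.max(pid)])
    } else {
      best <- which(fda == max(fda))
      keep <- c(keep, g$primaryid[best[which.max(pid[best])]])
    }
  }
  keep
}

# brute-force (report, term) pair counter: double loop over reports and
# terms
brute_count <- function(cohort_reac, comparator_reac, term) {
  co_pairs <- unique(paste(cohort_reac$primaryid,
                           tolower(trimws(cohort_reac$pt))))
  cm_pairs <- unique(paste(comparator_reac$primaryid,
                           tolower(trimws(comparator_reac$pt))))
  a <- sum(endsWith(co_pairs, paste0(" ", term)))
  cc <- sum(endsWith(cm_pairs, paste0(" ", term)))
  list(a = a, b = length(co_pairs) - a, c = cc,
       d = length(cm_pairs) - cc, n = length(co_pairs) + length(cm_pairs))
}

# small hand-built database: nf female cohort reports carry pt "sig_pt",
# males do not; a comparator block reports background terms only
sexed_signal_db <- function(n_f = 60, n_m = 60, n_comp = 400) {
  n <- n_f + n_m + n_comp
  pid <- as.character(seq(500001, length.out = n))
  sex <- c(rep("F", n_f), rep("M", n_m),
           rep(c("F", "M"), length.out = n_comp))
  demo <- data.frame(primaryid = pid, caseid = pid,
                     fda_dt = "20240101", event_dt = NA_character_,
                     age = NA_character_, age_cod = NA_character_,
                     sex = sex, reporter_country = "US",
                     occp_cod = "MD", stringsAsFactors = FALSE)
  drugname <- c(rep("TARGET", n_f + n_m), rep("OTHER", n_comp))
  drug <- data.frame(primaryid = pid, drug_seq = "1", role_cod = "PS",
                     drugname = drugname, stringsAsFactors = FALSE)
  # every report gets a background term; female cohort reports add sig_pt
  bg <- rep(sprintf("bg_%02d", 1:10), length.out = n)
  reac <- data.frame(primaryid = pid, pt = bg, stringsAsFactors = FALSE)
  reac <- rbind(reac, data.frame(primaryid = pid[seq_len(n_f)],
                                 pt = "sig_pt", stringsAsFactors = FALSE))
  # sprinkle sig_pt thinly into the comparator so tables stay non-degenerate
  comp_ids <- pid[(n_f + n_m + 1):n]
  reac <- rbind(reac, data.frame(primaryid = comp_ids[seq(1, n_comp, by = 40)],
                                 pt = "sig_pt", stringsAsFactors = FALSE))
  faers_data(demo = demo, drug = drug, reac = reac)
}

# fixed prior used wherever a known prior is needed
test_prior <- function() mgps_prior(0.2, 0.1, 2.0, 4.0, 1 / 3)
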