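test_that("ROR and PRR reproduce hand-computed reference values", {
  r <- ror_stat(10, 90, 100, 9900)
  expect_equal(r$ror, 11.0, tolerance = 1e-12)
  expect_equal(r$ror_lo, 5.559515, tolerance = 1e-6)
  expect_equal(r$ror_hi, 21.76449, tolerance = 1e-6)
  expect_false(r$corrected)

  p <- prr_stat(10, 90, 100, 9900)
  expect_equal(p$prr, 10.0, tolerance = 1e-12)
  expect_equal(p$chi2, 74.44717, tolerance = 1e-6)

  # symmetric table: no disproportionality
  expect_equal(ror_stat(10, 10, 10, 10)$ror, 1.0)
  expect_equal(prr_stat(10, 10, 10, 10)$prr, 1.0)
  expect_equal(prr_stat(10, 10, 10, 10)$chi2, 0.0)
})

test_that("zero cells trigger the continuity correction and stay finite", {
  r <- ror_stat(0, 50, 100, 5000)
  expect_true(r$corrected)
  expect_true(is.finite(r$ror) && r$ror < 1)
  p <- prr_stat(5, 50, 0, 5000)
  expect_true(p$corrected && is.finite(p$prr))
})

test_that("sweep of random tables matches hand formulas to 1e-12", {
  tt <- random_tables(1000, seed = 21)
  r <- ror_stat(tt$a, tt$b, tt$c, tt$d)
  p <- prr_stat(tt$a, tt$b, tt$c, tt$d)
  h_r <- hand_ror(tt$a, tt$b, tt$c, tt$d)
  h_p <- hand_prr(tt$a, tt$b, tt$c, tt$d)
  expect_equal(r$ror, h_r$ror, tolerance = 1e-12)
  expect_equal(r$ror_lo, h_r$lo, tolerance = 1e-12)
  expect_equal(r$ror_hi, h_r$hi, tolerance = 1e-12)
  expect_equal(p$prr, h_p$prr, tolerance = 1e-12)
  expect_equal(p$chi2, h_p$chi2, tolerance = 1e-12)
  # algebraic identity: ad > bc  <=>  a/(a+b) > c/(c+d)
  expect_true(all(sign(r$ror - 1) == sign(p$prr - 1)))
  expect_true(all(r$ror_lo <= r$ror & r$ror <= r$ror_hi))
})

test_that("information component vanishes under balanced independence", {
  ic <- bcpnn_stat(10000, 10000, 10000, 10000)
  expect_lt(abs(ic$ic), 0.01)
  # worked reference value for the canonical example table
  expect_equal(bcpnn_stat(10, 90, 100, 9900)$ic, 2.382489, tolerance = 1e-5)
})

test_that("ic025 lies strictly below ic across a random sweep", {
  tt <- random_tables(200, seed = 23)
  ic <- bcpnn_stat(tt$a, tt$b, tt$c, tt$d)
  expect_true(all(ic$ic025 < ic$ic))
  expect_true(all(is.finite(ic$ic)))
})

test_that("closed-form IC agrees with the Monte-Carlo posterior oracle", {
  tt <- random_tables(20, seed = 25, amax = 500)
  tt$a <- pmax(tt$a, 5)
  set.seed(99)
  for (i in seq_len(nrow(tt))) {
    ic <- bcpnn_stat(tt$a[i], tt$b[i], tt$c[i], tt$d[i])$ic
    mc <- mc_ic_oracle(tt$a[i], tt$b[i], tt$c[i], tt$d[i])
    expect_lt(abs(ic - mc), 0.05)
  }
})

test_that("EBGM matches the quadrature oracle on a spot grid", {
  prior <- test_prior()
  for (a in c(0, 3, 10, 35)) {
    for (E in c(0.1, 1, 10)) {
      got <- ebgm_stat(a, E, prior)
      want <- quad_ebgm_oracle(a, E, prior)
      expect_equal(got$ebgm, want$ebgm, tolerance = 1e-6,
                   label = sprintf("ebgm a=%d E=%g", a, E))
      expect_equal(got$ebgm05, want$q05, tolerance = 1e-6,
                   label = sprintf("ebgm05 a=%d E=%g", a, E))
    }
  }
})

test_that("EBGM shrinks to a/E asymptotically and is monotone in a", {
  prior <- test_prior()
  big <- ebgm_stat(5000, 1000, prior)
  expect_equal(big$ebgm, 5, tolerance = 0.01)

  seq_a <- 0:40
  eb <- ebgm_stat(seq_a, 2, prior)
  expect_true(all(diff(eb$ebgm) > 0))
  expect_true(all(eb$ebgm05 < eb$ebgm))
})

test_that("MGPS prior fit recovers simulated hyperparameters", {
  set.seed(31)
  n <- 2e4
  truth <- test_prior()
  comp <- runif(n) < truth$P
  lam <- ifelse(comp, rgamma(n, truth$alpha1, rate = truth$beta1),
                rgamma(n, truth$alpha2, rate = truth$beta2))
  E <- rlnorm(n, 0, 1)
  a <- rpois(n, lam * E)
  # simulated cells include zeros, so the untruncated likelihood applies
  fit <- fit_mgps_prior(a, E, include_zeros = TRUE)
  pars <- c(fit$alpha1, fit$beta1, fit$alpha2, fit$beta2, fit$P)
  want <- c(truth$alpha1, truth$beta1, truth$alpha2, truth$beta2, truth$P)
  expect_true(all(abs(pars - want) / want < 0.25))
  # optimizer contract: fitted likelihood beats the generating values
  ll_fit <- faersignal:::.mgps_loglik(pars, a, E, FALSE)
  ll_start <- faersignal:::.mgps_loglik(want, a, E, FALSE)
  expect_gte(ll_fit, ll_start - 1e-6)
})

test_that("near single-component data reaches likelihood parity", {
  set.seed(33)
  n <- 5e3
  lam <- rgamma(n, 2, rate = 2)          # one-component truth
  E <- rlnorm(n, 0, 0.5)
  a <- rpois(n, lam * E)
  fit <- fit_mgps_prior(a, E)
  keep <- a >= 1
  ll_fit <- faersignal:::.mgps_loglik(
    c(fit$alpha1, fit$beta1, fit$alpha2, fit$beta2, fit$P),
    a[keep], E[keep], TRUE)
  ll_true <- faersignal:::.mgps_loglik(c(2, 2, 2, 2, 0.5),
                                       a[keep], E[keep], TRUE)
  expect_gte(ll_fit, ll_true - 1e-4)
})

test_that("signal flags follow the threshold quartet", {
  ct <- structure(data.frame(term = c("hi", "low_count"), level = "pt",
                             a = c(50L, 1L), b = c(450L, 499L),
                             c = c(100L, 10L), d = c(9400L, 9490L),
                             n = 10000L),
                  class = c("contingency_set", "data.frame"))
  sig <- detect_signals(ct, test_prior())
  hi <- sig[sig$term == "hi", ]
  expect_true(hi$ror_signal && hi$prr_signal && hi$ic_signal &&
                hi$ebgm_signal && hi$any_signal)
  # a below the minimum-count rule blocks ROR/PRR flags however large the ratio
  low <- sig[sig$term == "low_count", ]
  expect_false(low$ror_signal || low$prr_signal)
  # output sorted by a descending
  expect_equal(sig$term, c("hi", "low_count"))
})

test_that("statistics depend only on the cells, not term labels", {
  ct <- structure(data.frame(term = c("t1", "t2"), level = "pt",
                             a = c(20L, 8L), b = c(180L, 192L),
                             c = c(60L, 90L), d = c(8000L, 7970L),
                             n = 8260L),
                  class = c("contingency_set", "data.frame"))
  relabeled <- ct
  relabeled$term <- c("zz_other", "aa_other")
  s1 <- detect_signals(ct, test_prior())
  s2 <- detect_signals(relabeled, test_prior())
  num <- c("ror", "prr", "chi2", "ic", "ic025", "ebgm", "ebgm05")
  expect_equal(s2[match(c("zz_other", "aa_other"), s2$term), num],
               s1[match(c("t1", "t2"), s1$term), num],
               ignore_attr = TRUE)
})
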