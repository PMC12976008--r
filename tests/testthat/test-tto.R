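tto_db <- function(start_dt, event_dt) {
  n <- length(start_dt)
  pid <- as.character(seq(900001, length.out = n))
  demo <- data.frame(primaryid = pid, caseid = pid, fda_dt = "20240601",
                     event_dt = event_dt, age = NA_character_,
                     age_cod = NA_character_, sex = NA_character_,
                     reporter_country = NA_character_,
                     occp_cod = NA_character_, stringsAsFactors = FALSE)
  drug <- data.frame(primaryid = pid, drug_seq = "1", role_cod = "PS",
                     drugname = "TARGET", stringsAsFactors = FALSE)
  ther <- data.frame(primaryid = pid, dsg_drug_seq = "1",
                     start_dt = start_dt, end_dt = NA_character_,
                     stringsAsFactors = FALSE)
  faers_data(demo = demo, drug = drug,
             reac = data.frame(primaryid = pid, pt = "x",
                               stringsAsFactors = FALSE),
             ther = ther)
}

test_that("time-to-onset is event minus earliest PS start, day precision only", {
  db <- tto_db(c("20240101", "202401", "20240201", "20240301"),
               c("20240131", "20240131", "20240201", "20240201"))
  tto <- compute_tto(db)
  # eligible: only the first (30 d); second has month-precision start,
  # third tto = 0, fourth tto < 0
  expect_equal(as.numeric(tto), 30)
  expect_equal(attr(tto, "n_eligible"), 1L)
  expect_equal(sum(attr(tto, "excluded")), 3L)

  # earliest PS start anchors exposure when several therapy rows exist
  db2 <- tto_db("20240110", "20240120")
  db2$drug <- rbind(db2$drug,
                    data.frame(primaryid = db2$demo$primaryid, drug_seq = "2",
                               role_cod = "PS", drugname = "TARGET"))
  db2$ther <- rbind(db2$ther,
                    data.frame(primaryid = db2$demo$primaryid,
                               dsg_drug_seq = "2", start_dt = "20240101",
                               end_dt = NA_character_))
  expect_equal(as.numeric(compute_tto(db2)), 19)
})

test_that("onset quantiles use linear interpolation", {
  s <- onset_summary(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(s$n, 5L)
})

test_that("Weibull MLE matches an independent fitter and its invariants", {
  skip_if_not_installed("fitdistrplus")
  set.seed(41)
  x <- rweibull(500, shape = 0.8, scale = 150)
  fit <- fit_weibull_tto(x)
  ref <- fitdistrplus::fitdist(x, "weibull")
  expect_equal(fit$beta, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(fit$alpha, unname(ref$estimate["scale"]), tolerance = 1e-3)
  # both fits reach the same maximized likelihood
  ll_ref <- sum(dweibull(x, shape = ref$estimate["shape"],
                         scale = ref$estimate["scale"], log = TRUE))
  expect_equal(fit$loglik, ll_ref, tolerance = 1e-8)
  expect_gte(fit$loglik, ll_ref - 1e-6)

  # scale equivariance: t -> k t multiplies alpha by k, leaves beta alone
  # (to the optimizer's numerical tolerance)
  fit_k <- fit_weibull_tto(x * 3)
  expect_equal(fit_k$alpha, fit$alpha * 3, tolerance = 1e-3)
  expect_equal(fit_k$beta, fit$beta, tolerance = 1e-3)

  # MLE dominates a coarse grid of alternatives
  ll <- function(al, be) sum(dweibull(x, shape = be, scale = al, log = TRUE))
  grid <- expand.grid(al = c(50, 100, 150, 200, 300),
                      be = c(0.5, 0.8, 1, 1.5))
  expect_true(all(fit$loglik + 1e-8 >=
                    mapply(ll, grid$al, grid$be)))
})

test_that("exponential data gives random_failure and rate near 1/mean", {
  set.seed(43)
  x <- rexp(1000, rate = 1 / 100)
  fit <- fit_weibull_tto(x)
  expect_equal(fit$classification, "random_failure")
  se_log_beta <- (log(fit$beta_hi) - log(fit$beta_lo)) / (2 * 1.96)
  expect_lt(abs(log(fit$beta)) / se_log_beta, 3)   # beta within 3 SE of 1
  # at beta = 1 the scale MLE is the closed-form exponential mean
  ll_alpha <- function(al) sum(dweibull(x, 1, al, log = TRUE))
  cand <- mean(x) * c(0.9, 0.95, 1, 1.05, 1.1)
  expect_equal(which.max(vapply(cand, ll_alpha, numeric(1))), 3L)
})

test_that("degenerate or tiny samples are refused", {
  expect_error(fit_weibull_tto(rep(5, 50)), "degenerate")
  expect_error(fit_weibull_tto(1:5), "at least 10")
  expect_error(fit_weibull_tto(c(rep(2, 10), 0)), "positive")
})

test_that("histogram bins onset times in 30-day windows", {
  h <- tto_histogram(c(1, 30, 31, 400), max_days = 60)
  expect_equal(h$count[h$bin == "1-30"], 2L)
  expect_equal(h$count[h$bin == "31-60"], 1L)
  expect_equal(h$count[h$bin == ">60"], 1L)
})
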