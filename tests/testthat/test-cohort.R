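make_demo <- function(primaryid, caseid, fda_dt) {
  data.frame(primaryid = primaryid, caseid = caseid, fda_dt = fda_dt,
             event_dt = NA_character_, age = NA_character_,
             age_cod = NA_character_, sex = NA_character_,
             reporter_country = NA_character_, occp_cod = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("dedup keeps latest fda_dt, ties broken by highest primaryid", {
  d <- make_demo(c("71", "72"), c("7", "7"), c("20240101", "20240301"))
  expect_equal(deduplicate(d)$primaryid, "72")

  d <- make_demo(c("70001", "70009"), c("7", "7"), c("20240301", "20240301"))
  expect_equal(deduplicate(d)$primaryid, "70009")

  # unparseable date in a case falls back to primaryid-only comparison
  d <- make_demo(c("70009", "70001"), c("7", "7"), c("2024", "20240301"))
  expect_warning(out <- deduplicate(d), "unparseable")
  expect_equal(out$primaryid, "70009")
})

test_that("dedup equals the brute-force oracle and is idempotent", {
  set.seed(11)
  n_case <- 100
  rows <- lapply(seq_len(n_case), function(i) {
    k <- sample(1:4, 1)
    cid <- as.character(1000 + i)
    make_demo(paste0(cid, seq_len(k)), rep(cid, k),
              sprintf("2024%02d%02d", sample(1:12, k, TRUE),
                      sample(1:28, k, TRUE)))
  })
  demo <- do.call(rbind, rows)
  demo <- demo[sample(nrow(demo)), ]          # order must not matter

  out <- deduplicate(demo)
  expect_equal(nrow(out), n_case)
  expect_false(anyDuplicated(out$caseid) > 0)
  expect_setequal(out$primaryid, brute_dedup(demo))
  expect_equal(deduplicate(out), out)          # idempotent
})

test_that("primary-suspect selection follows role and dictionary", {
  demo <- make_demo(c("1", "2", "3"), c("1", "2", "3"), "20240101")
  drug <- data.frame(
    primaryid = c("1", "2", "2", "3"),
    drug_seq = c("1", "1", "2", "1"),
    role_cod = c("C", "PS", "PS", "PS"),
    drugname = c("target", "TARGET ", "other", "OTHER"),
    stringsAsFactors = FALSE)
  dat <- faers_data(demo = demo, drug = drug,
                    reac = data.frame(primaryid = c("1", "2", "3"),
                                      pt = "x", stringsAsFactors = FALSE))
  sp <- select_primary_suspect(dat, drug_dictionary("Target"))
  expect_equal(sp$cohort$demo$primaryid, "2")   # role C excluded; 2 PS, one matches
  expect_setequal(sp$comparator$demo$primaryid, c("1", "3"))
  expect_error(drug_dictionary(character(0)))
  expect_error(drug_dictionary("  "))
})

test_that("selection recovers the generator's planted cohort exactly", {
  sim <- simulate_faers(sim_config(n_cases = 2000, seed = 3))
  dd <- apply_dedup(sim$data)
  sp <- select_primary_suspect(dd, drug_dictionary(sim$config$target_drug))
  expect_equal(nrow(sp$cohort$demo), sim$manifest$expected_cohort_cases)
  truth <- sim$manifest$case
  expect_setequal(unique(sp$cohort$demo$caseid),
                  truth$caseid[truth$is_target])
})

test_that("baseline summary handles a single case and rounds half-up", {
  demo <- make_demo("1", "1", "20240101")
  demo$sex <- "M"
  dat <- faers_data(demo = demo)
  bl <- summarize_baseline(dat)
  expect_equal(baseline_cell(bl, "sex", "Male")$percent, 100.0)
  expect_equal(round_half_up(c(0.05, 0.15, 32.816, 9.021), 1),
               c(0.1, 0.2, 32.8, 9.0))

  empty <- summarize_baseline(faers_data(demo = demo[0, , drop = FALSE]))
  expect_equal(attr(empty, "total"), 0L)
  expect_equal(nrow(empty), 0L)
})

test_that("baseline counts are order-invariant and percents sum to ~100", {
  sim <- simulate_faers(sim_config(n_cases = 1500, seed = 5))
  dd <- apply_dedup(sim$data)
  bl1 <- summarize_baseline(dd)
  perm <- dd
  set.seed(1)
  for (k in faers_table_kinds()) {
    perm[[k]] <- perm[[k]][sample(nrow(perm[[k]])), , drop = FALSE]
  }
  bl2 <- summarize_baseline(perm)
  key <- function(b) b[order(b$dimension, b$level), c("count", "percent")]
  expect_equal(key(bl2), key(bl1), ignore_attr = TRUE)

  # dimensions with an explicit Unknown level partition the cohort
  for (dim in c("sex", "age_group", "reporter", "year")) {
    rows <- bl1[bl1$dimension == dim, ]
    expect_equal(sum(rows$count), attr(bl1, "total"))
    expect_lt(abs(sum(rows$percent) - 100), 0.1 * nrow(rows) + 1e-9)
  }
})

test_that("age bin boundaries follow the stated convention", {
  grp <- faersignal:::.age_group(c(17.9, 18, 65, 65.1, 85, 86, NA))
  expect_equal(grp, c("<18", "18-65", "18-65", "65-85", "65-85", ">85",
                      "Unknown"))
})
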