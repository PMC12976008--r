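# Synthetic spontaneous-reporting generator with known ground truth.
#
# Emulates the statistical structure a FAERS disproportionality analysis
# assumes: a study drug holding a share of primary-suspect reports, a
# heavy-tailed (Zipf) background of event terms reported independently of
# drug, planted drug-event associations with a specified relative
# reporting ratio, Table-1-shaped demographic marginals, Weibull onset
# times, partial dates, and injected duplicate case versions.  Every draw
# comes from one seeded stream, so outputs are byte-reproducible.

#' Configuration of the synthetic report generator
#'
#' Defaults mirror the marginal structure of a published study-drug cohort:
#' demographic proportions shaped like the baseline table, a Zipf
#' background over event terms, onset times Weibull(scale 198.63 days,
#' shape 0.63) (an early-failure pattern), and a 10% duplicate-version
#' rate.
#'
#' @param n_cases number of distinct cases.
#' @param target_drug study drug name.
#' @param target_share fraction of cases with the study drug as primary
#'   suspect.
#' @param drug_vocab comparator drug names (Zipf-weighted popularity).
#' @param pt_vocab event preferred terms.
#' @param n_soc number of organ classes the PTs are cycled over.
#' @param background_rates per-PT baseline reporting probability (named
#'   vector over `pt_vocab`); default Zipf: `0.05 / sqrt(rank)`.
#' @param planted_signals data.frame with columns `drug`, `pt`, `rr`:
#'   the reporting probability of `pt` is multiplied by `rr` for cases
#'   whose PS drug is `drug`.
#' @param demo_marginals named list of probability vectors for `sex`,
#'   `age`, `country`, `reporter`, `year`.
#' @param outcome_rates per-code outcome probabilities.
#' @param comed_rates named per-drug probabilities of a concomitant record.
#' @param duplicate_rate fraction of cases emitted in more than one
#'   version.
#' @param tto_scale,tto_shape Weibull onset-time parameters (days).
#' @param missing_date_rate fraction of therapy start dates emitted at
#'   month precision (ineligible for onset analysis).
#' @param seed integer seed fixing all randomness.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 10000,
                       target_drug = "STUDYDRUG",
                       target_share = 0.05,
                       drug_vocab = sprintf("DRUG_%02d", 1:20),
                       pt_vocab = sprintf("pt_%02d", 1:30),
                       n_soc = 5,
                       background_rates = NULL,
                       planted_signals = NULL,
                       demo_marginals = NULL,
                       outcome_rates = c(HO = 0.14, DE = 0.05, LT = 0.007,
                                         DS = 0.002),
                       comed_rates = c(COMED_A = 0.10, COMED_B = 0.05,
                                       COMED_C = 0.03),
                       duplicate_rate = 0.1,
                       tto_scale = 198.63, tto_shape = 0.63,
                       missing_date_rate = 0.1,
                       seed = 1L) {
  if (is.null(background_rates)) {
    # Zipf popularity scaled so a report carries ~3 event terms on average
    # (spontaneous reports typically list a handful of PTs)
    background_rates <- stats::setNames(0.3 / sqrt(seq_along(pt_vocab)),
                                        pt_vocab)
  }
  stopifnot(all(names(background_rates) %in% pt_vocab),
            all(background_rates >= 0 & background_rates <= 1),
            target_share > 0, target_share < 1,
            duplicate_rate >= 0, duplicate_rate < 1,
            missing_date_rate >= 0, missing_date_rate <= 1)
  if (is.null(planted_signals)) {
    planted_signals <- data.frame(drug = character(0), pt = character(0),
                                  rr = numeric(0))
  }
  stopifnot(all(planted_signals$rr >= 0),
            all(planted_signals$pt %in% pt_vocab))
  if (is.null(demo_marginals)) {
    demo_marginals <- list(
      sex = c(M = 0.292, F = 0.328, UNK = 0.380),
      age = c("<18" = 0.019, "18-65" = 0.112, "65-85" = 0.090,
              Unknown = 0.779),
      country = c(US = 0.852, JP = 0.053, GB = 0.017, DE = 0.014,
                  CA = 0.010, FR = 0.054),
      reporter = c(CN = 0.522, MD = 0.207, HP = 0.048, PH = 0.031,
                   UNK = 0.192),
      year = c("2019" = 0.058, "2020" = 0.044, "2021" = 0.043,
               "2022" = 0.043, "2023" = 0.154, "2024" = 0.492,
               "2025" = 0.166))
  }
  soc <- sprintf("SOC_%02d", rep_len(seq_len(n_soc), length(pt_vocab)))
  structure(list(n_cases = n_cases, target_drug = target_drug,
                 target_share = target_share, drug_vocab = drug_vocab,
                 pt_vocab = pt_vocab, soc_map = soc_map(pt_vocab, soc),
                 background_rates = background_rates,
                 planted_signals = planted_signals,
                 demo_marginals = demo_marginals,
                 outcome_rates = outcome_rates, comed_rates = comed_rates,
                 duplicate_rate = duplicate_rate,
                 tto_scale = tto_scale, tto_shape = tto_shape,
                 missing_date_rate = missing_date_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.sample_level <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic FAERS-style database with ground truth
#'
#' @param config a [sim_config()].
#' @return list of class `faers_sim` with elements `data` (a
#'   [faers_data()] object, readable and writable by the ASCII dialect
#'   functions) and `manifest` (ground truth: per-case assignments,
#'   planted pairs, duplicate lineage and expected counts).
#' @export
simulate_faers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cases
  m <- config$demo_marginals

  caseid <- as.character(seq(10000001L, length.out = n))
  primaryid <- paste0(caseid, "1")

  is_target <- stats::runif(n) < config$target_share
  ps_drug <- character(n)
  ps_drug[is_target] <- config$target_drug
  n_bg <- sum(!is_target)
  zipf <- 1 / seq_along(config$drug_vocab)
  ps_drug[!is_target] <- sample(config$drug_vocab, n_bg, replace = TRUE,
                                prob = zipf)

  sex <- .sample_level(n, m$sex)
  sex[sex == "UNK"] <- NA_character_
  age_grp <- .sample_level(n, m$age)
  age <- rep(NA_integer_, n)
  age[age_grp == "<18"] <- sample(1:17, sum(age_grp == "<18"), TRUE)
  age[age_grp == "18-65"] <- sample(18:65, sum(age_grp == "18-65"), TRUE)
  age[age_grp == "65-85"] <- sample(66:85, sum(age_grp == "65-85"), TRUE)
  country <- .sample_level(n, m$country)
  reporter <- .sample_level(n, m$reporter)
  reporter[reporter == "UNK"] <- NA_character_
  year <- as.integer(.sample_level(n, m$year))
  fda_dt <- sprintf("%04d%02d%02d", year,
                    sample(1:12, n, TRUE), sample(1:28, n, TRUE))

  # event assignment: per PT, background probability times any planted
  # relative reporting ratio for the case's PS drug
  pmat_col <- function(pt) {
    p <- rep(unname(config$background_rates[pt]), n)
    pl <- config$planted_signals
    pl <- pl[pl$pt == pt, , drop = FALSE]
    for (j in seq_len(nrow(pl))) {
      sel <- ps_drug == pl$drug[j]
      p[sel] <- pmin(1, p[sel] * pl$rr[j])
    }
    p
  }
  reac_id <- vector("list", length(config$pt_vocab))
  pcols <- vector("list", length(config$pt_vocab))
  for (k in seq_along(config$pt_vocab)) {
    pcols[[k]] <- pmat_col(config$pt_vocab[k])
    reac_id[[k]] <- which(stats::runif(n) < pcols[[k]])
  }
  reac <- data.frame(
    primaryid = primaryid[unlist(reac_id)],
    pt = rep(config$pt_vocab, lengths(reac_id)),
    stringsAsFactors = FALSE)
  # every case reports at least one event; the fallback term is drawn from
  # the case's OWN probability vector (planting included) so planted
  # relative reporting ratios survive the conditioning
  empty_idx <- which(!(primaryid %in% reac$primaryid))
  if (length(empty_idx)) {
    pm <- do.call(cbind, pcols)            # n x n_pt
    extra_pt <- vapply(empty_idx, function(i) {
      sample(config$pt_vocab, 1, prob = pm[i, ])
    }, character(1))
    reac <- rbind(reac, data.frame(primaryid = primaryid[empty_idx],
                                   pt = extra_pt, stringsAsFactors = FALSE))
  }

  # onset times: event date = therapy start + Weibull gap (days)
  tto_days <- pmax(1, ceiling(stats::rweibull(n, shape = config$tto_shape,
                                              scale = config$tto_scale)))
  fda_date <- as.Date(fda_dt, format = "%Y%m%d")
  start_date <- fda_date - 30L - tto_days
  event_date <- start_date + tto_days
  start_partial <- stats::runif(n) < config$missing_date_rate
  start_dt <- ifelse(start_partial, format(start_date, "%Y%m"),
                     format(start_date, "%Y%m%d"))
  event_dt <- format(event_date, "%Y%m%d")

  demo <- data.frame(primaryid = primaryid, caseid = caseid,
                     fda_dt = fda_dt, event_dt = event_dt,
                     age = as.character(age),
                     age_cod = ifelse(is.na(age), NA_character_, "YR"),
                     sex = sex, reporter_country = country,
                     occp_cod = reporter, stringsAsFactors = FALSE)

  drug <- data.frame(primaryid = primaryid, drug_seq = "1",
                     role_cod = "PS", drugname = ps_drug,
                     stringsAsFactors = FALSE)
  comed_assign <- list()
  for (j in seq_along(config$comed_rates)) {
    nm <- names(config$comed_rates)[j]
    sel <- stats::runif(n) < config$comed_rates[[j]]
    if (any(sel)) {
      comed_assign[[nm]] <- primaryid[sel]
      drug <- rbind(drug, data.frame(primaryid = primaryid[sel],
                                     drug_seq = as.character(j + 1L),
                                     role_cod = "C", drugname = nm,
                                     stringsAsFactors = FALSE))
    }
  }

  ther <- data.frame(primaryid = primaryid, dsg_drug_seq = "1",
                     start_dt = start_dt, end_dt = NA_character_,
                     stringsAsFactors = FALSE)

  ind_pool <- c("condition alpha", "condition beta", "condition gamma")
  ind <- sample(c(ind_pool, NA_character_), n, TRUE,
                prob = c(0.35, 0.2, 0.1, 0.35))
  has_ind <- !is.na(ind)
  indi <- data.frame(primaryid = primaryid[has_ind], indi_drug_seq = "1",
                     indi_pt = ind[has_ind], stringsAsFactors = FALSE)

  outc <- do.call(rbind, lapply(names(config$outcome_rates), function(code) {
    sel <- stats::runif(n) < config$outcome_rates[[code]]
    data.frame(primaryid = primaryid[sel],
               outc_cod = rep(code, sum(sel)),
               stringsAsFactors = FALSE)
  }))

  # duplicate case versions: same caseid, perturbed fda_dt / primaryid only
  dup_sel <- which(stats::runif(n) < config$duplicate_rate)
  dup_rows <- list(); dup_lineage <- NULL
  if (length(dup_sel)) {
    n_extra <- sample(1:2, length(dup_sel), TRUE, prob = c(0.7, 0.3))
    for (i in seq_along(dup_sel)) {
      idx <- dup_sel[i]
      for (v in seq_len(n_extra[i]) + 1L) {
        pid <- paste0(caseid[idx], v)
        delta <- sample(-40:40, 1)
        new_fda <- format(fda_date[idx] + delta, "%Y%m%d")
        dup_rows[[length(dup_rows) + 1L]] <-
          list(src = primaryid[idx], pid = pid, fda = new_fda, idx = idx)
      }
    }
    dup_lineage <- data.frame(
      caseid = caseid[vapply(dup_rows, `[[`, 1L, "idx")],
      primaryid = vapply(dup_rows, `[[`, character(1), "pid"),
      fda_dt = vapply(dup_rows, `[[`, character(1), "fda"),
      stringsAsFactors = FALSE)
  }
  copy_rows <- function(tab) {
    if (is.null(dup_lineage) || nrow(tab) == 0L) return(tab)
    src <- vapply(dup_rows, `[[`, character(1), "src")
    pid <- vapply(dup_rows, `[[`, character(1), "pid")
    idx_by_pid <- split(seq_len(nrow(tab)), tab$primaryid)
    rows_idx <- idx_by_pid[src]
    take <- unlist(rows_idx, use.names = FALSE)
    if (length(take) == 0L) return(tab)
    extras <- tab[take, , drop = FALSE]
    extras$primaryid <- rep(pid, lengths(rows_idx))
    rbind(tab, extras)
  }
  if (!is.null(dup_lineage)) {
    extra_demo <- demo[match(dup_lineage$caseid, demo$caseid), , drop = FALSE]
    extra_demo$primaryid <- dup_lineage$primaryid
    extra_demo$fda_dt <- dup_lineage$fda_dt
    demo <- rbind(demo, extra_demo)
    drug <- copy_rows(drug); reac <- copy_rows(reac); ther <- copy_rows(ther)
    indi <- copy_rows(indi); outc <- copy_rows(outc)
  }

  # ground-truth winner of the dedup rule per case
  key_fda <- as.numeric(demo$fda_dt)
  key_pid <- as.numeric(demo$primaryid)
  ord <- order(demo$caseid, key_fda, key_pid)
  winners <- demo[ord, ][!duplicated(demo$caseid[ord], fromLast = TRUE), ,
                         drop = FALSE]

  manifest <- list(
    case = data.frame(caseid = caseid, primaryid = primaryid,
                      ps_drug = ps_drug, is_target = is_target,
                      sex = ifelse(is.na(sex), "Unknown", sex),
                      age_group = age_grp, year = year,
                      tto_days = tto_days,
                      tto_eligible = !start_partial,
                      stringsAsFactors = FALSE),
    planted = config$planted_signals,
    duplicates = dup_lineage,
    winners = stats::setNames(winners$primaryid, winners$caseid),
    comeds = comed_assign,
    expected_case_count = n,
    expected_cohort_cases = sum(is_target))

  dat <- faers_data(demo = demo, drug = drug, reac = reac, ther = ther,
                    indi = indi, outc = outc)
  structure(list(data = dat, manifest = manifest, config = config),
            class = "faers_sim")
}

#' @export
print.faers_sim <- function(x, ...) {
  cat("<faers_sim> ", x$manifest$expected_case_count, " cases (",
      x$manifest$expected_cohort_cases, " with ", x$config$target_drug,
      " as PS), seed ", x$config$seed, "\n", sep = "")
  print(x$data)
  invisible(x)
}

#' Deterministic fixture reproducing published baseline marginals
#'
#' A 9,090-case database whose marginal counts equal a published
#' study-drug cohort's baseline table: 2,655 male / 2,983 female; ages
#' 172 under 18, 1,014 in 18-65, 820 in 65-85; indications 3,351
#' myasthenia gravis, 1,951 paroxysmal nocturnal haemoglobinuria, 965
#' atypical haemolytic uraemic syndrome; outcomes 1,271 hospitalization,
#' 454 death, 60 life-threatening, 14 disability; 7,744 US, 478 Japan,
#' 151 UK, 125 Germany, 87 Canada; reporters 4,748 consumer, 1,884
#' physician, 432 health professional, 282 pharmacist; yearly counts
#' 525/401/388/395/1,403/4,476/1,502 for 2019-2025.  The joint structure
#' is arbitrary: dimensions are filled independently in blocks.
#'
#' @return a [faers_data()] object of 9,090 deduplicated cases.
#' @export
table1_fixture <- function() {
  n <- 9090L
  caseid <- as.character(seq(20000001L, length.out = n))
  primaryid <- paste0(caseid, "1")

  fill <- function(counts, labels, default = NA_character_) {
    out <- rep(default, n)
    pos <- 1L
    for (i in seq_along(counts)) {
      if (counts[i] > 0) out[pos:(pos + counts[i] - 1L)] <- labels[i]
      pos <- pos + counts[i]
    }
    out
  }

  sex <- fill(c(2655L, 2983L), c("M", "F"))
  age <- fill(c(172L, 1014L, 820L), c("10", "40", "75"))
  age_cod <- ifelse(is.na(age), NA_character_, "YR")
  year <- fill(c(525L, 401L, 388L, 395L, 1403L, 4476L, 1502L),
               as.character(2019:2025))
  fda_dt <- paste0(year, "0615")
  # remainder countries each kept below the 5th-ranked count (87)
  country <- fill(c(7744L, 478L, 151L, 125L, 87L, 86L, 86L, 86L, 86L, 86L,
                    75L),
                  c("US", "JP", "GB", "DE", "CA", paste0("C0", 1:6)))
  occp <- fill(c(4748L, 1884L, 432L, 282L), c("CN", "MD", "HP", "PH"))

  demo <- data.frame(primaryid = primaryid, caseid = caseid,
                     fda_dt = fda_dt, event_dt = NA_character_,
                     age = age, age_cod = age_cod, sex = sex,
                     reporter_country = country, occp_cod = occp,
                     stringsAsFactors = FALSE)
  drug <- data.frame(primaryid = primaryid, drug_seq = "1",
                     role_cod = "PS", drugname = "RAVULIZUMAB",
                     stringsAsFactors = FALSE)
  ind <- fill(c(3351L, 1951L, 965L),
              c("Myasthenia gravis", "Paroxysmal nocturnal haemoglobinuria",
                "Atypical haemolytic uraemic syndrome"))
  has_ind <- !is.na(ind)
  indi <- data.frame(primaryid = primaryid[has_ind], indi_drug_seq = "1",
                     indi_pt = ind[has_ind], stringsAsFactors = FALSE)
  outc_code <- fill(c(1271L, 454L, 60L, 14L), c("HO", "DE", "LT", "DS"))
  has_outc <- !is.na(outc_code)
  outc <- data.frame(primaryid = primaryid[has_outc],
                     outc_cod = outc_code[has_outc], stringsAsFactors = FALSE)
  reac <- data.frame(primaryid = primaryid, pt = "fatigue",
                     stringsAsFactors = FALSE)

  faers_data(demo = demo, drug = drug, reac = reac, indi = indi, outc = outc)
}
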