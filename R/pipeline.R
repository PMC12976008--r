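# End-to-end pipeline: extract -> deduplicate -> PS filter -> code ->
# analyze, with publication-style CSV outputs and an attrition log.

#' Pipeline configuration
#'
#' @param data a [faers_data()] object (already read from disk or
#'   simulated); alternatively give `input_dir` to read the ASCII tables.
#' @param input_dir directory of FAERS-style ASCII tables (used when
#'   `data` is `NULL`).
#' @param dict a [drug_dictionary()] identifying the study drug.
#' @param map optional PT to SOC map (named vector or path to TSV); when
#'   absent the SOC-level table is skipped.
#' @param outdir output directory.
#' @param levels which term levels to analyze (`"pt"`, `"soc"`).
#' @param subgroups character vector of stratification dimensions among
#'   `"sex"`, `"age_group"`, `"reporter"` (empty to skip).
#' @param sensitivity_drugs drug names to exclude in the sensitivity
#'   analysis (empty to skip).
#' @param run_tto fit the Weibull time-to-onset model?
#' @param thresholds signal thresholds, see [signal_thresholds()].
#' @param seed integer seed recorded in the run manifest.
#' @return list of class `run_config`.
#' @export
run_config <- function(data = NULL, input_dir = NULL, dict, map = NULL,
                       outdir, levels = c("pt", "soc"),
                       subgroups = c("sex", "age_group", "reporter"),
                       sensitivity_drugs = character(0),
                       run_tto = TRUE,
                       thresholds = signal_thresholds(), seed = 1L) {
  if (is.null(data) && is.null(input_dir)) {
    stop("run_config needs either `data` or `input_dir`")
  }
  if (is.character(map) && length(map) == 1L) map <- read_soc_map(map)
  structure(list(data = data, input_dir = input_dir, dict = dict, map = map,
                 outdir = outdir, levels = levels, subgroups = subgroups,
                 sensitivity_drugs = sensitivity_drugs, run_tto = run_tto,
                 thresholds = thresholds, seed = as.integer(seed)),
            class = "run_config")
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

.fmt_stats <- function(sig) {
  num <- c("expected", "ror", "ror_lo", "ror_hi", "prr", "chi2",
           "ic", "ic025", "ebgm", "ebgm05")
  for (cl in num) sig[[cl]] <- round(sig[[cl]], 2)
  sig
}

#' Run the full signal-detection pipeline
#'
#' Stages: read (or take) the database, deduplicate by the FDA rule, split
#' into study-drug cohort and comparator, summarize baseline
#' characteristics, build contingency tables and run the four
#' disproportionality statistics at the requested term levels, fit the
#' Weibull time-to-onset model, re-run signals within demographic strata,
#' apply the concomitant-drug exclusion, and write every table as CSV plus
#' an attrition log and a run manifest.  Any stage failure aborts with the
#' stage name.
#'
#' @param config a [run_config()].
#' @return the output directory, invisibly; side effect: CSV files
#'   `baseline.csv`, `signals_pt.csv`, `signals_soc.csv`, `tto.csv`,
#'   `subgroup_*.csv`, `sensitivity.csv`, `attrition.csv`,
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  attrition <- list()

  data <- stage("extract", {
    if (!is.null(config$data)) config$data else read_faers_data(config$input_dir)
  })
  attrition$raw_reports <- nrow(data$demo)

  data <- stage("deduplicate", apply_dedup(data))
  attrition$deduplicated_cases <- nrow(data$demo)

  split <- stage("ps_filter", select_primary_suspect(data, config$dict))
  cohort <- split$cohort; comparator <- split$comparator
  attrition$cohort_cases <- nrow(cohort$demo)
  attrition$comparator_cases <- nrow(comparator$demo)

  stage("baseline", {
    bl <- summarize_baseline(cohort)
    .write_csv(cbind(total = attr(bl, "total"), bl),
               file.path(config$outdir, "baseline.csv"))
  })

  prior <- stage("mgps_prior", {
    cells <- mgps_cells(data, level = "pt")
    tryCatch(fit_mgps_prior(cells$a, cells$E),
             error = function(e) mgps_prior(0.2, 0.1, 2.0, 4.0, 1 / 3))
  })

  signals <- list()
  for (lv in config$levels) {
    if (lv == "soc" && is.null(config$map)) next
    signals[[lv]] <- stage(paste0("signals_", lv), {
      ct <- count_pairs(cohort, comparator, level = lv, map = config$map)
      sig <- detect_signals(ct, prior, config$thresholds)
      .write_csv(.fmt_stats(sig),
                 file.path(config$outdir, paste0("signals_", lv, ".csv")))
      sig
    })
  }

  if (config$run_tto) {
    stage("tto", {
      tto <- compute_tto(cohort, config$dict)
      attrition$tto_eligible <- attr(tto, "n_eligible")
      if (length(tto) >= 10) {
        fit <- fit_weibull_tto(tto)
        s <- onset_summary(tto)
        .write_csv(data.frame(n = s$n, median = s$median, q1 = s$q1,
                              q3 = s$q3,
                              alpha = fit$alpha, alpha_lo = fit$alpha_lo,
                              alpha_hi = fit$alpha_hi, beta = fit$beta,
                              beta_lo = fit$beta_lo, beta_hi = fit$beta_hi,
                              type = fit$classification),
                   file.path(config$outdir, "tto.csv"))
      }
    })
  }

  for (dim in config$subgroups) {
    stage(paste0("subgroup_", dim), {
      lv_all <- unique(assign_stratum(cohort$demo, dim))
      lv_all <- setdiff(lv_all, "Unknown")
      for (lv in lv_all) {
        sig <- tryCatch(
          subgroup_signals(cohort, comparator, dim, lv, prior = prior),
          error = function(e) NULL)
        if (!is.null(sig)) {
          .write_csv(.fmt_stats(sig),
                     file.path(config$outdir,
                               sprintf("subgroup_%s_%s.csv", dim,
                                       gsub("[^A-Za-z0-9]+", "_", lv))))
        }
      }
    })
  }

  if (length(config$sensitivity_drugs)) {
    stage("sensitivity", {
      sens <- sensitivity_exclude(data, config$sensitivity_drugs)
      split2 <- select_primary_suspect(sens$data, config$dict)
      ct <- count_pairs(split2$cohort, split2$comparator, level = "pt")
      sig <- detect_signals(ct, prior, config$thresholds)
      .write_csv(.fmt_stats(sig), file.path(config$outdir, "sensitivity.csv"))
      .write_csv(sens$attrition,
                 file.path(config$outdir, "sensitivity_attrition.csv"))
      attrition$sensitivity_cases <- sens$attrition$cases[2]
    })
  }

  .write_csv(data.frame(stage = names(attrition),
                        count = unlist(attrition)),
             file.path(config$outdir, "attrition.csv"))

  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("faersignal")),
                   r_version = R.version.string,
                   levels = config$levels,
                   thresholds = config$thresholds,
                   target = config$dict$target)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(config$outdir)
}
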