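# Case deduplication, primary-suspect cohort extraction and baseline
# characteristics.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; published pharmacovigilance tables
#' round half up.  A small epsilon guards against floating-point
#' representations just below .5 at the last printed digit.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

#' Normalize drug or event names for matching
#'
#' Uppercases, trims, and collapses internal whitespace.  Matching is exact
#' after normalization; no fuzzy matching is attempted, trading recall for
#' reproducibility.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_name <- function(x) {
  toupper(trimws(gsub("\\s+", " ", as.character(x))))
}

#' Drug-name dictionary for cohort selection
#'
#' @param target character vector of names identifying the study drug
#'   (generic plus brand strings).
#' @param exclude optional character vector of names used by the
#'   sensitivity analysis (co-medications to exclude on).
#' @return object of class `drug_dictionary`.
#' @export
drug_dictionary <- function(target, exclude = character(0)) {
  target <- unique(normalize_name(target))
  target <- target[nzchar(target)]
  if (length(target) == 0L) stop("drug dictionary needs at least one target name")
  structure(list(target = target, exclude = unique(normalize_name(exclude))),
            class = "drug_dictionary")
}

#' Deduplicate case versions by the FDA rule
#'
#' FAERS publishes every version of a case; analyses keep one row per case:
#' the version with the latest FDA receipt date (`fda_dt`), ties broken by
#' the numerically highest `primaryid`.  If any version of a case has an
#' unparseable `fda_dt`, the whole case falls back to the primaryid-only
#' comparison and a warning is raised.  The operation is idempotent.
#'
#' @param demo DEMO data.frame with `primaryid`, `caseid`, `fda_dt`.
#' @return the subset of `demo` with exactly one row per `caseid`.
#' @export
deduplicate <- function(demo) {
  stopifnot(all(c("primaryid", "caseid", "fda_dt") %in% names(demo)))
  if (nrow(demo) == 0L) return(demo)
  prec <- parse_partial_date(demo$fda_dt)$precision
  fda_key <- suppressWarnings(as.numeric(demo$fda_dt))
  fda_key[prec != "day"] <- NA_real_
  pid_key <- suppressWarnings(as.numeric(demo$primaryid))

  bad_group <- as.logical(ave(is.na(fda_key), demo$caseid, FUN = any))
  if (any(bad_group)) {
    warning(sum(is.na(fda_key)), " record(s) with unparseable fda_dt; ",
            "affected cases deduplicated by primaryid only")
  }
  fda_cmp <- ifelse(bad_group, 0, fda_key)
  ord <- order(demo$caseid, fda_cmp, pid_key)
  keep_last <- !duplicated(demo$caseid[ord], fromLast = TRUE)
  out <- demo[ord[keep_last], , drop = FALSE]
  out[order(suppressWarnings(as.numeric(out$caseid)), out$caseid), , drop = FALSE]
}

#' Deduplicate an entire database
#'
#' Applies [deduplicate()] to the DEMO table and restricts all child tables
#' to the surviving report versions.
#'
#' @param data a [faers_data()] object.
#' @return deduplicated [faers_data()] object with attribute
#'   `"n_duplicates_removed"`.
#' @export
apply_dedup <- function(data) {
  stopifnot(inherits(data, "faers_data"))
  kept <- deduplicate(data$demo)
  out <- subset_faers(data, kept$primaryid)
  out$demo <- kept
  attr(out, "n_duplicates_removed") <- nrow(data$demo) - nrow(kept)
  out
}

#' Split a database into study-drug cohort and comparator
#'
#' A report enters the cohort iff at least one of its drug records has role
#' `PS` (primary suspect) and a name matching the dictionary's target set
#' after normalization.  All remaining reports form the comparator ("rest of
#' database") used for contingency building.
#'
#' @param data deduplicated [faers_data()] object.
#' @param dict a [drug_dictionary()].
#' @return list with elements `cohort` and `comparator`, both
#'   [faers_data()] objects.
#' @export
select_primary_suspect <- function(data, dict) {
  stopifnot(inherits(data, "faers_data"), inherits(dict, "drug_dictionary"))
  drug <- data$drug
  is_target_ps <- toupper(trimws(drug$role_cod)) == "PS" &
    normalize_name(drug$drugname) %in% dict$target
  cohort_ids <- unique(drug$primaryid[is_target_ps])
  all_ids <- unique(data$demo$primaryid)
  list(cohort = subset_faers(data, cohort_ids),
       comparator = subset_faers(data, setdiff(all_ids, cohort_ids)))
}

.reporter_labels <- c(CN = "Consumer", MD = "Physician",
                      HP = "Health Professional", PH = "Pharmacist",
                      OT = "Other")

.age_group <- function(age_years, breaks = c(18, 65, 85)) {
  b <- sort(breaks)
  lab <- rep("Unknown", length(age_years))
  known <- !is.na(age_years)
  lab[known & age_years < b[1]] <- paste0("<", b[1])
  lab[known & age_years >= b[1] & age_years <= b[2]] <- paste0(b[1], "-", b[2])
  if (length(b) >= 3) {
    lab[known & age_years > b[2] & age_years <= b[3]] <- paste0(b[2], "-", b[3])
    lab[known & age_years > b[3]] <- paste0(">", b[3])
  } else {
    lab[known & age_years > b[2]] <- paste0(">", b[2])
  }
  lab
}

.count_level <- function(dimension, levels_vec, total) {
  tab <- table(levels_vec)
  data.frame(dimension = rep(dimension, length(tab)),
             level = as.character(names(tab)),
             count = as.integer(tab),
             percent = round_half_up(as.integer(tab) / total * 100, 1),
             stringsAsFactors = FALSE)
}

#' Baseline characteristics of a report cohort
#'
#' Tabulates sex, age group, top indications of the primary-suspect drug,
#' serious outcomes, top reporting countries, reporter type and reporting
#' year, with percentages of the total case count rounded half-up to one
#' decimal, in the layout of a published "Table 1".
#'
#' Age groups use `age_breaks` after unit normalization to years
#' ([age_in_years()]); the boundary value 65 falls in the middle bin.
#' Outcomes are counted once per case and code; indications once per case
#' and term over the PS drug's indication records.
#'
#' @param data deduplicated, PS-filtered [faers_data()] cohort.
#' @param age_breaks numeric bin edges (default `c(18, 65, 85)`).
#' @param top_indications,top_countries how many leading levels to report.
#' @return object of class `baseline_summary`: a data.frame with columns
#'   `dimension`, `level`, `count`, `percent`, and attribute `total`.
#' @export
summarize_baseline <- function(data, age_breaks = c(18, 65, 85),
                               top_indications = 3, top_countries = 5) {
  stopifnot(inherits(data, "faers_data"))
  demo <- data$demo
  total <- nrow(demo)
  if (total == 0L) {
    out <- data.frame(dimension = character(0), level = character(0),
                      count = integer(0), percent = numeric(0))
    return(structure(out, total = 0L, class = c("baseline_summary", "data.frame")))
  }

  sex <- toupper(trimws(demo$sex))
  sex[is.na(sex) | !(sex %in% c("M", "F"))] <- "Unknown"
  sex[sex == "M"] <- "Male"; sex[sex == "F"] <- "Female"

  age_y <- age_in_years(demo$age, demo$age_cod)
  age_grp <- .age_group(age_y, age_breaks)

  # indications of the PS drug, once per case and term
  ps <- data$drug[toupper(trimws(data$drug$role_cod)) == "PS", , drop = FALSE]
  ind <- merge(data$indi, ps[, c("primaryid", "drug_seq")],
               by.x = c("primaryid", "indi_drug_seq"),
               by.y = c("primaryid", "drug_seq"))
  ind$term <- tolower(trimws(ind$indi_pt))
  ind <- unique(ind[, c("primaryid", "term")])
  ind_tab <- sort(table(ind$term), decreasing = TRUE)
  ind_tab <- utils::head(ind_tab, top_indications)

  outc <- unique(data$outc[, c("primaryid", "outc_cod")])
  outc_lab <- c(DE = "Death", LT = "Life-Threatening", HO = "Hospitalization",
                DS = "Disability", CA = "Congenital Anomaly",
                RI = "Required Intervention", OT = "Other")
  outc$level <- unname(outc_lab[toupper(trimws(outc$outc_cod))])
  outc <- outc[!is.na(outc$level), , drop = FALSE]

  country <- trimws(demo$reporter_country)
  country[is.na(country) | !nzchar(country)] <- "Unknown"
  ctab <- sort(table(country[country != "Unknown"]), decreasing = TRUE)
  ctab <- utils::head(ctab, top_countries)

  rep_code <- toupper(trimws(demo$occp_cod))
  reporter <- unname(.reporter_labels[rep_code])
  reporter[is.na(reporter)] <- "Unknown"

  year <- ifelse(parse_partial_date(demo$fda_dt)$precision %in%
                   c("day", "month", "year"),
                 substr(demo$fda_dt, 1, 4), "Unknown")

  mk <- function(dim, tab) {
    data.frame(dimension = rep(dim, length(tab)),
               level = as.character(names(tab)),
               count = as.integer(tab),
               percent = round_half_up(as.integer(tab) / total * 100, 1),
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    .count_level("sex", sex, total),
    .count_level("age_group", age_grp, total),
    mk("indication", ind_tab),
    .count_level("outcome", outc$level, total),
    mk("country", ctab),
    .count_level("reporter", reporter, total),
    .count_level("year", year, total)
  )
  rownames(out) <- NULL
  structure(out, total = total, class = c("baseline_summary", "data.frame"))
}

#' @export
print.baseline_summary <- function(x, ...) {
  cat("Baseline characteristics (", attr(x, "total"), " cases)\n\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Look up one baseline cell
#'
#' Convenience accessor for a single (dimension, level) row of a
#' [summarize_baseline()] result.
#'
#' @param summary a `baseline_summary`.
#' @param dimension,level the stratum to extract.
#' @return one-row data.frame (zero rows if absent).
#' @export
baseline_cell <- function(summary, dimension, level) {
  summary[summary$dimension == dimension & summary$level == level, ,
          drop = FALSE]
}
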