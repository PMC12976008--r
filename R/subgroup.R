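# Subgroup (stratified) signal detection and the concomitant-drug
# sensitivity analysis.

#' Age-bin presets
#'
#' Two named presets are shipped: `"baseline"` (bins `<18`, `18-65`,
#' `65-85`, `>85`) used by the baseline table, and `"subgroup"` (bins
#' `<18`, `18-65`, `>65`) used by the age-stratified analysis.
#'
#' @param preset `"baseline"` or `"subgroup"`.
#' @return numeric vector of bin edges for [summarize_baseline()] /
#'   stratum assignment.
#' @export
age_bin_preset <- function(preset = c("baseline", "subgroup")) {
  switch(match.arg(preset), baseline = c(18, 65, 85), subgroup = c(18, 65))
}

#' Assign each report to a stratum level
#'
#' @param demo DEMO data.frame.
#' @param dimension one of `"sex"`, `"age_group"`, `"reporter"`.
#' @param age_breaks bin edges when `dimension = "age_group"`
#'   (default the `"subgroup"` preset).
#' @return character vector of stratum levels, one per DEMO row.
#' @export
assign_stratum <- function(demo, dimension = c("sex", "age_group", "reporter"),
                           age_breaks = age_bin_preset("subgroup")) {
  dimension <- match.arg(dimension)
  if (dimension == "sex") {
    s <- toupper(trimws(demo$sex))
    s[is.na(s) | !(s %in% c("M", "F"))] <- "Unknown"
    s
  } else if (dimension == "age_group") {
    .age_group(age_in_years(demo$age, demo$age_cod), age_breaks)
  } else {
    r <- unname(.reporter_labels[toupper(trimws(demo$occp_cod))])
    r[is.na(r)] <- "Unknown"
    r
  }
}

#' Stratified signal detection
#'
#' Restricts both the cohort and the comparator to one demographic stratum,
#' rebuilds the 2x2 tables (N is recomputed within the stratum), and runs
#' all four disproportionality statistics.
#'
#' @param cohort,comparator [faers_data()] objects.
#' @param dimension,level the stratum (see [assign_stratum()]).
#' @param age_breaks bin edges for age strata.
#' @param term_level `"pt"` or `"soc"`.
#' @param map PT to SOC map when `term_level = "soc"`.
#' @param prior an `mgps_prior` for the EBGM component; when `NULL` one is
#'   fitted on the stratum's database-wide cells.
#' @param thresholds see [signal_thresholds()].
#' @return a `signal_table` for the stratum.
#' @export
subgroup_signals <- function(cohort, comparator, dimension, level,
                             age_breaks = age_bin_preset("subgroup"),
                             term_level = "pt", map = NULL, prior = NULL,
                             thresholds = signal_thresholds()) {
  in_co <- assign_stratum(cohort$demo, dimension, age_breaks) == level
  in_cm <- assign_stratum(comparator$demo, dimension, age_breaks) == level
  if (!any(in_co) || !any(in_cm)) {
    stop("empty stratum: ", dimension, " = ", level)
  }
  co <- subset_faers(cohort, cohort$demo$primaryid[in_co])
  cm <- subset_faers(comparator, comparator$demo$primaryid[in_cm])
  ct <- count_pairs(co, cm, level = term_level, map = map)
  if (is.null(prior)) {
    merged <- faers_data(demo = rbind(co$demo, cm$demo),
                         drug = rbind(co$drug, cm$drug),
                         reac = rbind(co$reac, cm$reac))
    cells <- mgps_cells(merged, level = term_level, map = map)
    prior <- fit_mgps_prior(cells$a, cells$E)
  }
  detect_signals(ct, prior, thresholds)
}

#' Exclude reports involving listed drugs (sensitivity analysis)
#'
#' Removes every report that lists any of the given drug names in a drug
#' record of any role (suspect or concomitant), then reports the attrition:
#' retained case count and retained unique (case, PT) pair count.
#'
#' @param data a [faers_data()] object.
#' @param exclude_names character vector of drug names (normalized as in
#'   [drug_dictionary()]).
#' @return list with `data` (the filtered [faers_data()]) and `attrition`
#'   (data.frame with cases/pairs before and after).
#' @export
sensitivity_exclude <- function(data, exclude_names) {
  stopifnot(inherits(data, "faers_data"))
  exclude_names <- unique(normalize_name(exclude_names))
  exclude_names <- exclude_names[nzchar(exclude_names)]
  if (length(exclude_names) == 0L) stop("exclusion list is empty")

  hit <- normalize_name(data$drug$drugname) %in% exclude_names
  drop_ids <- unique(data$drug$primaryid[hit])
  keep_ids <- setdiff(unique(data$demo$primaryid), drop_ids)
  out <- subset_faers(data, keep_ids)

  pair_count <- function(d) {
    nrow(unique(data.frame(d$reac$primaryid, tolower(trimws(d$reac$pt)))))
  }
  attrition <- data.frame(
    stage = c("before", "after"),
    cases = c(nrow(data$demo), nrow(out$demo)),
    case_pt_pairs = c(pair_count(data), pair_count(out)))
  list(data = out, attrition = attrition)
}
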