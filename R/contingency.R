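# PT -> SOC mapping and 2x2 contingency construction.
#
# The counting unit throughout is the unique (report, event-term) pair: a
# report mentioning the same PT twice contributes once, and at SOC level a
# report contributes once per distinct SOC.  This makes the database-wide
# pair total N well-defined and the margins additive, which is what the
# four disproportionality statistics assume.

#' Read a PT to SOC map
#'
#' Two-column tab-separated file (`pt<TAB>soc`, no header, or a header line
#' `pt\tsoc`) standing in for the MedDRA primary-SOC assignment: each
#' preferred term maps to exactly one system organ class.
#'
#' @param path path to the TSV file.
#' @return named character vector: `names` are normalized PTs, values SOCs.
#' @export
read_soc_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2) stop("SOC map must have two tab-separated columns")
  if (identical(tolower(trimws(df[1, 1])), "pt")) df <- df[-1, , drop = FALSE]
  soc_map(df[[1]], df[[2]])
}

#' Construct a PT to SOC map
#'
#' @param pt character vector of preferred terms.
#' @param soc character vector of system organ classes, same length.
#' @return named character vector keyed by normalized PT.
#' @export
soc_map <- function(pt, soc) {
  pt <- tolower(trimws(as.character(pt)))
  soc <- trimws(as.character(soc))
  if (anyDuplicated(pt)) stop("each PT must map to a single primary SOC")
  stats::setNames(soc, pt)
}

.report_term_pairs <- function(data, level, map) {
  reac <- data$reac
  term <- tolower(trimws(reac$pt))
  if (level == "soc") {
    mapped <- unname(map[term])
    if (anyNA(mapped)) {
      missing_pts <- sort(unique(term[is.na(mapped)]))
      stop("PT(s) missing from the SOC map: ",
           paste(missing_pts, collapse = ", "))
    }
    term <- mapped
  }
  unique(data.frame(primaryid = reac$primaryid, term = term,
                    stringsAsFactors = FALSE))
}

#' Build 2x2 contingency tables for every event term
#'
#' For each event term (PT, or SOC via `map`) the cells are: `a` cohort
#' pairs with the term, `b` cohort pairs with other terms, `c` comparator
#' pairs with the term, `d` comparator pairs with other terms.  Every row
#' shares the same `n = a + b + c + d`, the database-wide pair total.
#'
#' @param cohort,comparator deduplicated [faers_data()] objects (disjoint
#'   report sets; the comparator is the rest of the database).
#' @param level `"pt"` or `"soc"`.
#' @param map named PT to SOC vector, required when `level = "soc"`.
#' @return data.frame of class `contingency_set` with columns `term`,
#'   `level`, `a`, `b`, `c`, `d`, `n`, sorted by `a` descending.
#' @export
count_pairs <- function(cohort, comparator, level = c("pt", "soc"),
                        map = NULL) {
  level <- match.arg(level)
  if (level == "soc" && is.null(map)) stop("level = 'soc' requires a PT->SOC map")
  co <- .report_term_pairs(cohort, level, map)
  cm <- .report_term_pairs(comparator, level, map)

  n_co <- nrow(co)
  n_cm <- nrow(cm)
  n_tot <- n_co + n_cm

  terms <- sort(unique(c(co$term, cm$term)))
  a <- as.integer(table(factor(co$term, levels = terms)))
  cc <- as.integer(table(factor(cm$term, levels = terms)))
  out <- data.frame(term = terms, level = level,
                    a = a, b = n_co - a, c = cc, d = n_cm - cc,
                    n = n_tot, stringsAsFactors = FALSE)
  out <- out[order(-out$a, out$term), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("contingency_set", "data.frame"))
}

#' Database-wide (drug, event) cells for empirical-Bayes prior fitting
#'
#' The gamma-Poisson shrinker's prior is fitted over the whole database:
#' one cell per (primary-suspect drug, event term) combination, with
#' observed pair count `a` and expected count `E = (row total)(column
#' total)/N` under independence.
#'
#' @param data deduplicated [faers_data()] object.
#' @param level `"pt"` or `"soc"`.
#' @param map PT to SOC map when `level = "soc"`.
#' @return data.frame with columns `drug`, `term`, `a`, `E`.
#' @export
mgps_cells <- function(data, level = c("pt", "soc"), map = NULL) {
  level <- match.arg(level)
  pairs <- .report_term_pairs(data, level, map)
  drug <- data$drug
  ps <- drug[toupper(trimws(drug$role_cod)) == "PS", c("primaryid", "drugname")]
  ps$drugname <- normalize_name(ps$drugname)
  ps <- unique(ps)
  m <- merge(pairs, ps, by = "primaryid")
  if (nrow(m) == 0L) stop("no PS drug / event pairs in database")
  tab <- table(m$drugname, m$term)
  N <- sum(tab)
  Emat <- outer(rowSums(tab), colSums(tab)) / N
  out <- data.frame(drug = rep(rownames(tab), times = ncol(tab)),
                    term = rep(colnames(tab), each = nrow(tab)),
                    a = as.integer(tab),
                    E = as.numeric(Emat),
                    stringsAsFactors = FALSE)
  out[out$E > 0, , drop = FALSE]
}
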