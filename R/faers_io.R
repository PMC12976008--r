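#' @keywords internal
"_PACKAGE"

# Canonical column layout of the FAERS-style quarterly ASCII tables.
# Only columns used downstream are modelled; unknown columns are ignored
# on read.  `required` columns must be present in the header.
.faers_schema <- list(
  demo = list(
    columns  = c("primaryid", "caseid", "fda_dt", "event_dt", "age",
                 "age_cod", "sex", "reporter_country", "occp_cod"),
    required = c("primaryid", "caseid", "fda_dt")
  ),
  drug = list(
    columns  = c("primaryid", "drug_seq", "role_cod", "drugname"),
    required = c("primaryid", "drug_seq", "role_cod", "drugname")
  ),
  reac = list(
    columns  = c("primaryid", "pt"),
    required = c("primaryid", "pt")
  ),
  ther = list(
    columns  = c("primaryid", "dsg_drug_seq", "start_dt", "end_dt"),
    required = c("primaryid", "dsg_drug_seq", "start_dt")
  ),
  indi = list(
    columns  = c("primaryid", "indi_drug_seq", "indi_pt"),
    required = c("primaryid", "indi_drug_seq", "indi_pt")
  ),
  outc = list(
    columns  = c("primaryid", "outc_cod"),
    required = c("primaryid", "outc_cod")
  )
)

#' Table kinds of the FAERS ASCII dialect
#'
#' @return Character vector of the six supported table kinds.
#' @export
faers_table_kinds <- function() names(.faers_schema)

#' Parse FAERS partial dates
#'
#' FAERS date fields are digit strings of varying completeness: 8 digits
#' (YYYYMMDD, day precision), 6 (YYYYMM, month precision) or 4 (YYYY, year
#' precision).  Anything else, including calendar-impossible dates, is
#' classified invalid.  Partial dates are anchored at the first day of the
#' period so they remain comparable, but their precision is reported so
#' downstream analyses can restrict to day-precision values.
#'
#' @param raw character vector of raw date strings.
#' @return data.frame with columns `date` (class `Date`, `NA` when invalid)
#'   and `precision` (one of `"day"`, `"month"`, `"year"`, `"invalid"`).
#' @examples
#' parse_partial_date(c("20240115", "202401", "2024", "2024023"))
#' @export
parse_partial_date <- function(raw) {
  raw <- as.character(raw)
  n <- length(raw)
  date <- rep(as.Date(NA), n)
  precision <- rep("invalid", n)
  digits <- !is.na(raw) & grepl("^[0-9]+$", raw)

  i8 <- digits & nchar(raw) == 8L
  if (any(i8)) {
    d <- as.Date(raw[i8], format = "%Y%m%d")
    date[i8] <- d
    precision[i8][!is.na(d)] <- "day"
  }
  i6 <- digits & nchar(raw) == 6L
  if (any(i6)) {
    d <- as.Date(paste0(raw[i6], "01"), format = "%Y%m%d")
    date[i6] <- d
    precision[i6][!is.na(d)] <- "month"
  }
  i4 <- digits & nchar(raw) == 4L
  if (any(i4)) {
    d <- as.Date(paste0(raw[i4], "0101"), format = "%Y%m%d")
    date[i4] <- d
    precision[i4][!is.na(d)] <- "year"
  }
  date[precision == "invalid"] <- NA
  data.frame(date = date, precision = precision, stringsAsFactors = FALSE)
}

#' Convert reported age to years
#'
#' Unit codes follow the FAERS AGE_COD vocabulary: `YR` years, `MON` months,
#' `WK` weeks, `DY` days, `HR` hours, `DEC` decades.  Unknown codes or
#' missing ages yield `NA`.
#'
#' @param age numeric vector of reported age values.
#' @param age_cod character vector of unit codes (recycled if length 1).
#' @return numeric vector of ages in years.
#' @export
age_in_years <- function(age, age_cod) {
  age <- suppressWarnings(as.numeric(age))
  age_cod <- rep_len(toupper(trimws(as.character(age_cod))), length(age))
  factor_map <- c(YR = 1, MON = 1 / 12, WK = 1 / 52.14, DY = 1 / 365.25,
                  HR = 1 / 8766, DEC = 10)
  f <- unname(factor_map[age_cod])
  out <- age * f
  out[is.na(age)] <- NA_real_
  out
}

.read_text_lines <- function(path) {
  # UTF-8 with latin-1 fallback: real FAERS extracts mix encodings.
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  bad <- !validUTF8(lines)
  if (any(bad)) lines[bad] <- iconv(lines[bad], from = "latin1", to = "UTF-8")
  lines
}

#' Read a FAERS-style $-delimited ASCII table
#'
#' Reads one quarterly ASCII table ($-delimited, header row, no quoting).
#' Header names are matched case-insensitively; unknown columns are ignored
#' and missing optional columns are filled with `NA`.  Every data line yields
#' exactly one row.  Date fields are kept as raw strings; rows of a DEMO
#' table whose `fda_dt` does not parse are flagged in the
#' `"invalid_fda_dt"` attribute (row indices).
#'
#' @param path path to the ASCII file.
#' @param kind one of [faers_table_kinds()].
#' @return data.frame with the canonical columns for `kind`.
#' @seealso [write_faers_table()]
#' @export
read_faers_table <- function(path, kind) {
  kind <- match.arg(tolower(kind), faers_table_kinds())
  if (!file.exists(path)) stop("cannot read FAERS table: no such file: ", path)
  schema <- .faers_schema[[kind]]
  lines <- .read_text_lines(path)
  if (length(lines) == 0L) stop("empty file: ", path)

  header <- tolower(trimws(strsplit(lines[[1L]], "$", fixed = TRUE)[[1L]]))
  missing_req <- setdiff(schema$required, header)
  if (length(missing_req)) {
    stop("FAERS ", toupper(kind), " table ", path,
         " is missing required column(s): ", paste(missing_req, collapse = ", "))
  }

  body <- lines[-1L]
  parts <- strsplit(body, "$", fixed = TRUE)
  ncol_h <- length(header)
  mat <- matrix(NA_character_, nrow = length(body), ncol = ncol_h)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    length(p) <- ncol_h                 # short lines padded with NA
    mat[i, ] <- p
  }
  mat[!is.na(mat) & mat == ""] <- NA_character_

  out <- data.frame(matrix(NA_character_, nrow = length(body),
                           ncol = length(schema$columns)),
                    stringsAsFactors = FALSE)
  names(out) <- schema$columns
  for (col in intersect(schema$columns, header)) {
    out[[col]] <- mat[, match(col, header)]
  }

  if (kind == "demo") {
    prec <- parse_partial_date(out$fda_dt)$precision
    attr(out, "invalid_fda_dt") <- which(prec != "day")
  }
  out
}

#' Write a FAERS-style $-delimited ASCII table
#'
#' Inverse of [read_faers_table()]: writes the canonical columns for `kind`
#' with a `$`-delimited header row and no quoting.  Because the dialect has
#' no quoting, field values containing `$` are rejected.
#'
#' @param records data.frame with (at least) the canonical columns.
#' @param path output file path.
#' @param kind one of [faers_table_kinds()].
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(records, path, kind) {
  kind <- match.arg(tolower(kind), faers_table_kinds())
  cols <- .faers_schema[[kind]]$columns
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols)) {
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  m <- vapply(cols, function(cl) {
    v <- as.character(records[[cl]])
    v[is.na(v)] <- ""
    v
  }, character(nrow(records)))
  if (nrow(records) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, cols))
  if (nrow(records) > 0L && any(grepl("$", m, fixed = TRUE))) {
    stop("field values may not contain the '$' delimiter")
  }
  lines <- c(paste(cols, collapse = "$"),
             if (nrow(records) > 0L) apply(m, 1L, paste, collapse = "$"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Bundle the six FAERS tables into one database object
#'
#' @param demo,drug,reac,ther,indi,outc data.frames as returned by
#'   [read_faers_table()]; missing tables default to empty.
#' @return object of class `faers_data`: a named list of the six tables.
#' @export
faers_data <- function(demo, drug = NULL, reac = NULL, ther = NULL,
                       indi = NULL, outc = NULL) {
  empty <- function(kind) {
    cols <- .faers_schema[[kind]]$columns
    df <- data.frame(matrix(character(0), nrow = 0, ncol = length(cols)),
                     stringsAsFactors = FALSE)
    names(df) <- cols
    df
  }
  x <- list(demo = demo,
            drug = if (is.null(drug)) empty("drug") else drug,
            reac = if (is.null(reac)) empty("reac") else reac,
            ther = if (is.null(ther)) empty("ther") else ther,
            indi = if (is.null(indi)) empty("indi") else indi,
            outc = if (is.null(outc)) empty("outc") else outc)
  structure(x, class = "faers_data")
}

#' @export
print.faers_data <- function(x, ...) {
  cat("<faers_data>\n")
  for (k in names(x)) {
    cat(sprintf("  %s: %d rows\n", toupper(k), nrow(x[[k]])))
  }
  cat(sprintf("  reports: %d\n", length(unique(x$demo$primaryid))))
  invisible(x)
}

#' Read a full FAERS-style database from a directory
#'
#' Expects files `<kind>.txt` (e.g. `demo.txt`) for each of the six table
#' kinds; absent files yield empty tables (DEMO is required).
#'
#' @param dir directory containing the ASCII tables.
#' @return a [faers_data()] object.
#' @export
read_faers_data <- function(dir) {
  paths <- file.path(dir, paste0(faers_table_kinds(), ".txt"))
  names(paths) <- faers_table_kinds()
  if (!file.exists(paths[["demo"]])) {
    stop("no DEMO table found at ", paths[["demo"]])
  }
  tabs <- lapply(faers_table_kinds(), function(k) {
    if (file.exists(paths[[k]])) read_faers_table(paths[[k]], k) else NULL
  })
  names(tabs) <- faers_table_kinds()
  faers_data(demo = tabs$demo, drug = tabs$drug, reac = tabs$reac,
             ther = tabs$ther, indi = tabs$indi, outc = tabs$outc)
}

#' Write a full FAERS-style database to a directory
#'
#' @param data a [faers_data()] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_faers_data <- function(data, dir) {
  stopifnot(inherits(data, "faers_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in faers_table_kinds()) {
    write_faers_table(data[[k]], file.path(dir, paste0(k, ".txt")), k)
  }
  invisible(dir)
}

#' Restrict a database to a set of report identifiers
#'
#' @param data a [faers_data()] object.
#' @param primaryids character vector of report identifiers to keep.
#' @return a [faers_data()] object containing only those reports.
#' @export
subset_faers <- function(data, primaryids) {
  stopifnot(inherits(data, "faers_data"))
  out <- lapply(data, function(tab) {
    tab[tab$primaryid %in% primaryids, , drop = FALSE]
  })
  structure(out, class = "faers_data")
}
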