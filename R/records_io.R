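#' Anthropometric measure columns
#'
#' Canonical column names for the five anthropometric measures carried by a
#' health-record table: standing height (cm), body weight (kg), body-mass
#' index (kg/m^2), waist circumference (cm) and hip circumference (cm).
#'
#' @return Character vector of the five measure column names.
#' @export
measure_columns <- function() {
  c("height_cm", "weight_kg", "bmi", "waist_cm", "hip_cm")
}

# Full record-table header, in interchange order.
record_columns <- function() {
  c("patient_id", "visit_date", "age", "gender", measure_columns(), "validated")
}

# Fixed token table for gender normalization; matching is case-insensitive
# after trimming. Unknown tokens are never guessed.
.gender_tokens <- c(
  m = "male", male = "male", "1" = "male",
  f = "female", female = "female", "2" = "female"
)

#' Normalize gender tokens
#'
#' Maps the accepted spellings (`m`, `male`, `1` and `f`, `female`, `2`,
#' case-insensitive, surrounding whitespace ignored) onto `"male"` /
#' `"female"`. Empty strings and `NA` stay missing; anything else becomes
#' `NA` with attribute `unknown` listing the offending positions.
#'
#' @param x Character vector of raw gender tokens.
#' @return Character vector of `"male"`, `"female"` or `NA`, with an
#'   `unknown` attribute holding indices of unrecognized non-missing tokens.
#' @export
normalize_gender <- function(x) {
  tok <- tolower(trimws(as.character(x)))
  tok[tok %in% c("", "na")] <- NA_character_
  out <- unname(.gender_tokens[tok])
  unknown <- which(!is.na(tok) & is.na(out))
  attr(out, "unknown") <- unknown
  out
}

#' Construct a health-record set
#'
#' Validates and normalizes a data frame of visit records into a
#' `health_records` object: one row per visit, the fixed interchange columns
#' (see [measure_columns()]), integer ages, normalized gender, numeric
#' measures and a logical `validated` flag. Missing values are explicit
#' `NA`s; an absent age is never encoded as 0.
#'
#' @param df Data frame with at least `patient_id`; other columns optional
#'   and filled with `NA` (`validated` defaults to `FALSE`).
#' @param source_label Free-text provenance label stored as an attribute.
#' @return A `health_records` data frame.
#' @export
health_records <- function(df, source_label = "unspecified") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in record_columns()) {
    if (!col %in% names(df)) {
      df[[col]] <- rep(if (col == "validated") FALSE else NA, nrow(df))
    }
  }
  df <- df[record_columns()]
  df$patient_id <- as.character(df$patient_id)
  df$visit_date <- as.character(df$visit_date)
  age <- suppressWarnings(as.numeric(df$age))
  if (any(!is.na(age) & (age < 0 | age != floor(age)))) {
    stop("age must be a non-negative integer or missing", call. = FALSE)
  }
  df$age <- as.integer(age)
  df$gender <- c(normalize_gender(df$gender))
  for (m in measure_columns()) {
    v <- suppressWarnings(as.numeric(df[[m]]))
    if (any(!is.na(v) & (v < 0 | !is.finite(v)))) {
      stop(sprintf("measure '%s' contains negative or non-finite values", m),
           call. = FALSE)
    }
    df[[m]] <- v
  }
  df$validated <- as.logical(df$validated)
  df$validated[is.na(df$validated)] <- FALSE
  rownames(df) <- NULL
  structure(df, source_label = source_label,
            class = c("health_records", "data.frame"))
}

#' Read a health-record table
#'
#' Reads a comma-separated, UTF-8, header-required record table into a
#' [health_records()] set. Empty cells and `NA` both map to missing. A row is
#' malformed if its age is not a non-negative integer, a measure is negative
#' or non-numeric, or its gender token is not in the fixed table; under
#' `on_error = "fail"` the first malformed row aborts with its row number,
#' under `"skip_and_log"` malformed rows are dropped, counted and reported
#' via the `skipped` attribute.
#'
#' @param path Path to a CSV file with header.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(age = "AGE_YRS")`.
#' @param on_error `"fail"` (default) or `"skip_and_log"`.
#' @return A `health_records` set; attribute `skipped` is a data frame of
#'   dropped row numbers and reasons (empty under `"fail"`).
#' @export
read_records <- function(path, schema = NULL,
                         on_error = c("fail", "skip_and_log")) {
  on_error <- match.arg(on_error)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file",
                               call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("", "NA"), fileEncoding = "UTF-8",
                         check.names = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(c("patient_id"), names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(raw)
  bad <- character(n)  # "" = well-formed
  if ("age" %in% names(raw)) {
    age <- suppressWarnings(as.numeric(raw$age))
    bad_age <- !is.na(raw$age) & (is.na(age) | age < 0 | age != floor(age))
    bad[bad_age & bad == ""] <- "invalid age"
  }
  if ("gender" %in% names(raw)) {
    g <- normalize_gender(raw$gender)
    bad[attr(g, "unknown")] <- "unknown gender token"
  }
  for (m in intersect(measure_columns(), names(raw))) {
    v <- suppressWarnings(as.numeric(raw[[m]]))
    bad_m <- !is.na(raw[[m]]) & (is.na(v) | v < 0 | !is.finite(v))
    bad[bad_m & bad == ""] <- paste("invalid", m)
  }
  if (any(bad != "")) {
    rows <- which(bad != "")
    if (on_error == "fail") {
      stop(sprintf("malformed row %d: %s", rows[1], bad[rows[1]]),
           call. = FALSE)
    }
    message(length(rows), " malformed row(s) skipped while reading ", path)
    skipped <- data.frame(row = rows, reason = bad[rows],
                          stringsAsFactors = FALSE)
    raw <- raw[bad == "", , drop = FALSE]
  } else {
    skipped <- data.frame(row = integer(), reason = character(),
                          stringsAsFactors = FALSE)
  }
  rs <- health_records(raw, source_label = path)
  attr(rs, "skipped") <- skipped
  rs
}

#' Write a health-record table
#'
#' Writes a record set as comma-separated UTF-8 with the canonical header.
#' Missing values become empty cells (never `"0"`), so
#' `read_records(write_records(rs))` reproduces `rs` field for field.
#'
#' @param rs A `health_records` set.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(rs, path) {
  df <- as.data.frame(rs)[record_columns()]
  utils::write.csv(df, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' @export
print.health_records <- function(x, ...) {
  lab <- attr(x, "source_label")
  cat(sprintf("<health_records> %d record(s) from '%s'\n",
              nrow(x), if (is.null(lab)) "unspecified" else lab))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}
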