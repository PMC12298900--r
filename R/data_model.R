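#' @title Report-level data model for fish mercury summaries
#' @description
#' The unit of the meta-database is a *report*: one study x genus x site
#' summary carrying the sample mean, standard deviation and sample size of
#' total mercury in muscle (ug/g wet weight) plus the ecological covariates
#' that influence fish Hg (feeding habit, ecosystem type, Amazonian water
#' type, sub-basin, fish size). A database is an ordered collection of
#' validated reports.
#' @name data_model
NULL

# Fixed vocabulary -----------------------------------------------------------

#' Genus to feeding-habit mapping
#'
#' The six target genera and their fixed feeding habits: `Cichla`, `Hoplias`
#' and `Plagioscion` are carnivores; `Leporinus`, `Semaprochilodus` and
#' `Schizodon` are non-carnivores. The mapping is total and deterministic;
#' any report contradicting it is invalid.
#'
#' @return Named character vector mapping genus to habit.
#' @export
#' @examples
#' genus_habit_map()[["Hoplias"]]
genus_habit_map <- function() {
  c(Cichla = "carnivore", Hoplias = "carnivore", Plagioscion = "carnivore",
    Leporinus = "non_carnivore", Semaprochilodus = "non_carnivore",
    Schizodon = "non_carnivore")
}

.ecosystem_levels <- c("river", "lake", "hydroelectric", "market")
.water_levels <- c("black", "white", "clear", "unknown")

# Fixed CSV column order (interchange schema).
.report_columns <- c(
  "report_id", "study_id", "first_author_year", "genus", "species",
  "feeding_habit", "n_samples", "length_mean_cm", "length_sd_cm",
  "weight_mean_g", "weight_sd_g", "hg_mean_ugg_ww", "hg_sd_ugg_ww",
  "ecosystem_type", "water_type", "sub_basin", "country", "state", "city",
  "sampling_year", "latitude", "longitude", "detection_method")

# internal (short) names <-> CSV names
.col_internal <- function(x) {
  x[x == "hg_mean_ugg_ww"] <- "hg_mean"
  x[x == "hg_sd_ugg_ww"] <- "hg_sd"
  x
}
.col_csv <- function(x) {
  x[x == "hg_mean"] <- "hg_mean_ugg_ww"
  x[x == "hg_sd"] <- "hg_sd_ugg_ww"
  x
}

.numeric_cols <- c("length_mean_cm", "length_sd_cm", "weight_mean_g",
                   "weight_sd_g", "hg_mean", "hg_sd", "latitude", "longitude")

# Validation -----------------------------------------------------------------

# Returns a character vector of problems for one report row (zero length if
# valid). Checks are row-local, so validation is order-independent.
.validate_report_row <- function(row) {
  problems <- character(0)
  bad <- function(msg) problems <<- c(problems, msg)

  if (is.na(row$report_id) || !nzchar(row$report_id)) bad("missing report_id")
  if (!row$genus %in% names(genus_habit_map())) {
    bad(sprintf("unknown genus '%s'", row$genus))
  } else if (!identical(row$feeding_habit,
                        unname(genus_habit_map()[row$genus]))) {
    bad(sprintf("feeding_habit '%s' contradicts fixed mapping for genus '%s'",
                row$feeding_habit, row$genus))
  }
  if (is.na(row$n_samples) || row$n_samples < 1 ||
      row$n_samples != as.integer(row$n_samples)) {
    bad("n_samples must be a positive integer")
  }
  if (is.na(row$hg_mean) || row$hg_mean <= 0) bad("hg_mean must be > 0")
  for (sd_col in c("hg_sd", "length_sd_cm", "weight_sd_g")) {
    v <- row[[sd_col]]
    if (!is.na(v) && v < 0) bad(sprintf("%s must be >= 0", sd_col))
  }
  for (pos_col in c("length_mean_cm", "weight_mean_g")) {
    v <- row[[pos_col]]
    if (!is.na(v) && v <= 0) bad(sprintf("%s must be > 0", pos_col))
  }
  if (!row$ecosystem_type %in% .ecosystem_levels) {
    bad(sprintf("unknown ecosystem_type '%s'", row$ecosystem_type))
  }
  if (!row$water_type %in% .water_levels) {
    bad(sprintf("unknown water_type '%s'", row$water_type))
  } else if (identical(row$water_type, "unknown") &&
             !identical(row$ecosystem_type, "market")) {
    bad("water_type 'unknown' is only permitted for market reports")
  }
  if (!is.na(row$sampling_year) && nzchar(row$sampling_year) &&
      !grepl("^[0-9]{4}([-–][0-9]{4})?$", row$sampling_year)) {
    bad("sampling_year must be YYYY or YYYY-YYYY")
  }
  if (!is.na(row$latitude) && abs(row$latitude) > 90) bad("latitude out of range")
  if (!is.na(row$longitude) && abs(row$longitude) > 180) bad("longitude out of range")
  problems
}

#' Build a validated report database from a data frame
#'
#' Validates each row against the report invariants (positive `hg_mean`,
#' integer `n_samples >= 1`, non-negative SDs, the fixed genus-to-habit
#' mapping, controlled ecosystem/water vocabularies, `water_type = "unknown"`
#' only for market fish) and uniqueness of `report_id`.
#'
#' @param df Data frame with the report columns (internal names `hg_mean`,
#'   `hg_sd` or CSV names `hg_mean_ugg_ww`, `hg_sd_ugg_ww`; missing optional
#'   columns are added as `NA`).
#' @param strict If `TRUE` (default) any invalid row is an error naming the
#'   offending `report_id`; if `FALSE` invalid rows are dropped and recorded
#'   in the `"rejected"` attribute with their reasons.
#' @param provenance Free-text provenance note stored as an attribute.
#' @return A `fish_reports` data frame (one row per accepted report).
#' @export
as_fish_reports <- function(df, strict = TRUE, provenance = "") {
  stopifnot(is.data.frame(df))
  names(df) <- .col_internal(names(df))
  mandatory <- c("report_id", "study_id", "genus", "feeding_habit",
                 "n_samples", "hg_mean", "ecosystem_type", "water_type")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  all_internal <- .col_internal(.report_columns)
  for (col in setdiff(all_internal, names(df))) df[[col]] <- NA
  df <- df[all_internal]

  chr_cols <- setdiff(all_internal, c(.numeric_cols, "n_samples"))
  for (col in chr_cols) df[[col]] <- as.character(df[[col]])
  for (col in .numeric_cols) df[[col]] <- as.numeric(df[[col]])
  df$n_samples <- suppressWarnings(as.numeric(df$n_samples))

  problems <- lapply(seq_len(nrow(df)), function(i) .validate_report_row(df[i, ]))
  n_problems <- lengths(problems)
  if (any(n_problems > 0)) {
    msgs <- vapply(which(n_problems > 0), function(i) {
      sprintf("report '%s': %s", df$report_id[i],
              paste(problems[[i]], collapse = "; "))
    }, character(1))
    if (strict) {
      stop("row validation error:\n  ", paste(msgs, collapse = "\n  "),
           call. = FALSE)
    }
    rejected <- data.frame(report_id = df$report_id[n_problems > 0],
                           reason = msgs, stringsAsFactors = FALSE)
    message(sprintf("dropped %d invalid report(s)", nrow(rejected)))
    df <- df[n_problems == 0, , drop = FALSE]
  } else {
    rejected <- data.frame(report_id = character(0), reason = character(0))
  }
  if (anyDuplicated(df$report_id)) {
    stop("row validation error: duplicated report_id: ",
         paste(unique(df$report_id[duplicated(df$report_id)]), collapse = ", "),
         call. = FALSE)
  }
  df$n_samples <- as.integer(df$n_samples)
  rownames(df) <- NULL
  structure(df, class = c("fish_reports", "data.frame"),
            provenance = provenance, rejected = rejected)
}

#' Read a report database from CSV
#'
#' Reads the comma-separated interchange format (UTF-8, `.` decimal separator,
#' one header row, fixed column set) and validates every row.
#'
#' @param path Path to a CSV file.
#' @inheritParams as_fish_reports
#' @return A `fish_reports` data frame.
#' @seealso [write_reports()] for the inverse; the two are exact round-trips.
#' @export
read_reports <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(.report_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in names(raw)) raw[[col]][!nzchar(trimws(raw[[col]]))] <- NA
  as_fish_reports(raw, strict = strict, provenance = path)
}

#' Write a report database to CSV
#'
#' Numeric fields are written with 15 significant digits so that
#' `read_reports(write_reports(db))` reproduces `db` field-for-field; absent
#' optional fields become empty cells and round-trip back to `NA`.
#'
#' @param db A `fish_reports` database.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reports <- function(db, path) {
  stopifnot(inherits(db, "fish_reports"))
  out <- as.data.frame(db)
  names(out) <- .col_csv(names(out))
  out <- out[.report_columns]
  num_csv <- .col_csv(c(.numeric_cols, "n_samples"))
  for (col in num_csv) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v), "", formatC(v, digits = 15, format = "g"))
  }
  for (col in setdiff(.report_columns, num_csv)) {
    out[[col]][is.na(out[[col]])] <- ""
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert a dry-weight mercury concentration to wet weight
#'
#' Literature values reported on a dry-weight basis are harmonized to the wet
#' weight basis used throughout the database. No default moisture content is
#' assumed: the conversion factor must be supplied explicitly (fish muscle
#' moisture is typically around 0.75-0.80 but varies by species and study).
#'
#' @param hg_dry Mercury concentration in ug/g dry weight (> 0).
#' @param moisture_fraction Tissue moisture fraction, strictly between 0 and 1.
#' @return Concentration in ug/g wet weight, `hg_dry * (1 - moisture_fraction)`.
#' @export
#' @examples
#' convert_dry_to_wet(1.0, 0.8)   # 0.2 ug/g w.w.
convert_dry_to_wet <- function(hg_dry, moisture_fraction) {
  if (any(!is.finite(moisture_fraction)) ||
      any(moisture_fraction <= 0) || any(moisture_fraction >= 1)) {
    stop("moisture_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  if (any(!is.finite(hg_dry)) || any(hg_dry <= 0)) {
    stop("hg_dry must be > 0", call. = FALSE)
  }
  hg_dry * (1 - moisture_fraction)
}

#' @export
print.fish_reports <- function(x, ...) {
  cat(sprintf("<fish_reports> %d reports, %d studies\n",
              nrow(x), length(unique(x$study_id))))
  if (nrow(x) > 0) {
    tab <- table(x$feeding_habit)
    cat("  habits: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n", sep = "")
  }
  prov <- attr(x, "provenance")
  if (!is.null(prov) && nzchar(prov)) cat("  provenance: ", prov, "\n", sep = "")
  invisible(x)
}
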