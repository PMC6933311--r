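#' Required columns of a study table, in canonical order
#' @keywords internal
.study_cols <- c("seal_id", "season", "at_sea_fmr", "mass_change_adj",
                 "water_influx", "trip_duration", "pct_dive",
                 "mean_max_depth", "fa_cluster", "tag_fsa")
.study_numeric <- setdiff(.study_cols, c("seal_id", "season", "fa_cluster"))

#' Load a trip-level study table
#'
#' Reads a delimited table of per-trip at-sea field metabolic rate (FMR),
#' foraging-success and behavioural variables. The built-in name
#' `"table1"` loads the packaged study table: 48 foraging-trip measurements
#' from 33 lactating northern fur seals (seals measured in both summer and
#' fall contribute two rows, summer first). One trip (seal 360, fall) has no
#' usable FMR of its own; it is retained with `at_sea_fmr` missing and
#' flagged unusable.
#'
#' @param path path to a CSV file with a header naming the study columns,
#'   or the built-in fixture name `"table1"`.
#' @return a `data.frame` of class `study_table` with columns `seal_id`,
#'   `season` (factor, `summer` reference), `at_sea_fmr` (W kg-1),
#'   `mass_change_adj` (kg), `water_influx` (ml kg-1 day-1),
#'   `trip_duration` (days), `pct_dive` (%), `mean_max_depth` (m),
#'   `fa_cluster` (factor 1/2/3), `tag_fsa` (cm2) and a logical `usable`
#'   flag (`FALSE` where `at_sea_fmr` is missing). Attributes
#'   `n_measurements` and `n_seals` give the row and distinct-seal counts.
#' @examples
#' tab <- load_study_table("table1")
#' attr(tab, "n_measurements")  # 48
#' attr(tab, "n_seals")         # 33
#' @export
load_study_table <- function(path = "table1") {
  if (identical(path, "table1")) {
    path <- system.file("extdata", "table1_trips.csv", package = "sealflux",
                        mustWork = TRUE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(.study_cols, names(raw))
  if (length(missing_cols)) {
    stop("study table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[, .study_cols]
  for (cl in .study_numeric) {
    v <- trimws(raw[[cl]])
    v[v == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad)) {
      stop(sprintf("study table parse error: non-numeric value '%s' in column '%s', row %d",
                   v[bad[1]], cl, bad[1]), call. = FALSE)
    }
    raw[[cl]] <- num
  }
  raw$season <- factor(tolower(trimws(raw$season)),
                       levels = c("summer", "fall"))
  if (nrow(raw) && anyNA(raw$season)) {
    stop("study table parse error: season must be 'summer' or 'fall'",
         call. = FALSE)
  }
  raw$fa_cluster <- factor(trimws(raw$fa_cluster), levels = c("1", "2", "3"))
  raw$usable <- !is.na(raw$at_sea_fmr)
  validate_study_table(raw)
  structure(raw,
            n_measurements = nrow(raw),
            n_seals = length(unique(raw$seal_id)),
            class = c("study_table", "data.frame"))
}

#' @keywords internal
validate_study_table <- function(tab) {
  if (!nrow(tab)) return(invisible(tab))
  if (any(tab$trip_duration <= 0, na.rm = TRUE))
    stop("invalid study table: trip_duration must be > 0", call. = FALSE)
  if (any(tab$pct_dive < 0 | tab$pct_dive > 100, na.rm = TRUE))
    stop("invalid study table: pct_dive must lie in [0, 100]", call. = FALSE)
  if (any(tab$mean_max_depth <= 3, na.rm = TRUE))
    stop("invalid study table: mean_max_depth must exceed the 3 m dive threshold",
         call. = FALSE)
  invisible(tab)
}

#' Write a study table back to CSV
#'
#' Inverse of [load_study_table()]: a written table reloads with every field
#' unchanged.
#'
#' @param table a `study_table`
#' @param path output CSV path
#' @export
write_study_table <- function(table, path) {
  out <- as.data.frame(table)[, .study_cols]
  out$season <- as.character(out$season)
  out$fa_cluster <- as.character(out$fa_cluster)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Summarize a numeric study-table column
#'
#' @param table a `study_table`
#' @param column name of a numeric column
#' @return a one-row `data.frame` with `mean`, `sd` (n-1 denominator,
#'   `NA` when fewer than two non-missing values), `min`, `max` and `n`
#'   (non-missing count)
#' @examples
#' summarize_column(load_study_table("table1"), "pct_dive")  # 13.2 +/- 3.8
#' @export
summarize_column <- function(table, column) {
  if (!column %in% names(table))
    stop("unknown column: ", column, call. = FALSE)
  x <- table[[column]]
  if (!is.numeric(x))
    stop("column '", column, "' is not numeric", call. = FALSE)
  x <- x[!is.na(x)]
  data.frame(column = column,
             mean = if (length(x)) mean(x) else NA_real_,
             sd = if (length(x) > 1) stats::sd(x) else NA_real_,
             min = if (length(x)) min(x) else NA_real_,
             max = if (length(x)) max(x) else NA_real_,
             n = length(x))
}
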