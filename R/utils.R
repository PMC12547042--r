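# Shared internal helpers: calendar arithmetic, scaling, table validation.
# Administrative extracts carry day-resolution dates; month arithmetic is
# calendar-month based with day-of-month clamping (e.g. Aug 31 + 6 months ->
# Feb 28/29), and durations in "months" use the mean Gregorian month length.

DAYS_PER_MONTH <- 30.4375

days_in_month <- function(year, month) {
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  ifelse(month == 2L & leap, 29L, base)
}

#' Shift calendar dates by whole months
#'
#' Adds `n` calendar months to each date, clamping the day of month to the
#' last day of the target month when needed (e.g. 2015-08-31 plus 6 months is
#' 2016-02-29).  This is the convention used for the 6-month observation
#' windows throughout the package.
#'
#' @param dates a `Date` vector.
#' @param n integer number of months (scalar).
#' @return a `Date` vector.
#' @export
add_months <- function(dates, n) {
  stopifnot(inherits(dates, "Date"), length(n) == 1L)
  lt <- as.POSIXlt(dates)
  m0 <- lt$year * 12L + lt$mon + as.integer(n)
  y <- m0 %/% 12L + 1900L
  m <- m0 %% 12L + 1L
  d <- pmin(lt$mday, days_in_month(y, m))
  as.Date(sprintf("%04d-%02d-%02d", y, m, d))
}

months_between <- function(from, to) {
  as.numeric(difftime(to, from, units = "days")) / DAYS_PER_MONTH
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_date_strict <- function(x, what) {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop(sprintf("unparseable date in %s at row %d: '%s'",
                 what, bad[1L], as.character(x[bad[1L]])), call. = FALSE)
  }
  out
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s table is missing column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# --- table validators (shared by case-finding and feature building) ---------

validate_prescriptions <- function(df) {
  require_columns(df, c("patient_id", "date", "drug_name"), "prescriptions")
  df$date <- as_date_strict(df$date, "prescriptions$date")
  check_patient_id(df$patient_id, "prescriptions")
  df
}

validate_admissions <- function(df) {
  require_columns(df, c("patient_id", "admit_date", "discharge_date",
                        "icd9_codes", "emergency_flag"), "admissions")
  df$admit_date <- as_date_strict(df$admit_date, "admissions$admit_date")
  df$discharge_date <- as_date_strict(df$discharge_date,
                                      "admissions$discharge_date")
  check_patient_id(df$patient_id, "admissions")
  bad <- which(df$discharge_date < df$admit_date)
  if (length(bad)) {
    stop(sprintf("admissions row %d: discharge_date precedes admit_date",
                 bad[1L]), call. = FALSE)
  }
  df
}

validate_outpatients <- function(df) {
  require_columns(df, c("patient_id", "date", "service_category"),
                  "outpatients")
  df$date <- as_date_strict(df$date, "outpatients$date")
  check_patient_id(df$patient_id, "outpatients")
  df
}

validate_demographics <- function(df) {
  require_columns(df, c("patient_id", "sex", "birth_year", "resident_flag"),
                  "demographics")
  check_patient_id(df$patient_id, "demographics")
  df
}

check_patient_id <- function(id, what) {
  bad <- which(is.na(id) | !nzchar(as.character(id)))
  if (length(bad)) {
    stop(sprintf("%s row %d: empty patient_id", what, bad[1L]), call. = FALSE)
  }
  invisible(TRUE)
}

split_icd9 <- function(codes) {
  strsplit(trimws(as.character(codes)), "\\s*;\\s*")
}

# --- feature standardization ------------------------------------------------

fit_scaler <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2L, scaler$center, "-"), 2L, scaler$scale, "/")
}

# Checks that a prediction-time feature matrix carries exactly the columns
# seen at training time; errors list both directions of the mismatch.
check_schema <- function(cols, expected) {
  missing <- setdiff(expected, cols)
  extra <- setdiff(cols, expected)
  if (length(missing) || length(extra)) {
    stop(sprintf(
      "feature schema mismatch; missing: [%s]; unexpected: [%s]",
      paste(missing, collapse = ", "), paste(extra, collapse = ", ")),
      call. = FALSE)
  }
  invisible(TRUE)
}

# Truncated-normal draws by inverse CDF so the draw count is fixed.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  qnorm(pl + runif(n) * (pu - pl), mean, sd)
}

truncnorm_mean <- function(mu, sd, lower, upper) {
  a <- (lower - mu) / sd
  b <- (upper - mu) / sd
  mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# Parent mean such that the truncated-normal mean equals `target`.
solve_parent_mean <- function(target, sd, lower, upper) {
  uniroot(function(mu) truncnorm_mean(mu, sd, lower, upper) - target,
          interval = c(target - 3 * sd, target + 3 * sd))$root
}

trapezoid <- function(x, y) {
  if (length(x) < 2L) return(y[1L])
  sum(diff(x) * (head(y, -1L) + y[-1L]) / 2)
}

#' Write a metrics list as pretty-printed JSON
#'
#' Serializes an evaluation report (any nested list of numbers/strings) to a
#' JSON file with unboxed scalars, so repeated runs with identical inputs
#' produce byte-identical files.
#'
#' @param x a list of metrics.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
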