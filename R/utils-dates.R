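#' Calendar arithmetic helpers
#'
#' Whole-year date arithmetic used throughout the eligibility and matching
#' stages.  `add_years()` moves a date forward by a whole number of years;
#' a Feb-29 anniversary falling in a non-leap year rolls forward to Mar-1,
#' so "the date a patient attains age x" is always the first day on which
#' the patient *is* x years old.  `age_on()` returns age in completed years
#' on a given day.
#'
#' @param date a `Date` vector.
#' @param n number of years to add (scalar or vector, may be negative).
#' @return `add_years()`: a `Date` vector; `age_on()`: an integer vector.
#' @examples
#' add_years(as.Date("2000-02-29"), 1)  # "2001-03-01"
#' age_on(as.Date("1980-03-10"), as.Date("2005-03-09"))  # 24
#' @export
add_years <- function(date, n) {
  lt <- as.POSIXlt(date)
  y <- lt$year + 1900L + n
  m <- lt$mon + 1L
  d <- lt$mday
  out <- as.Date(sprintf("%04d-%02d-%02d", y, m, d), format = "%Y-%m-%d")
  # only Feb 29 can fail to exist in the target year: roll to Mar 1
  bad <- is.na(out) & !is.na(date)
  if (any(bad)) out[bad] <- as.Date(sprintf("%04d-03-01", y[bad]))
  out
}

#' @rdname add_years
#' @param on the date(s) on which age is evaluated.
#' @param birth_date a `Date` vector of births.
#' @export
age_on <- function(birth_date, on) {
  bl <- as.POSIXlt(birth_date)
  ol <- as.POSIXlt(on)
  age <- ol$year - bl$year
  pre <- (ol$mon < bl$mon) | (ol$mon == bl$mon & ol$mday < bl$mday)
  as.integer(age - pre)
}

# Parse dates that are either ISO-8601 (YYYY-MM-DD) or, for design configs,
# DD/MM/YYYY.  Vectorised; "" and NA give NA without warnings.
parse_date_flex <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
  x <- trimws(x)
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  iso <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  dmy <- !is.na(x) & grepl("^\\d{1,2}/\\d{1,2}/\\d{4}$", x)
  out[iso] <- as.Date(x[iso], format = "%Y-%m-%d")
  out[dmy] <- as.Date(x[dmy], format = "%d/%m/%Y")
  bad <- !is.na(x) & !iso & !dmy
  if (any(bad)) {
    abort(paste0("unparseable date(s): ", paste(unique(x[bad]), collapse = ", ")))
  }
  out
}

# pmin/pmax over Dates ignoring NA but returning NA when all inputs are NA
pmin_date <- function(...) {
  m <- suppressWarnings(do.call(pmin, c(list(...), na.rm = TRUE)))
  as.Date(m, origin = "1970-01-01")
}

pmax_date <- function(...) {
  m <- suppressWarnings(do.call(pmax, c(list(...), na.rm = TRUE)))
  as.Date(m, origin = "1970-01-01")
}

# min over a possibly empty Date vector without the base warning
min_date <- function(x) {
  if (length(x)) min(x) else as.Date(NA_real_, origin = "1970-01-01")
}
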