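# Rule-based normalization of referral spans to calendar dates.

#' Parse a numeric date string into its components
#'
#' Recognizes (day-first, German convention): `DD.MM.YYYY`, `D.M.YYYY`,
#' `DD.MM.YY`, `DD.MM.` (year omitted), `DD/MM/YYYY`, `MM/YYYY` (day
#' omitted), ISO `YYYY-MM-DD`, and day ranges `DD.-DD.MM.YYYY` (resolved to
#' the last complete date). Missing components are returned as `NA`, never
#' guessed. Two-digit years are mapped into the window
#' `[ref_year - 99, ref_year]`, i.e. "15" in a 2018 context means 2015.
#'
#' @param s Date string.
#' @param ref_year Reference year anchoring the two-digit-year pivot
#'   (typically the referencing report's year). Defaults to the current year.
#' @return Named integer vector `c(day, month, year)` with `NA` for absent
#'   components; all `NA` when the string is not a recognized numeric date.
#' @export
parse_numeric_date <- function(s, ref_year = as.integer(format(Sys.Date(), "%Y"))) {
  none <- c(day = NA_integer_, month = NA_integer_, year = NA_integer_)
  if (is.na(s)) return(none)
  s <- trimws(s)
  ref_year <- as.integer(ref_year)
  pivot <- function(y) {
    y <- as.integer(y)
    if (is.na(y)) return(NA_integer_)
    if (y >= 100L) return(y)
    cent <- ref_year %/% 100L * 100L
    cand <- cent + y
    if (cand > ref_year) cand <- cand - 100L
    cand
  }
  m <- regmatches(s, regexec("^(\\d{1,2})\\.[–-](\\d{1,2})\\.(\\d{1,2})\\.(\\d{2,4})$", s))[[1]]
  if (length(m)) {
    return(c(day = as.integer(m[3]), month = as.integer(m[4]),
             year = pivot(m[5])))
  }
  m <- regmatches(s, regexec("^(\\d{1,2})\\.(\\d{1,2})\\.(\\d{2,4})$", s))[[1]]
  if (length(m)) {
    return(c(day = as.integer(m[2]), month = as.integer(m[3]),
             year = pivot(m[4])))
  }
  m <- regmatches(s, regexec("^(\\d{1,2})\\.(\\d{1,2})\\.$", s))[[1]]
  if (length(m)) {
    return(c(day = as.integer(m[2]), month = as.integer(m[3]),
             year = NA_integer_))
  }
  m <- regmatches(s, regexec("^(\\d{1,2})/(\\d{1,2})/(\\d{2,4})$", s))[[1]]
  if (length(m)) {
    return(c(day = as.integer(m[2]), month = as.integer(m[3]),
             year = pivot(m[4])))
  }
  m <- regmatches(s, regexec("^(\\d{1,2})/(\\d{4})$", s))[[1]]
  if (length(m)) {
    return(c(day = NA_integer_, month = as.integer(m[2]),
             year = as.integer(m[3])))
  }
  m <- regmatches(s, regexec("^(\\d{4})-(\\d{2})-(\\d{2})$", s))[[1]]
  if (length(m)) {
    return(c(day = as.integer(m[4]), month = as.integer(m[3]),
             year = as.integer(m[2])))
  }
  none
}

.make_date <- function(day, month, year) {
  if (anyNA(c(day, month, year))) return(as.Date(NA))
  if (month < 1L || month > 12L || day < 1L || day > 31L) return(as.Date(NA))
  # format-anchored parse returns NA (not an error) for 31.02. and kin
  as.Date(sprintf("%04d-%02d-%02d", year, month, day), format = "%Y-%m-%d")
}

#' Resolve referral spans to calendar dates
#'
#' Applies the normalization rules: `TODAY` spans resolve to the referencing
#' report's date, `YESTERDAY` to the day before, numeric `DATE` spans are
#' parsed against the format bank. A date missing its year is assigned the
#' referencing report's year (`YEAR_IMPUTED`); a date missing its day or
#' month is discarded (`DISCARDED_INCOMPLETE`); unparseable or impossible
#' dates (e.g. 31.02.) are discarded (`DISCARDED_INVALID`).
#'
#' @param spans Span table (`report_id`, `start`, `end`, `cls`, `surface`)
#'   restricted to classes `DATE`, `TODAY`, `YESTERDAY`; any other class is a
#'   contract violation and raises an error.
#' @param reports Report table supplying `study_date` per `report_id`.
#' @param strict_year If `TRUE`, a year-imputed date falling after the
#'   referencing report's date has its year decremented so that resolved
#'   dates never lie in the referencing report's future. The default `FALSE`
#'   implements the literal same-year rule even when it yields a future date.
#' @return `spans` with added columns `resolved` (`Date`, `NA` when
#'   discarded) and `resolution_rule` (one of `FULL_NUMERIC`, `YEAR_IMPUTED`,
#'   `TODAY_RULE`, `YESTERDAY_RULE`, `DISCARDED_INCOMPLETE`,
#'   `DISCARDED_INVALID`).
#' @export
resolve_spans <- function(spans, reports, strict_year = FALSE) {
  bad <- setdiff(unique(spans$cls), c("DATE", "TODAY", "YESTERDAY"))
  if (length(bad)) {
    stop("resolve_spans only accepts DATE/TODAY/YESTERDAY spans, got: ",
         paste(bad, collapse = ", "))
  }
  rdate <- as.Date(stats::setNames(as.character(reports$study_date),
                                   reports$report_id)[spans$report_id])
  if (anyNA(rdate)) stop("spans reference reports with unknown study_date")
  n <- nrow(spans)
  resolved <- as.Date(rep(NA, n))
  rule <- character(n)
  for (i in seq_len(n)) {
    cls <- spans$cls[i]
    rd <- rdate[i]
    if (cls == "TODAY") {
      resolved[i] <- rd; rule[i] <- "TODAY_RULE"
    } else if (cls == "YESTERDAY") {
      resolved[i] <- rd - 1L; rule[i] <- "YESTERDAY_RULE"
    } else {
      comp <- parse_numeric_date(spans$surface[i],
                                 ref_year = as.integer(format(rd, "%Y")))
      if (is.na(comp["day"]) || is.na(comp["month"])) {
        if (all(is.na(comp))) {
          rule[i] <- "DISCARDED_INVALID"
        } else {
          rule[i] <- "DISCARDED_INCOMPLETE"
        }
      } else if (is.na(comp["year"])) {
        yr <- as.integer(format(rd, "%Y"))
        d <- .make_date(comp["day"], comp["month"], yr)
        if (strict_year && !is.na(d) && d > rd) {
          d <- .make_date(comp["day"], comp["month"], yr - 1L)
        }
        if (is.na(d)) {
          rule[i] <- "DISCARDED_INVALID"
        } else {
          resolved[i] <- d; rule[i] <- "YEAR_IMPUTED"
        }
      } else {
        d <- .make_date(comp["day"], comp["month"], comp["year"])
        if (is.na(d)) {
          rule[i] <- "DISCARDED_INVALID"
        } else {
          resolved[i] <- d; rule[i] <- "FULL_NUMERIC"
        }
      }
    }
  }
  spans$resolved <- resolved
  spans$resolution_rule <- rule
  spans
}

#' Write a resolved-spans table to CSV
#'
#' @param resolved Output of [resolve_spans()].
#' @param path Output path.
#' @export
write_resolved_csv <- function(resolved, path) {
  out <- data.frame(
    src_report_id = resolved$report_id,
    span_start = resolved$start, span_end = resolved$end,
    surface = resolved$surface, class = resolved$cls,
    resolved_date = as.character(resolved$resolved),
    resolution_rule = resolved$resolution_rule,
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
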