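# Corpus-level referencing analytics: per-report status, status summaries,
# and inter-referral interval summaries.

round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Classify the referencing status of each report
#'
#' Three-way document status with precedence REFERENCED > NO_PREVIOUS >
#' MISSING: any `DATE`/`TODAY`/`YESTERDAY` span makes a report `REFERENCED`;
#' otherwise any `NO_PREVIOUS` span makes it `NO_PREVIOUS`; a report with no
#' span is `MISSING`. The three statuses partition any corpus.
#'
#' @param reports Report table.
#' @param spans Span table for those reports.
#' @return Data frame with columns `report_id`, `status`.
#' @export
classify_status <- function(reports, spans) {
  status <- rep("MISSING", nrow(reports))
  names(status) <- reports$report_id
  if (nrow(spans)) {
    np <- unique(spans$report_id[spans$cls == "NO_PREVIOUS"])
    status[np] <- "NO_PREVIOUS"
    ref <- unique(spans$report_id[spans$cls %in%
                                    c("DATE", "TODAY", "YESTERDAY")])
    status[ref] <- "REFERENCED"
  }
  data.frame(report_id = reports$report_id, status = unname(status),
             stringsAsFactors = FALSE)
}

#' Summarize referencing statuses as counts and percentages
#'
#' Percentages are `100 * count / group total`, rounded half-up to one
#' decimal; within each group they sum to 100.0 up to rounding.
#'
#' @param statuses Data frame from [classify_status()] (columns `report_id`,
#'   `status`).
#' @param reports Report table; required when `group_by` is given.
#' @param group_by Optional grouping: `"year"`, `"modality"` or
#'   `"body_region"`.
#' @return Data frame with columns (`group`,) `status`, `n`, `pct`.
#' @export
status_summary <- function(statuses, reports = NULL, group_by = NULL) {
  lev <- c("REFERENCED", "NO_PREVIOUS", "MISSING")
  if (is.null(group_by)) {
    tab <- table(factor(statuses$status, levels = lev))
    out <- data.frame(status = lev, n = as.integer(tab),
                      stringsAsFactors = FALSE)
    out$pct <- round_half_up(100 * out$n / sum(out$n))
    return(out)
  }
  if (is.null(reports)) stop("group_by requires the report table")
  group_by <- match.arg(group_by, c("year", "modality", "body_region"))
  grp <- switch(group_by,
                year = format(as.Date(reports$study_date), "%Y"),
                modality = reports$modality,
                body_region = reports$body_region)
  grp <- stats::setNames(grp, reports$report_id)[statuses$report_id]
  out <- list()
  for (g in sort(unique(grp))) {
    tab <- table(factor(statuses$status[grp == g], levels = lev))
    tot <- sum(tab)
    out[[g]] <- data.frame(group = g, status = lev, n = as.integer(tab),
                           pct = round_half_up(100 * as.integer(tab) / tot),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize intervals between referencing and referenced reports
#'
#' Computes, per group of the referencing report, the median, first and
#' third quartile and IQR of `src.study_date - dst.study_date` in days.
#' Quantiles use linear interpolation between order statistics, so
#' half-day medians occur on even counts. Empty groups yield no row.
#'
#' @param links Link table (`src_report_id`, `dst_report_id`, ...).
#' @param reports Report table.
#' @param group_by `"modality"` or `"body_region"` of the referencing report.
#' @return Data frame with columns `group`, `n`, `median`, `q1`, `q3`, `iqr`.
#' @export
interval_summary <- function(links, reports, group_by = c("modality",
                                                          "body_region")) {
  group_by <- match.arg(group_by)
  dates <- as.Date(stats::setNames(as.character(reports$study_date),
                                   reports$report_id))
  attr_src <- stats::setNames(reports[[group_by]], reports$report_id)
  gap <- as.numeric(dates[links$src_report_id] - dates[links$dst_report_id])
  grp <- unname(attr_src[links$src_report_id])
  out <- list()
  for (g in sort(unique(grp))) {
    x <- gap[grp == g]
    q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
    out[[g]] <- data.frame(group = g, n = length(x), median = q[2],
                           q1 = q[1], q3 = q[3], iqr = q[3] - q[1],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
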