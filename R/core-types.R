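#' Validate a table of reports
#'
#' Checks the report invariants: parsable study dates, unique report ids,
#' known modality and body-region codes, non-missing patient ids. Violations
#' are returned as data, not raised.
#'
#' @param reports Data frame with columns `report_id`, `patient_id`,
#'   `modality`, `body_region`, `study_date`, `exam_name`, `text`.
#' @param modalities,regions Allowed code sets.
#' @return Data frame with columns `report_id`, `field`, `problem`; zero rows
#'   when all invariants hold.
#' @export
validate_reports <- function(reports, modalities = modality_codes(),
                             regions = body_regions()) {
  viol <- list()
  add <- function(id, field, problem) {
    viol[[length(viol) + 1L]] <<- data.frame(
      report_id = id, field = field, problem = problem,
      stringsAsFactors = FALSE)
  }
  need <- c("report_id", "patient_id", "modality", "body_region",
            "study_date", "exam_name", "text")
  miss <- setdiff(need, names(reports))
  if (length(miss)) {
    stop("reports is missing columns: ", paste(miss, collapse = ", "))
  }
  dup <- reports$report_id[duplicated(reports$report_id)]
  for (id in unique(dup)) add(id, "report_id", "duplicate report_id")
  # format-anchored so an impossible date yields NA instead of an error
  dates <- as.Date(as.character(reports$study_date), format = "%Y-%m-%d")
  bad <- which(is.na(dates))
  for (i in bad) add(reports$report_id[i], "study_date",
                     paste0("invalid date: ", reports$study_date[i]))
  for (i in which(!reports$modality %in% modalities)) {
    add(reports$report_id[i], "modality",
        paste0("unknown modality: ", reports$modality[i]))
  }
  for (i in which(!reports$body_region %in% regions)) {
    add(reports$report_id[i], "body_region",
        paste0("unknown body_region: ", reports$body_region[i]))
  }
  for (i in which(is.na(reports$patient_id) | !nzchar(reports$patient_id))) {
    add(reports$report_id[i], "patient_id", "empty patient_id")
  }
  if (length(viol)) do.call(rbind, viol) else
    data.frame(report_id = character(), field = character(),
               problem = character(), stringsAsFactors = FALSE)
}

#' Validate annotation spans against their reports
#'
#' Checks 0-based half-open offsets (`0 <= start < end <= nchar(text)`),
#' surface/text agreement, span class membership, and per-report overlap.
#'
#' @param spans Data frame with columns `report_id`, `start`, `end`, `cls`,
#'   `surface`.
#' @param reports Report table (see [validate_reports()]).
#' @return Data frame of violations (zero rows when valid).
#' @export
validate_spans <- function(spans, reports) {
  viol <- list()
  add <- function(id, problem) {
    viol[[length(viol) + 1L]] <<- data.frame(
      report_id = id, field = "span", problem = problem,
      stringsAsFactors = FALSE)
  }
  texts <- stats::setNames(reports$text, reports$report_id)
  span_cls <- setdiff(referral_classes(), "MISSING")
  for (i in seq_len(nrow(spans))) {
    id <- spans$report_id[i]
    if (!id %in% names(texts)) { add(id, "unknown report_id"); next }
    txt <- texts[[id]]
    s <- spans$start[i]; e <- spans$end[i]
    if (is.na(s) || is.na(e) || s < 0 || s >= e || e > nchar(txt)) {
      add(id, sprintf("bad offsets [%s,%s)", s, e)); next
    }
    surf <- substr(txt, s + 1L, e)
    if (!identical(surf, spans$surface[i])) {
      add(id, sprintf("surface mismatch at [%d,%d): '%s' vs '%s'",
                      s, e, spans$surface[i], surf))
    }
    if (!spans$cls[i] %in% span_cls) {
      add(id, paste0("invalid span class: ", spans$cls[i]))
    }
  }
  for (id in unique(spans$report_id)) {
    ss <- spans[spans$report_id == id, , drop = FALSE]
    ss <- ss[order(ss$start), , drop = FALSE]
    if (nrow(ss) > 1 && any(ss$start[-1] < ss$end[-nrow(ss)])) {
      add(id, "overlapping spans")
    }
  }
  if (length(viol)) do.call(rbind, viol) else
    data.frame(report_id = character(), field = character(),
               problem = character(), stringsAsFactors = FALSE)
}

#' Serialize reports to JSON Lines
#'
#' One JSON object per line with fields `report_id`, `patient_id`,
#' `modality`, `body_region`, `study_date` (ISO-8601), `exam_name`, `text`.
#'
#' @param reports Report table.
#' @param path Output file path.
#' @export
write_reports_jsonl <- function(reports, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(reports))) {
    rec <- list(
      report_id = reports$report_id[i],
      patient_id = reports$patient_id[i],
      modality = reports$modality[i],
      body_region = reports$body_region[i],
      study_date = as.character(reports$study_date[i]),
      exam_name = reports$exam_name[i],
      text = reports$text[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read reports from JSON Lines
#'
#' @param path File written by [write_reports_jsonl()].
#' @return Report data frame with `study_date` as `Date`.
#' @export
read_reports_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  out <- do.call(rbind, lapply(recs, function(r) {
    data.frame(report_id = r$report_id, patient_id = r$patient_id,
               modality = r$modality, body_region = r$body_region,
               study_date = r$study_date, exam_name = r$exam_name,
               text = r$text, stringsAsFactors = FALSE)
  }))
  out$study_date <- as.Date(out$study_date)
  out
}

#' Write exam metadata to CSV
#'
#' Metadata-only view (no text) with header
#' `patient_id,report_id,modality,body_region,study_date,exam_name`.
#'
#' @param reports Report table.
#' @param path Output path.
#' @export
write_metadata_csv <- function(reports, path) {
  utils::write.csv(
    reports[, c("patient_id", "report_id", "modality", "body_region",
                "study_date", "exam_name")],
    path, row.names = FALSE)
  invisible(path)
}

#' Write annotation spans to JSON Lines
#' @param spans Span table (`report_id`, `start`, `end`, `cls`, `surface`).
#' @param path Output path.
#' @export
write_spans_jsonl <- function(spans, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(spans))) {
    rec <- list(report_id = spans$report_id[i],
                start = spans$start[i], end = spans$end[i],
                cls = spans$cls[i], surface = spans$surface[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read annotation spans from JSON Lines
#' @param path File written by [write_spans_jsonl()].
#' @return Span data frame.
#' @export
read_spans_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  out <- do.call(rbind, lapply(lines, function(l) {
    r <- jsonlite::fromJSON(l)
    data.frame(report_id = r$report_id, start = r$start, end = r$end,
               cls = r$cls, surface = r$surface, stringsAsFactors = FALSE)
  }))
  out
}
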