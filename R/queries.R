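# Exploration primitives over the report graph: related-study retrieval,
# sequence selection, missing-comparison detection, and the referral matrix.

#' Related studies of a report
#'
#' Returns the weakly connected component containing the given report. Since
#' referral links never cross patients, the component is always confined to
#' the report's patient, and the result is identical for every seed node
#' inside the component.
#'
#' @param g A `report_graph`.
#' @param report_id Seed node.
#' @return A `report_graph` restricted to the component.
#' @export
related_component <- function(g, report_id) {
  if (!report_id %in% g$reports$report_id) {
    stop("unknown report: ", report_id)
  }
  comp <- igraph::subcomponent(g$ig, report_id, mode = "all")
  ids <- igraph::V(g$ig)$name[comp]
  reports <- g$reports[g$reports$report_id %in% ids, , drop = FALSE]
  links <- g$links[g$links$src_report_id %in% ids &
                     g$links$dst_report_id %in% ids, , drop = FALSE]
  build_report_graph(reports, links)
}

#' Describe an exam-sequence pattern
#'
#' A linear pattern of node filters applied to consecutive exams of one
#' patient, ordered earliest step first. Each step filter may restrict the
#' modality set, body-region set, a case-insensitive keyword in the report
#' text, and a study-date window.
#'
#' @param steps List of step filters; each a list with optional elements
#'   `modality`, `body_region` (character vectors), `keyword` (scalar
#'   string), `date_min`, `date_max`.
#' @param max_gap_days Upper bound on the study-date difference of each
#'   adjacent pair; scalar or vector of length `length(steps) - 1`.
#' @param require_edge Must consecutive steps be connected by a referral
#'   edge (from the later exam to the earlier one)?
#' @return Object of class `sequence_pattern`.
#' @export
sequence_pattern <- function(steps, max_gap_days = Inf, require_edge = TRUE) {
  if (!length(steps)) stop("a pattern needs at least one step")
  if (any(max_gap_days < 0)) stop("max_gap_days must be nonnegative")
  structure(list(steps = steps, max_gap_days = max_gap_days,
                 require_edge = require_edge), class = "sequence_pattern")
}

.step_matches <- function(reports, step) {
  keep <- rep(TRUE, nrow(reports))
  if (!is.null(step$modality)) keep <- keep & reports$modality %in% step$modality
  if (!is.null(step$body_region)) {
    keep <- keep & reports$body_region %in% step$body_region
  }
  if (!is.null(step$keyword)) {
    keep <- keep & grepl(step$keyword, reports$text, ignore.case = TRUE,
                         fixed = FALSE)
  }
  if (!is.null(step$date_min)) {
    keep <- keep & reports$study_date >= as.Date(step$date_min)
  }
  if (!is.null(step$date_max)) {
    keep <- keep & reports$study_date <= as.Date(step$date_max)
  }
  reports$report_id[keep]
}

#' Select exam sequences matching a pattern
#'
#' Finds all tuples of same-patient reports (earliest step first, dates
#' nondecreasing) in which every member satisfies its step filter, each
#' adjacent gap respects the bound, and — when `require_edge` — the later
#' member of each pair references the earlier one by an edge. Results are
#' deterministic: sorted by patient, then first-step date, then report ids.
#'
#' @param g A `report_graph`.
#' @param pattern A [sequence_pattern()].
#' @return List of character vectors of report ids (possibly empty).
#' @export
select_sequences <- function(g, pattern) {
  stopifnot(inherits(pattern, "sequence_pattern"))
  k <- length(pattern$steps)
  gaps <- rep(pattern$max_gap_days, length.out = max(k - 1L, 1L))
  matches <- lapply(pattern$steps, .step_matches, reports = g$reports)
  if (any(!vapply(matches, length, 1L))) return(list())
  dates <- as.Date(stats::setNames(as.character(g$reports$study_date),
                                   g$reports$report_id))
  pats <- stats::setNames(g$reports$patient_id, g$reports$report_id)
  edge_key <- paste(g$links$src_report_id, g$links$dst_report_id, sep = "\r")
  tuples <- lapply(matches[[1]], function(id) id)
  if (k > 1L) {
    for (s in 2:k) {
      nxt <- list()
      for (tp in tuples) {
        prev <- tp[length(tp)]
        for (id in matches[[s]]) {
          if (id %in% tp) next
          if (pats[[id]] != pats[[prev]]) next
          gap <- as.numeric(dates[[id]] - dates[[prev]])
          if (gap < 0 || gap > gaps[s - 1L]) next
          if (pattern$require_edge &&
                !(paste(id, prev, sep = "\r") %in% edge_key)) next
          nxt[[length(nxt) + 1L]] <- c(tp, id)
        }
      }
      tuples <- nxt
      if (!length(tuples)) return(list())
    }
  }
  ord <- order(vapply(tuples, function(tp) pats[[tp[1]]], ""),
               vapply(tuples, function(tp) as.character(dates[[tp[1]]]), ""),
               vapply(tuples, paste, "", collapse = "\r"))
  tuples[ord]
}

#' Detect suspected missing comparisons
#'
#' Flags ordered same-patient exam pairs (earlier, later) within the gap
#' window and matching the region/modality constraints for which (a) the
#' later report does not reference the earlier one and (b) — unless
#' `require_superseded` is disabled — the later report references no exam
#' acquired on or after the earlier exam's date, i.e. the comparison was
#' genuinely skipped rather than superseded by a newer comparison.
#'
#' @param g A `report_graph`.
#' @param same_region,same_modality Restrict pairs to equal body region /
#'   modality.
#' @param max_gap_days Maximum days between the two exams.
#' @param require_superseded Apply clause (b) above (default `TRUE`).
#' @param statuses Optional status table (from [classify_status()]); used to
#'   distinguish the reasons.
#' @return Data frame `earlier_id`, `later_id`, `reason` with reason
#'   `"missing"` (the later report references nothing at all),
#'   `"no_previous_stated"`, or `"referenced_but_skipped"`.
#' @export
detect_missing_links <- function(g, same_region = TRUE, same_modality = TRUE,
                                 max_gap_days = 365,
                                 require_superseded = TRUE,
                                 statuses = NULL) {
  reports <- g$reports
  dates <- as.Date(as.character(reports$study_date))
  out_edges <- split(g$links$dst_report_id, g$links$src_report_id)
  date_of <- stats::setNames(dates, reports$report_id)
  status_of <- if (!is.null(statuses)) {
    stats::setNames(statuses$status, statuses$report_id)
  } else NULL
  cols <- list(earlier_id = character(0), later_id = character(0),
               reason = character(0))
  for (pid in unique(reports$patient_id)) {
    px <- which(reports$patient_id == pid)
    px <- px[order(dates[px], reports$report_id[px])]
    if (length(px) < 2L) next
    for (a in seq_len(length(px) - 1L)) {
      for (b in (a + 1L):length(px)) {
        i <- px[a]; j <- px[b]
        gap <- as.numeric(dates[j] - dates[i])
        if (gap <= 0 || gap > max_gap_days) next
        if (same_region && reports$body_region[i] != reports$body_region[j]) next
        if (same_modality && reports$modality[i] != reports$modality[j]) next
        refs <- out_edges[[reports$report_id[j]]]
        if (!is.null(refs) && reports$report_id[i] %in% refs) next
        if (require_superseded && !is.null(refs) &&
              any(date_of[refs] >= dates[i])) next
        reason <- if (!is.null(status_of)) {
          st <- status_of[[reports$report_id[j]]]
          switch(st, MISSING = "missing",
                 NO_PREVIOUS = "no_previous_stated",
                 "referenced_but_skipped")
        } else if (is.null(refs)) "missing" else "referenced_but_skipped"
        cols$earlier_id <- c(cols$earlier_id, reports$report_id[i])
        cols$later_id <- c(cols$later_id, reports$report_id[j])
        cols$reason <- c(cols$reason, reason)
      }
    }
  }
  data.frame(cols, stringsAsFactors = FALSE)
}

#' Cross-group referral count matrix
#'
#' Cell `[a, b]` counts the edges whose referencing report belongs to group
#' `a` and whose referenced report belongs to group `b` — the count matrix
#' behind a chord diagram of cross-modality (or cross-region) referrals.
#' Row sums equal per-group outgoing edge counts; without a window the total
#' equals the number of edges.
#'
#' @param g A `report_graph`.
#' @param group_by `"modality"` or `"body_region"`.
#' @param window_days Optional: keep only edges with
#'   `src.study_date - dst.study_date <= window_days`.
#' @return Square integer matrix with all group levels as dimnames.
#' @export
referral_matrix <- function(g, group_by = c("modality", "body_region"),
                            window_days = NULL) {
  group_by <- match.arg(group_by)
  lev <- if (group_by == "modality") modality_codes() else
    sort(unique(c(body_regions(), g$reports$body_region)))
  attr_of <- stats::setNames(g$reports[[group_by]], g$reports$report_id)
  links <- g$links
  if (!is.null(window_days) && nrow(links)) {
    dates <- as.Date(stats::setNames(as.character(g$reports$study_date),
                                     g$reports$report_id))
    gap <- as.numeric(dates[links$src_report_id] - dates[links$dst_report_id])
    links <- links[gap <= window_days, , drop = FALSE]
  }
  src <- factor(attr_of[links$src_report_id], levels = lev)
  dst <- factor(attr_of[links$dst_report_id], levels = lev)
  m <- table(src, dst)
  out <- matrix(as.integer(m), nrow = length(lev), dimnames = list(lev, lev))
  out
}
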