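# Resolve referral dates to concrete prior exams of the same patient and
# grade each link's confidence 1-4.

#' Extract the modality mentioned in a sentence
#'
#' Lexicon lookup over the German modality synonym table; the synonym whose
#' match starts earliest in the sentence wins (at equal start positions the
#' longer synonym wins, so "PET-CT" beats the embedded "CT"). Matching is
#' case-insensitive and bounded by non-alphanumeric characters.
#'
#' @param sentence Sentence text.
#' @param lexicon Synonym table, see [modality_lexicon()].
#' @return A modality code, or `NA_character_` when no synonym occurs.
#' @export
extract_mentioned_modality <- function(sentence, lexicon = modality_lexicon()) {
  best_pos <- Inf; best_len <- -1L; best_mod <- NA_character_
  for (mod in names(lexicon)) {
    for (syn in lexicon[[mod]]) {
      pat <- paste0("(?<![\\p{L}\\p{N}])", .regex_escape(syn),
                    "(?![\\p{L}\\p{N}])")
      m <- regexpr(pat, sentence, perl = TRUE, ignore.case = TRUE)
      if (m[1] == -1) next
      pos <- as.integer(m[1]); len <- attr(m, "match.length")
      if (pos < best_pos || (pos == best_pos && len > best_len)) {
        best_pos <- pos; best_len <- len; best_mod <- mod
      }
    }
  }
  best_mod
}

#' Resolve one referral to a prior exam and grade its confidence
#'
#' Candidates are the patient's exams acquired on the resolved date, no
#' later than the referencing report and excluding it. The grading criteria
#' are tried in order: (1) date, modality and body part; (2) date and
#' modality; (3) date and body part; (4) date — where "modality" means the
#' candidate's modality equals the modality mentioned in the referral
#' sentence and "body part" means the candidate's body region equals the
#' referencing report's. The first criterion with at least one candidate
#' wins; grade 1 is the most confident, 4 the least. When no modality is
#' mentioned, grades 1 and 2 are unsatisfiable and grading starts at 3.
#' Ties break to the lexicographically lowest report id. Returns `NULL`
#' when the link cannot be generated (no exam on that date).
#'
#' @param src One-row data frame: the referencing report.
#' @param resolved_date Resolved referral date (`Date`).
#' @param mentioned_modality Modality code or `NA`.
#' @param exams All exams (report table rows) of the source report's patient.
#' @return List with `dst_report_id` and `confidence`, or `NULL`.
#' @export
build_link <- function(src, resolved_date, mentioned_modality, exams) {
  if (is.na(resolved_date)) return(NULL)
  cand <- exams[exams$study_date == resolved_date &
                  exams$study_date <= src$study_date &
                  exams$report_id != src$report_id, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  has_m <- !is.na(mentioned_modality)
  crit <- list(
    if (has_m) cand$modality == mentioned_modality &
      cand$body_region == src$body_region else rep(FALSE, nrow(cand)),
    if (has_m) cand$modality == mentioned_modality else
      rep(FALSE, nrow(cand)),
    cand$body_region == src$body_region,
    rep(TRUE, nrow(cand)))
  for (g in 1:4) {
    hit <- which(crit[[g]])
    if (length(hit)) {
      return(list(dst_report_id = min(cand$report_id[hit]),
                  confidence = g))
    }
  }
  NULL
}

#' Build the referral link table for a corpus
#'
#' For every resolved span, extracts the modality mentioned in the sentence
#' containing the span, resolves the referral against the patient's exam
#' history with [build_link()], and collects the surviving links. Spans
#' whose date was discarded, that resolve to a future date, or that match no
#' exam are dropped.
#'
#' @param resolved Output of [resolve_spans()].
#' @param reports Report table (all exams; the per-patient index is derived
#'   from it).
#' @param lexicon Modality synonym table.
#' @return Link table: `src_report_id`, `dst_report_id`, `reference_class`,
#'   `extracted_string`, `confidence`.
#' @export
build_links <- function(resolved, reports, lexicon = modality_lexicon()) {
  cols <- list(src_report_id = character(0), dst_report_id = character(0),
               reference_class = character(0), extracted_string = character(0),
               confidence = integer(0))
  if (!nrow(resolved)) return(data.frame(cols, stringsAsFactors = FALSE))
  rep_idx <- stats::setNames(seq_len(nrow(reports)), reports$report_id)
  sent_cache <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(resolved))) {
    if (is.na(resolved$resolved[k])) next
    src_i <- rep_idx[[resolved$report_id[k]]]
    if (is.null(src_i)) stop("unknown report: ", resolved$report_id[k])
    src <- reports[src_i, , drop = FALSE]
    key <- resolved$report_id[k]
    sents <- if (!is.null(sent_cache[[key]])) sent_cache[[key]] else {
      s <- split_sentences(src$text)
      sent_cache[[key]] <- s
      s
    }
    hit <- which(sents$start <= resolved$start[k] &
                   sents$end >= resolved$end[k])
    sentence <- if (length(hit)) sents$text[hit[1]] else src$text
    mention <- extract_mentioned_modality(sentence, lexicon)
    exams <- reports[reports$patient_id == src$patient_id, , drop = FALSE]
    link <- build_link(src, resolved$resolved[k], mention, exams)
    if (is.null(link)) next
    cols$src_report_id <- c(cols$src_report_id, src$report_id)
    cols$dst_report_id <- c(cols$dst_report_id, link$dst_report_id)
    cols$reference_class <- c(cols$reference_class, resolved$cls[k])
    cols$extracted_string <- c(cols$extracted_string, resolved$surface[k])
    cols$confidence <- c(cols$confidence, link$confidence)
  }
  data.frame(cols, stringsAsFactors = FALSE)
}
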