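# Deterministic regex/lexicon tagger: the no-training baseline and the gold
# consistency oracle for synthetic corpora.

.date_token_regex <- paste0(
  "^(",
  "\\d{1,2}\\.[–-]\\d{1,2}\\.\\d{1,2}\\.\\d{2,4}",
  "|\\d{1,2}\\.\\d{1,2}\\.(\\d{2,4})?",
  "|\\d{1,2}/\\d{1,2}/\\d{2,4}",
  "|\\d{1,2}/\\d{4}",
  "|\\d{4}-\\d{2}-\\d{2}",
  ")$")

#' Tag referral spans with deterministic rules
#'
#' Numeric-date tokens (any of the supported full or partial formats) are
#' tagged `DATE`; literal matches from the `TODAY`, `YESTERDAY` and
#' `NO_PREVIOUS` phrase lexicons are tagged with their class. Longer phrases
#' take precedence over shorter ones at overlapping positions; matching is
#' case-insensitive and bounded by non-letter characters.
#'
#' @param reports Report table.
#' @param phrases Phrase lexicon, see [referral_phrases()].
#' @param include_yesterday Tag the `YESTERDAY` lexicon (default `TRUE`; the
#'   class is handled by rules even when excluded from NER training).
#' @return Span table (`report_id`, `start`, `end`, `cls`, `surface`).
#' @export
rule_tagger <- function(reports, phrases = referral_phrases(),
                        include_yesterday = TRUE) {
  classes <- c("TODAY", "NO_PREVIOUS", if (include_yesterday) "YESTERDAY")
  phrase_tab <- do.call(rbind, lapply(classes, function(cl) {
    if (!length(phrases[[cl]])) return(NULL)
    data.frame(cls = cl, phrase = phrases[[cl]], stringsAsFactors = FALSE)
  }))
  phrase_tab <- phrase_tab[order(-nchar(phrase_tab$phrase)), , drop = FALSE]

  cols <- list(report_id = character(0), start = integer(0),
               end = integer(0), cls = character(0), surface = character(0))
  for (i in seq_len(nrow(reports))) {
    text <- reports$text[i]
    taken <- logical(nchar(text))
    # date tokens
    toks <- report_tokens(reports[i, , drop = FALSE])
    if (nrow(toks)) {
      hits <- grepl(.date_token_regex, toks$token, perl = TRUE)
      for (k in which(hits)) {
        cols$report_id <- c(cols$report_id, reports$report_id[i])
        cols$start <- c(cols$start, toks$start[k])
        cols$end <- c(cols$end, toks$end[k])
        cols$cls <- c(cols$cls, "DATE")
        cols$surface <- c(cols$surface, toks$token[k])
        taken[(toks$start[k] + 1L):toks$end[k]] <- TRUE
      }
    }
    # lexicon phrases, longest first, no overlap
    for (r in seq_len(nrow(phrase_tab))) {
      pat <- paste0("(?<![\\p{L}\\p{N}])",
                    .regex_escape(phrase_tab$phrase[r]),
                    "(?![\\p{L}\\p{N}])")
      m <- gregexpr(pat, text, perl = TRUE, ignore.case = TRUE)[[1]]
      if (m[1] == -1) next
      lens <- attr(m, "match.length")
      for (j in seq_along(m)) {
        s <- as.integer(m[j]); e <- s + lens[j] - 1L  # 1-based inclusive
        if (any(taken[s:e])) next
        taken[s:e] <- TRUE
        cols$report_id <- c(cols$report_id, reports$report_id[i])
        cols$start <- c(cols$start, s - 1L)
        cols$end <- c(cols$end, e)
        cols$cls <- c(cols$cls, phrase_tab$cls[r])
        cols$surface <- c(cols$surface, substr(text, s, e))
      }
    }
  }
  out <- data.frame(cols, stringsAsFactors = FALSE)
  out[order(out$report_id, out$start), , drop = FALSE]
}
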