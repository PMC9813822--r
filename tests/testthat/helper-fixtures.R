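# Fixture builders shared across test files.

make_reports <- function(ids, patient = "P1", modality = "CT",
                         region = "thorax", dates = NULL, text = "Befund.") {
  n <- length(ids)
  data.frame(
    report_id = ids,
    patient_id = rep_len(patient, n),
    modality = rep_len(modality, n),
    body_region = rep_len(region, n),
    study_date = as.Date(rep_len(if (is.null(dates))
      as.character(seq(as.Date("2015-01-01"), by = "month",
                       length.out = n)) else as.character(dates), n)),
    exam_name = paste0(rep_len(modality, n), "-", rep_len(region, n)),
    text = rep_len(text, n),
    stringsAsFactors = FALSE)
}

# A small deterministic corpus reused by several files.
small_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_corpus(corpus_config(n_patients = 30, seed = 303))
    }
    cache
  }
})

span_keys <- function(spans) {
  paste(spans$report_id, spans$start, spans$end, spans$cls, sep = "|")
}

# Exhaustive comparison of build_link against an independent best-match
# search over all presence masks of {2 modalities} x {2 regions} candidates,
# crossed with the mention and source-region choices. Returns the number of
# disagreeing cases (0 when the grading is equivalent).
build_link_enumeration_mismatches <- function() {
  combos <- expand.grid(mod = c("CT", "MR"), reg = c("thorax", "head"),
                        stringsAsFactors = FALSE)
  day <- as.Date("2016-01-01")
  brute <- function(cand, mention, src_reg) {
    if (!nrow(cand)) return(NULL)
    g <- vapply(seq_len(nrow(cand)), function(i) {
      m <- !is.na(mention) && cand$modality[i] == mention
      r <- cand$body_region[i] == src_reg
      if (m && r) 1L else if (m) 2L else if (r) 3L else 4L
    }, 1L)
    best <- min(g)
    list(dst_report_id = min(cand$report_id[g == best]), confidence = best)
  }
  bad <- 0L
  for (mask in 0:15) {
    present <- which(bitwAnd(mask, 2^(0:3)) > 0)
    cand <- if (length(present)) {
      do.call(rbind, lapply(seq_along(present), function(k) {
        make_reports(sprintf("R%d", k), modality = combos$mod[present[k]],
                     region = combos$reg[present[k]], dates = day)
      }))
    } else NULL
    for (mention in c("CT", "MR", NA_character_)) {
      for (src_reg in c("thorax", "head")) {
        src <- make_reports("R9", region = src_reg, dates = "2016-05-01")
        exams <- if (is.null(cand)) src else rbind(src, cand)
        got <- build_link(src, day, mention, exams)
        want <- if (is.null(cand)) NULL else brute(cand, mention, src_reg)
        if (!identical(got, want)) bad <- bad + 1L
      }
    }
  }
  bad
}
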