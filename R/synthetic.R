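# Synthetic longitudinal corpus of German-style radiology reports with gold
# spans, gold links and gold statuses. Surface text is template-based; the
# realism target is exercising tokenization, mixed date formats and
# same-sentence modality mentions, not fluency.

#' Configuration for the synthetic corpus generator
#'
#' Defaults encode the study conditions emulated by the generator: the
#' annotation class mixture 44% date / 27% no-previous / 23% missing /
#' 6% today, longitudinal per-patient exam histories, mixed German date
#' formats, and controlled rates of partial dates, dangling dates and
#' same-sentence modality mentions.
#'
#' @param n_patients Number of patients.
#' @param exams_per_patient_mean Mean exams per patient; counts are
#'   `1 + Geometric(1/mean)`.
#' @param date_range Character vector of two ISO dates bounding study dates.
#' @param class_mixture Named probabilities over `DATE`, `NO_PREVIOUS`,
#'   `MISSING`, `TODAY` (optionally `YESTERDAY`), summing to 1.
#' @param date_format_mixture Named probabilities over the full-date render
#'   formats `DD.MM.YYYY`, `D.M.YYYY`, `DD.MM.YY`, `DD/MM/YYYY`,
#'   `YYYY-MM-DD`.
#' @param p_year_omitted Probability a renderable date drops its year
#'   ("12.03."); only applied when the referenced exam shares the
#'   referencing report's year, so year imputation recovers it.
#' @param p_day_or_month_omitted Probability a date is rendered month/year
#'   only ("03/2019"), which the normalizer must discard.
#' @param p_dangling_date Probability a date span points at a date on which
#'   the patient has no exam (span without link).
#' @param p_mention_modality_in_sentence Probability the referral sentence
#'   names the referenced exam's modality.
#' @param p_same_region Probability the referenced prior exam is drawn from
#'   priors of the referencing report's body region (when one exists).
#' @param p_same_day Probability an exam shares its predecessor's date
#'   (enables resolvable same-day TODAY references).
#' @param extra_date_referrals_lambda Poisson mean of additional date spans
#'   beyond the primary one in a DATE-class report.
#' @param p_noise Probability a TODAY/YESTERDAY/NO_PREVIOUS phrase is drawn
#'   from out-of-lexicon variants unknown to the rule-based tagger.
#' @param seed Integer seed; the same seed and config yield a byte-identical
#'   corpus.
#' @return Object of class `corpus_config`.
#' @export
corpus_config <- function(n_patients = 100,
                          exams_per_patient_mean = 4,
                          date_range = c("2011-01-01", "2020-12-31"),
                          class_mixture = c(DATE = 0.44, NO_PREVIOUS = 0.27,
                                            MISSING = 0.23, TODAY = 0.06),
                          date_format_mixture = c("DD.MM.YYYY" = 0.60,
                                                  "D.M.YYYY" = 0.15,
                                                  "DD.MM.YY" = 0.15,
                                                  "DD/MM/YYYY" = 0.05,
                                                  "YYYY-MM-DD" = 0.05),
                          p_year_omitted = 0.08,
                          p_day_or_month_omitted = 0.02,
                          p_dangling_date = 0.05,
                          p_mention_modality_in_sentence = 0.7,
                          p_same_region = 0.8,
                          p_same_day = 0.05,
                          extra_date_referrals_lambda = 1.3,
                          p_noise = 0,
                          seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              exams_per_patient_mean = exams_per_patient_mean,
              date_range = as.Date(date_range),
              class_mixture = class_mixture,
              date_format_mixture = date_format_mixture,
              p_year_omitted = p_year_omitted,
              p_day_or_month_omitted = p_day_or_month_omitted,
              p_dangling_date = p_dangling_date,
              p_mention_modality_in_sentence = p_mention_modality_in_sentence,
              p_same_region = p_same_region,
              p_same_day = p_same_day,
              extra_date_referrals_lambda = extra_date_referrals_lambda,
              p_noise = p_noise,
              seed = as.integer(seed))
  class(cfg) <- "corpus_config"
  validate_corpus_config(cfg)
  cfg
}

validate_corpus_config <- function(cfg) {
  probs <- c(cfg$p_year_omitted, cfg$p_day_or_month_omitted,
             cfg$p_dangling_date, cfg$p_mention_modality_in_sentence,
             cfg$p_same_region, cfg$p_same_day, cfg$p_noise)
  if (any(probs < 0 | probs > 1)) {
    stop("configuration error: probabilities must lie in [0, 1]")
  }
  allowed <- c("DATE", "NO_PREVIOUS", "MISSING", "TODAY", "YESTERDAY")
  if (!all(names(cfg$class_mixture) %in% allowed)) {
    stop("configuration error: unknown class in class_mixture")
  }
  if (abs(sum(cfg$class_mixture) - 1) > 1e-9) {
    stop("configuration error: class_mixture must sum to 1")
  }
  if (abs(sum(cfg$date_format_mixture) - 1) > 1e-9) {
    stop("configuration error: date_format_mixture must sum to 1")
  }
  if (cfg$n_patients < 1 || cfg$exams_per_patient_mean < 1) {
    stop("configuration error: counts must be positive")
  }
  if (cfg$date_range[1] > cfg$date_range[2]) {
    stop("configuration error: empty date_range")
  }
  invisible(cfg)
}

.modality_weights <- c(CR = 0.30, CT = 0.22, MR = 0.18, US = 0.12, MG = 0.06,
                       XA = 0.04, NM = 0.04, PT = 0.03, OT = 0.01)
.region_weights <- c(thorax = 0.22, abdomen = 0.16, head = 0.14, spine = 0.08,
                     pelvis = 0.06, breast = 0.06, upper_extremity = 0.06,
                     lower_extremity = 0.06, neck = 0.04, heart = 0.04,
                     trunk = 0.03, whole_body = 0.03, vessels = 0.01,
                     other = 0.01)

.filler <- list(
  Anamnese = c("Bekanntes Tumorleiden.", "Zustand nach Operation.",
               "Chronische Schmerzen seit mehreren Wochen.",
               "Klinisch progrediente Beschwerden.",
               "Patient in gutem Allgemeinzustand."),
  Fragestellung = c("Verlauf?", "Progredienz?", "Infiltrat?", "Fraktur?",
                    "Metastasen?"),
  Untersuchung = c("Untersuchung in Standardtechnik.",
                   "Nativ und nach Kontrastmittelgabe untersucht.",
                   "Regelrechte Lagerung und Technik.",
                   "Untersuchung in zwei Ebenen."),
  Befund = c("Kein Nachweis eines Infiltrats.",
             "Unauffaellige Darstellung der Organe.",
             "Regelrechte Weite der Liquorraeume.",
             "Kein Anhalt fuer eine frische Fraktur.",
             "Herzgroesse im Normbereich.",
             "Laesion von 3,5 cm Durchmesser."),
  Beurteilung = c("Unauffaelliger Befund.", "Stabiler Verlauf.",
                  "Kein Anhalt fuer Progredienz.",
                  "Weitere Kontrolle empfohlen.")
)

.date_templates <- c(
  "Vergleich mit %svom %s.",
  "Im Vergleich zur Voruntersuchung %svom %s unveraendert.",
  "Verlaufskontrolle %svom %s.",
  "Gegenueber %svom %s kein neuer Befund."
)

.phrase_templates <- c(
  "Vergleich mit %s%s.",
  "Gegenueber %s%s stabiler Befund."
)

.render_date <- function(date, fmt) {
  switch(fmt,
    "DD.MM.YYYY" = format(date, "%d.%m.%Y"),
    "D.M.YYYY" = sprintf("%d.%d.%d", as.integer(format(date, "%d")),
                         as.integer(format(date, "%m")),
                         as.integer(format(date, "%Y"))),
    "DD.MM.YY" = format(date, "%d.%m.%y"),
    "DD/MM/YYYY" = format(date, "%d/%m/%Y"),
    "YYYY-MM-DD" = format(date, "%Y-%m-%d"),
    "DD.MM." = format(date, "%d.%m."),
    "MM/YYYY" = format(date, "%m/%Y"),
    stop("unknown format id: ", fmt))
}

#' Render a single referral sentence with its gold span
#'
#' Instantiates a German template for one referral of class `DATE`, `TODAY`,
#' `YESTERDAY` or `NO_PREVIOUS` (class `MISSING` has no surface form). The
#' returned offsets are 0-based half-open into the sentence and exactly cover
#' the date token or lexicon phrase.
#'
#' @param cls Referral class (not `MISSING`).
#' @param date Calendar date for `DATE` spans (ignored otherwise).
#' @param fmt Format id for `DATE` spans: one of `DD.MM.YYYY`, `D.M.YYYY`,
#'   `DD.MM.YY`, `DD/MM/YYYY`, `YYYY-MM-DD`, `DD.MM.`, `MM/YYYY`.
#' @param modality_mention Modality code to mention in the sentence, or
#'   `NULL`.
#' @param phrase Literal phrase for the non-numeric classes; defaults to the
#'   first lexicon entry of the class.
#' @param template Template index.
#' @return List with `text`, `start`, `end`, `surface`.
#' @export
render_referral_sentence <- function(cls, date = NULL, fmt = "DD.MM.YYYY",
                                     modality_mention = NULL, phrase = NULL,
                                     template = 1L) {
  if (cls == "MISSING") stop("MISSING is document-level and has no sentence")
  mod_txt <- ""
  if (!is.null(modality_mention) && !is.na(modality_mention)) {
    syn <- modality_lexicon()[[modality_mention]]
    if (length(syn)) mod_txt <- paste0("der ", syn[1], " ")
  }
  if (cls == "DATE") {
    if (is.null(date)) stop("DATE spans need a date")
    surface <- .render_date(date, fmt)
    tpl <- .date_templates[((template - 1L) %% length(.date_templates)) + 1L]
    text <- sprintf(tpl, mod_txt, surface)
  } else if (cls %in% c("TODAY", "YESTERDAY")) {
    if (is.null(phrase)) phrase <- referral_phrases()[[cls]][1]
    surface <- phrase
    tpl <- .phrase_templates[((template - 1L) %% length(.phrase_templates)) + 1L]
    text <- sprintf(tpl, mod_txt, surface)
  } else if (cls == "NO_PREVIOUS") {
    if (is.null(phrase)) phrase <- referral_phrases()[[cls]][1]
    surface <- phrase
    text <- paste0(surface, ".")
  } else {
    stop("unknown referral class: ", cls)
  }
  start <- regexpr(surface, text, fixed = TRUE)[[1]] - 1L
  list(text = text, start = start, end = start + nchar(surface),
       surface = surface)
}

.sample1 <- function(x, w = NULL) {
  if (length(x) == 1L) return(x)
  sample(x, 1L, prob = w)
}

#' Generate a synthetic report corpus with gold annotations
#'
#' Produces longitudinal per-patient exam histories; each report is composed
#' of five sections (history, question, protocol, finding, impression) and
#' carries gold annotation spans, gold referral links (with confidence
#' grades) and a gold referencing status. Referenced dates are drawn from
#' the patient's actual prior exams except for a configurable dangling-date
#' fraction, so link-resolution ground truth is exact.
#'
#' @param cfg A [corpus_config()].
#' @return Object of class `report_corpus`: list with `reports`, `spans`,
#'   `links`, `statuses`, `config`.
#' @export
generate_corpus <- function(cfg = corpus_config()) {
  validate_corpus_config(cfg)
  set.seed(cfg$seed)
  phrases <- referral_phrases()
  days_pool <- seq(cfg$date_range[1], cfg$date_range[2], by = "day")
  mix <- cfg$class_mixture[cfg$class_mixture > 0]
  first_mix <- mix[names(mix) %in% c("NO_PREVIOUS", "MISSING")]
  if (!length(first_mix)) {
    first_mix <- c(NO_PREVIOUS = 0.5, MISSING = 0.5)
  }

  rep_cols <- list(report_id = character(0), patient_id = character(0),
                   modality = character(0), body_region = character(0),
                   study_date = character(0), exam_name = character(0),
                   text = character(0), drawn_class = character(0),
                   first_exam = logical(0))
  span_cols <- list(report_id = character(0), start = integer(0),
                    end = integer(0), cls = character(0),
                    surface = character(0), gold_date = character(0),
                    gold_mention = character(0))
  rid_counter <- 0L

  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%05d", p)
    n_exams <- 1L + stats::rgeom(1L, 1 / cfg$exams_per_patient_mean)
    dates <- sort(sample(days_pool, min(n_exams, length(days_pool))))
    n_exams <- length(dates)
    if (n_exams > 1L) {
      for (i in 2:n_exams) {
        if (stats::runif(1) < cfg$p_same_day) dates[i] <- dates[i - 1L]
      }
      dates <- sort(dates)
    }
    pref_regions <- sample(names(.region_weights),
                           size = min(2L, length(.region_weights)),
                           prob = .region_weights)
    modality <- character(n_exams); region <- character(n_exams)
    for (i in seq_len(n_exams)) {
      modality[i] <- .sample1(names(.modality_weights), .modality_weights)
      region[i] <- if (stats::runif(1) < 0.8) .sample1(pref_regions) else
        .sample1(names(.region_weights), .region_weights)
    }
    ids <- sprintf("R%06d", rid_counter + seq_len(n_exams))
    rid_counter <- rid_counter + n_exams

    for (i in seq_len(n_exams)) {
      drawn <- if (i == 1L) {
        .sample1(names(first_mix), first_mix)
      } else {
        .sample1(names(mix), mix)
      }
      cls <- drawn
      if (i == 1L && cls %in% c("DATE", "TODAY", "YESTERDAY")) {
        cls <- .sample1(names(first_mix), first_mix)
      }
      ref_sents <- list()
      add_ref <- function(sent) ref_sents[[length(ref_sents) + 1L]] <<- sent

      make_date_ref <- function() {
        mention <- NA_character_
        if (stats::runif(1) < cfg$p_mention_modality_in_sentence) {
          mention <- "pending"
        }
        dangling <- stats::runif(1) < cfg$p_dangling_date
        priors <- which(dates <= dates[i])
        priors <- priors[priors != i]
        if (dangling || !length(priors)) {
          off <- sample(5:600, 1L)
          tgt_date <- dates[i] - off
          tries <- 0L
          while (tgt_date %in% dates && tries < 20L) {
            tgt_date <- dates[i] - sample(5:600, 1L)
            tries <- tries + 1L
          }
          tgt_mod <- .sample1(names(.modality_weights), .modality_weights)
        } else {
          same_reg <- priors[region[priors] == region[i]]
          pool <- if (length(same_reg) &&
                        stats::runif(1) < cfg$p_same_region) same_reg else priors
          tgt <- if (stats::runif(1) < 0.7) pool[length(pool)] else .sample1(pool)
          tgt_date <- dates[tgt]
          tgt_mod <- modality[tgt]
        }
        if (identical(mention, "pending")) mention <- tgt_mod
        if (stats::runif(1) < cfg$p_day_or_month_omitted) {
          fmt <- "MM/YYYY"
        } else if (stats::runif(1) < cfg$p_year_omitted &&
                     format(tgt_date, "%Y") == format(dates[i], "%Y")) {
          fmt <- "DD.MM."
        } else {
          fmt <- .sample1(names(cfg$date_format_mixture),
                          cfg$date_format_mixture)
        }
        sent <- render_referral_sentence(
          "DATE", date = tgt_date, fmt = fmt,
          modality_mention = if (is.na(mention)) NULL else mention,
          template = sample.int(length(.date_templates), 1L))
        sent$cls <- "DATE"
        sent$gold_date <- if (fmt == "MM/YYYY") NA_character_ else
          as.character(tgt_date)
        sent$gold_mention <- mention
        sent
      }

      if (cls == "DATE") {
        add_ref(make_date_ref())
        n_extra <- stats::rpois(1L, cfg$extra_date_referrals_lambda)
        for (k in seq_len(n_extra)) add_ref(make_date_ref())
      } else if (cls %in% c("TODAY", "YESTERDAY")) {
        noisy <- cfg$p_noise > 0 && stats::runif(1) < cfg$p_noise
        bank <- if (noisy) phrases$noisy[[cls]] else phrases[[cls]]
        mention <- NA_character_
        if (stats::runif(1) < cfg$p_mention_modality_in_sentence) {
          same_day <- which(dates == (if (cls == "TODAY") dates[i] else
            dates[i] - 1L))
          same_day <- same_day[same_day != i]
          mention <- if (length(same_day)) modality[same_day[1]] else
            .sample1(names(.modality_weights), .modality_weights)
        }
        sent <- render_referral_sentence(
          cls, phrase = .sample1(bank),
          modality_mention = if (is.na(mention)) NULL else mention,
          template = sample.int(length(.phrase_templates), 1L))
        sent$cls <- cls
        sent$gold_date <- as.character(
          if (cls == "TODAY") dates[i] else dates[i] - 1L)
        sent$gold_mention <- mention
        add_ref(sent)
      } else if (cls == "NO_PREVIOUS") {
        noisy <- cfg$p_noise > 0 && stats::runif(1) < cfg$p_noise
        bank <- if (noisy) phrases$noisy$NO_PREVIOUS else phrases$NO_PREVIOUS
        sent <- render_referral_sentence("NO_PREVIOUS", phrase = .sample1(bank))
        sent$cls <- "NO_PREVIOUS"
        sent$gold_date <- NA_character_
        sent$gold_mention <- NA_character_
        add_ref(sent)
      }

      # assemble the five sections; referral sentences live in the finding
      # section (first) and impression (extras)
      sec_text <- function(name, n) {
        paste(sample(.filler[[name]], n, replace = n > length(.filler[[name]])),
              collapse = " ")
      }
      befund_refs <- ref_sents
      beurteilung_refs <- list()
      if (length(ref_sents) > 2L) {
        befund_refs <- ref_sents[1:2]
        beurteilung_refs <- ref_sents[-(1:2)]
      }
      parts <- c(
        paste0("Anamnese: ", sec_text("Anamnese", 1L)),
        paste0("Fragestellung: ", sec_text("Fragestellung", 1L)),
        paste0("Untersuchung: ", sec_text("Untersuchung", 1L)),
        paste0("Befund: ",
               paste(c(vapply(befund_refs, `[[`, "", "text"),
                       sample(.filler$Befund, 2L)), collapse = " ")),
        paste0("Beurteilung: ",
               paste(c(vapply(beurteilung_refs, `[[`, "", "text"),
                       sample(.filler$Beurteilung, 1L)), collapse = " "))
      )
      text <- paste(parts, collapse = "\n")

      # recover absolute span offsets from the known relative offsets;
      # a cursor keeps repeated identical sentences at distinct offsets
      cursor <- 0L
      for (sent in c(befund_refs, beurteilung_refs)) {
        rel <- regexpr(sent$text, substr(text, cursor + 1L, nchar(text)),
                       fixed = TRUE)[[1]]
        at <- cursor + rel - 1L
        cursor <- at + nchar(sent$text)
        span_cols$report_id <- c(span_cols$report_id, ids[i])
        span_cols$start <- c(span_cols$start, at + sent$start)
        span_cols$end <- c(span_cols$end, at + sent$end)
        span_cols$cls <- c(span_cols$cls, sent$cls)
        span_cols$surface <- c(span_cols$surface, sent$surface)
        span_cols$gold_date <- c(span_cols$gold_date, sent$gold_date)
        span_cols$gold_mention <- c(span_cols$gold_mention, sent$gold_mention)
      }

      rep_cols$report_id <- c(rep_cols$report_id, ids[i])
      rep_cols$patient_id <- c(rep_cols$patient_id, pid)
      rep_cols$modality <- c(rep_cols$modality, modality[i])
      rep_cols$body_region <- c(rep_cols$body_region, region[i])
      rep_cols$study_date <- c(rep_cols$study_date, as.character(dates[i]))
      rep_cols$exam_name <- c(rep_cols$exam_name,
                              paste0(modality[i], "-", region[i]))
      rep_cols$text <- c(rep_cols$text, text)
      rep_cols$drawn_class <- c(rep_cols$drawn_class, drawn)
      rep_cols$first_exam <- c(rep_cols$first_exam, i == 1L)
    }
  }

  reports <- data.frame(rep_cols[1:7], stringsAsFactors = FALSE)
  reports$study_date <- as.Date(reports$study_date)
  meta <- data.frame(drawn_class = rep_cols$drawn_class,
                     first_exam = rep_cols$first_exam,
                     stringsAsFactors = FALSE)
  spans <- data.frame(span_cols[1:5], stringsAsFactors = FALSE)
  gold_aux <- data.frame(gold_date = span_cols$gold_date,
                         gold_mention = span_cols$gold_mention,
                         stringsAsFactors = FALSE)

  links <- .gold_links(reports, spans, gold_aux)
  statuses <- classify_status(reports, spans)

  corpus <- list(reports = reports, spans = spans, links = links,
                 statuses = statuses, config = cfg,
                 generator_meta = meta)
  class(corpus) <- "report_corpus"
  corpus
}

# Gold links follow the confidence-grading semantics exactly: candidates are
# the patient's exams on the referenced date; criteria are tried in the order
# (1) date+modality+region, (2) date+modality, (3) date+region, (4) date;
# ties break to the lexicographically lowest report_id.
.gold_links <- function(reports, spans, gold_aux) {
  cols <- list(src_report_id = character(0), dst_report_id = character(0),
               reference_class = character(0), extracted_string = character(0),
               confidence = integer(0))
  pat <- stats::setNames(reports$patient_id, reports$report_id)
  reg <- stats::setNames(reports$body_region, reports$report_id)
  for (k in seq_len(nrow(spans))) {
    gd <- gold_aux$gold_date[k]
    if (is.na(gd) || spans$cls[k] == "NO_PREVIOUS") next
    src <- spans$report_id[k]
    cand <- reports[reports$patient_id == pat[[src]] &
                      as.character(reports$study_date) == gd &
                      reports$report_id != src, , drop = FALSE]
    if (!nrow(cand)) next
    mention <- gold_aux$gold_mention[k]
    grades <- list(
      if (!is.na(mention)) cand$modality == mention &
        cand$body_region == reg[[src]] else rep(FALSE, nrow(cand)),
      if (!is.na(mention)) cand$modality == mention else
        rep(FALSE, nrow(cand)),
      cand$body_region == reg[[src]],
      rep(TRUE, nrow(cand)))
    for (g in 1:4) {
      hit <- which(grades[[g]])
      if (length(hit)) {
        dst <- min(cand$report_id[hit])
        cols$src_report_id <- c(cols$src_report_id, src)
        cols$dst_report_id <- c(cols$dst_report_id, dst)
        cols$reference_class <- c(cols$reference_class, spans$cls[k])
        cols$extracted_string <- c(cols$extracted_string, spans$surface[k])
        cols$confidence <- c(cols$confidence, g)
        break
      }
    }
  }
  data.frame(cols, stringsAsFactors = FALSE)
}

#' @export
print.report_corpus <- function(x, ...) {
  cat("Synthetic report corpus\n")
  cat(sprintf("  reports:  %d (%d patients)\n", nrow(x$reports),
              length(unique(x$reports$patient_id))))
  cat(sprintf("  spans:    %d gold annotation spans\n", nrow(x$spans)))
  cat(sprintf("  links:    %d gold referral links\n", nrow(x$links)))
  st <- table(x$statuses$status)
  cat("  statuses:", paste(sprintf("%s=%d", names(st), st), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a corpus to disk
#'
#' Writes `reports.jsonl`, `spans.jsonl`, `links.csv`, `statuses.csv` and
#' `metadata.csv` into a directory.
#'
#' @param corpus A `report_corpus`.
#' @param dir Output directory (created if needed).
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_reports_jsonl(corpus$reports, file.path(dir, "reports.jsonl"))
  write_spans_jsonl(corpus$spans, file.path(dir, "spans.jsonl"))
  utils::write.csv(corpus$links, file.path(dir, "links.csv"),
                   row.names = FALSE)
  utils::write.csv(corpus$statuses, file.path(dir, "statuses.csv"),
                   row.names = FALSE)
  write_metadata_csv(corpus$reports, file.path(dir, "metadata.csv"))
  invisible(dir)
}
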