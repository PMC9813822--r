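test_that("simple two-sentence split yields the expected offsets", {
  s <- split_sentences("Satz eins. Satz zwei.")
  expect_identical(nrow(s), 2L)
  expect_identical(s$start, c(0L, 11L))
  expect_identical(s$text, c("Satz eins.", "Satz zwei."))
})

test_that("empty text splits to nothing", {
  expect_identical(nrow(split_sentences("")), 0L)
})

test_that("sentence boundaries never fall inside date tokens", {
  # twenty date-bearing sentences over the supported formats; the oracle is
  # that the date substring survives inside exactly one sentence and as one
  # token
  dates <- c("12.03.2015", "12.3.15", "12.03.", "12/03/2015", "2015-03-12",
             "1.1.2011", "31.12.99", "05.11.", "09/2019", "28.02.2020")
  lead <- c("Vergleich mit CT vom %s und stabiler Befund.",
            "Verlaufskontrolle vom %s bei bekannter Laesion.")
  n_checked <- 0L
  for (d in dates) {
    for (tpl in lead) {
      txt <- paste(sprintf(tpl, d), "Kein Infiltrat.")
      sents <- split_sentences(txt)
      hits <- vapply(seq_len(nrow(sents)), function(i) {
        grepl(d, sents$text[i], fixed = TRUE)
      }, TRUE)
      expect_identical(sum(hits), 1L, info = paste(d, tpl))
      toks <- tokenize(sents$text[which(hits)])
      expect_true(d %in% toks$token, info = d)
      n_checked <- n_checked + 1L
    }
  }
  expect_identical(n_checked, 20L)
})

test_that("abbreviations and lowercase continuations do not split", {
  s <- split_sentences("Vergleich z.B. mit CT. Danach weiter.")
  expect_identical(nrow(s), 2L)
  s2 <- split_sentences("Kontrolle vom 12.03. bei Beschwerden. Sonst frei.")
  expect_identical(nrow(s2), 2L)
  expect_match(s2$text[1], "12\\.03\\. bei")
})

test_that("sentence offsets reconstruct the original report text", {
  cx <- small_corpus()
  for (i in seq_len(10)) {
    txt <- cx$reports$text[i]
    s <- split_sentences(txt)
    for (j in seq_len(nrow(s))) {
      expect_identical(substr(txt, s$start[j] + 1, s$end[j]), s$text[j])
    }
    # nothing but whitespace may fall between sentences
    gaps <- substring(txt, c(1, s$end + 1), c(s$start, nchar(txt)))
    expect_true(all(grepl("^[ \t\n]*$", gaps)))
  }
})

test_that("spans project onto tokens as IOB2 and invert exactly", {
  r <- make_reports("R1", text = "CT vom 12.03.2015.")
  toks <- report_tokens(r)
  expect_identical(toks$token, c("CT", "vom", "12.03.2015", "."))
  sp <- data.frame(report_id = "R1", start = 7L, end = 17L, cls = "DATE",
                   surface = "12.03.2015", stringsAsFactors = FALSE)
  tagged <- spans_to_iob2(toks, sp)
  expect_identical(tagged$tag, c("O", "O", "B-DATE", "O"))

  r2 <- make_reports("R2", text = "Keine Voraufnahmen vorhanden.")
  sp2 <- data.frame(report_id = "R2", start = 0L, end = 28L,
                    cls = "NO_PREVIOUS",
                    surface = "Keine Voraufnahmen vorhanden",
                    stringsAsFactors = FALSE)
  tg2 <- spans_to_iob2(report_tokens(r2), sp2)
  expect_identical(tg2$tag,
                   c("B-NO_PREVIOUS", "I-NO_PREVIOUS", "I-NO_PREVIOUS", "O"))

  # no spans -> all O
  expect_true(all(spans_to_iob2(toks, sp[0, ])$tag == "O"))

  back <- iob2_to_spans(tagged, stats::setNames(r$text, r$report_id))
  expect_identical(back$start, sp$start)
  expect_identical(back$end, sp$end)
  expect_identical(back$surface, sp$surface)
})

test_that("adjacent B- tags decode as adjacent single-token spans", {
  toks <- data.frame(report_id = "R1", sent_id = 1L,
                     token = c("12.03.2015", "14.04.2016"),
                     start = c(0L, 11L), end = c(10L, 21L),
                     tag = c("B-DATE", "B-DATE"), stringsAsFactors = FALSE)
  sp <- iob2_to_spans(toks)
  expect_identical(nrow(sp), 2L)
  expect_identical(sp$start, c(0L, 11L))
  # all-O decodes to nothing
  toks$tag <- "O"
  expect_identical(nrow(iob2_to_spans(toks)), 0L)
})

test_that("span/IOB2 round-trip is the identity on generated corpora", {
  cx <- small_corpus()
  toks <- spans_to_iob2(report_tokens(cx$reports), cx$spans)
  back <- iob2_to_spans(toks, stats::setNames(cx$reports$text,
                                              cx$reports$report_id))
  expect_setequal(span_keys(back), span_keys(cx$spans))
  expect_identical(nrow(back), nrow(cx$spans))
  # surfaces are reconstructed exactly
  ord_b <- order(back$report_id, back$start)
  ord_g <- order(cx$spans$report_id, cx$spans$start)
  expect_identical(back$surface[ord_b], cx$spans$surface[ord_g])
})

test_that("spans crossing sentences or overlapping raise errors", {
  r <- make_reports("R1", text = "Satz eins. Satz zwei.")
  toks <- report_tokens(r)
  crossing <- data.frame(report_id = "R1", start = 5L, end = 15L,
                         cls = "DATE", surface = "eins. Satz",
                         stringsAsFactors = FALSE)
  expect_error(spans_to_iob2(toks, crossing), "sentence boundary")
  overlapping <- data.frame(report_id = "R1", start = c(0L, 5L),
                            end = c(9L, 9L), cls = "DATE",
                            surface = c("Satz eins", "eins"),
                            stringsAsFactors = FALSE)
  expect_error(spans_to_iob2(toks, overlapping), "verlap")
})

test_that("IOB2 repair removes orphan runs and keeps valid entities", {
  fx <- filter_invalid_iob2(c("O", "I-DATE", "O"))
  expect_identical(fx$tags, c("O", "O", "O"))
  expect_identical(fx$n_removed, 1L)

  fx2 <- filter_invalid_iob2(c("B-DATE", "I-TODAY"))
  expect_identical(fx2$tags, c("B-DATE", "O"))
  expect_identical(fx2$n_removed, 1L)
  # the surviving entity set matches the IOB2 entity-extraction convention:
  # one single-token DATE entity, the orphan I-TODAY run gone
  toks <- data.frame(report_id = "R", sent_id = 1L, token = c("a", "b"),
                     start = c(0L, 2L), end = c(1L, 3L), tag = fx2$tags,
                     stringsAsFactors = FALSE)
  ent <- iob2_to_spans(toks)
  expect_identical(ent$cls, "DATE")
  expect_identical(nrow(ent), 1L)

  valid <- c("B-DATE", "I-DATE", "O", "B-TODAY")
  fx3 <- filter_invalid_iob2(valid)
  expect_identical(fx3$tags, valid)
  expect_identical(fx3$n_removed, 0L)

  # consecutive orphan I runs of one class count once; class switch counts
  # again
  fx4 <- filter_invalid_iob2(c("I-DATE", "I-DATE", "I-TODAY"))
  expect_identical(fx4$tags, c("O", "O", "O"))
  expect_identical(fx4$n_removed, 2L)
})

test_that("IOB2 repair is idempotent on randomly corrupted sequences", {
  set.seed(41)
  tags_pool <- c("O", "B-DATE", "I-DATE", "B-TODAY", "I-TODAY",
                 "B-NO_PREVIOUS", "I-NO_PREVIOUS")
  for (k in seq_len(200)) {
    tg <- sample(tags_pool, sample(1:12, 1), replace = TRUE)
    once <- filter_invalid_iob2(tg)
    twice <- filter_invalid_iob2(once$tags)
    expect_identical(twice$tags, once$tags)
    expect_identical(twice$n_removed, 0L)
  }
})

test_that("CoNLL files round-trip tokens and tags", {
  cx <- small_corpus()
  toks <- spans_to_iob2(report_tokens(cx$reports[1:5, ]),
                        cx$spans[cx$spans$report_id %in%
                                   cx$reports$report_id[1:5], ])
  p <- withr::local_tempfile(fileext = ".conll")
  write_conll(toks, p)
  back <- read_conll(p)
  expect_identical(back$token, toks$token)
  expect_identical(back$tag, toks$tag)
  expect_identical(back$report_id, toks$report_id)
})
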