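two_chain_fixture <- function() {
  reports <- make_reports(
    sprintf("R%d", 1:5), patient = "P1",
    dates = c("2015-01-01", "2015-03-01", "2015-06-01", "2016-01-01",
              "2016-03-01"))
  links <- data.frame(
    src_report_id = c("R2", "R5"), dst_report_id = c("R1", "R4"),
    reference_class = "DATE", extracted_string = "x",
    confidence = 1L, stringsAsFactors = FALSE)
  build_report_graph(reports, links)
}

test_that("related component returns the whole linked chain from any node", {
  g <- two_chain_fixture()
  # chain R2 -> R1 queried from either end
  expect_setequal(related_component(g, "R1")$reports$report_id,
                  c("R1", "R2"))
  expect_setequal(related_component(g, "R2")$reports$report_id,
                  c("R1", "R2"))
  # isolated node
  expect_identical(related_component(g, "R3")$reports$report_id, "R3")
  # the second chain of the same patient stays separate
  expect_setequal(related_component(g, "R5")$reports$report_id,
                  c("R4", "R5"))
  expect_error(related_component(g, "R99"), "unknown report")
})

test_that("the component view is invariant to the seed node", {
  cx <- small_corpus()
  g <- build_report_graph(cx$reports, cx$links)
  comp <- igraph::components(g$ig, mode = "weak")$membership
  for (cid in unique(comp)) {
    ids <- names(comp)[comp == cid]
    views <- lapply(ids, function(id) {
      sort(related_component(g, id)$reports$report_id)
    })
    expect_identical(length(unique(views)), 1L, info = paste("comp", cid))
  }
})

seq_fixture <- function() {
  reports <- rbind(
    make_reports("CT1", patient = "P1", modality = "CT", region = "head",
                 dates = "2018-01-10",
                 text = "Befund: Unauffaellig."),
    make_reports("MR1", patient = "P1", modality = "MR", region = "head",
                 dates = "2018-01-12",
                 text = "Beurteilung: Subakuter Infarkt links."),
    make_reports("MR2", patient = "P1", modality = "MR", region = "head",
                 dates = "2018-03-01",
                 text = "Beurteilung: Kein Infarkt."),
    make_reports("CT2", patient = "P2", modality = "CT", region = "head",
                 dates = "2018-01-01", text = "Befund: Infarkt."))
  links <- data.frame(
    src_report_id = "MR1", dst_report_id = "CT1",
    reference_class = "DATE", extracted_string = "10.01.2018",
    confidence = 1L, stringsAsFactors = FALSE)
  build_report_graph(reports, links)
}

test_that("sequence selection finds the referenced head CT/MR pair", {
  g <- seq_fixture()
  pat <- sequence_pattern(
    steps = list(list(modality = "CT", body_region = "head"),
                 list(modality = "MR", body_region = "head",
                      keyword = "infarkt")),
    max_gap_days = 3, require_edge = TRUE)
  res <- select_sequences(g, pat)
  expect_identical(res, list(c("CT1", "MR1")))

  # a zero-day gap bound excludes the 2-day pair
  pat0 <- sequence_pattern(pat$steps, max_gap_days = 0, require_edge = TRUE)
  expect_identical(select_sequences(g, pat0), list())

  # dropping the edge requirement can only widen the result set
  pat_free <- sequence_pattern(pat$steps, max_gap_days = 60,
                               require_edge = FALSE)
  free <- select_sequences(g, pat_free)
  pat_edge <- sequence_pattern(pat$steps, max_gap_days = 60,
                               require_edge = TRUE)
  edge <- select_sequences(g, pat_edge)
  expect_true(all(vapply(edge, paste, "", collapse = ",") %in%
                    vapply(free, paste, "", collapse = ",")))
  expect_gte(length(free), length(edge))
})

test_that("sequence patterns validate their arguments", {
  expect_error(sequence_pattern(list()), "at least one step")
  expect_error(sequence_pattern(list(list()), max_gap_days = -1),
               "nonnegative")
})

missing_fixture <- function(extra_links = NULL) {
  reports <- make_reports(
    sprintf("R%d", 1:6), patient = "P1", modality = "CT", region = "thorax",
    dates = c("2018-01-01", "2018-01-31", "2018-03-01", "2018-04-01",
              "2018-05-01", "2018-06-01"))
  links <- data.frame(
    src_report_id = c("R3", "R5"), dst_report_id = c("R2", "R4"),
    reference_class = "DATE", extracted_string = "x", confidence = 1L,
    stringsAsFactors = FALSE)
  if (!is.null(extra_links)) links <- rbind(links, extra_links)
  build_report_graph(reports, links)
}

test_that("missing-comparison detection flags skipped pairs only", {
  g <- missing_fixture()
  res <- detect_missing_links(g, max_gap_days = 45)
  # R2 never references R1 (30 days apart, same modality+region) -> flagged
  expect_true(any(res$earlier_id == "R1" & res$later_id == "R2"))
  # R3 references R2 -> the (R2, R3) pair is not flagged
  expect_false(any(res$earlier_id == "R2" & res$later_id == "R3"))
  # R5 references R4 (dated after R3): pair (R4, R5) linked, not flagged;
  # pair (R3, R4): R4 references nothing -> flagged
  expect_true(any(res$earlier_id == "R3" & res$later_id == "R4"))
  # R6 references nothing -> (R5, R6) flagged
  expect_true(any(res$earlier_id == "R5" & res$later_id == "R6"))

  # a grade-4 link still counts as a reference
  g2 <- missing_fixture(data.frame(
    src_report_id = "R2", dst_report_id = "R1", reference_class = "DATE",
    extracted_string = "x", confidence = 4L, stringsAsFactors = FALSE))
  res2 <- detect_missing_links(g2, max_gap_days = 45)
  expect_false(any(res2$earlier_id == "R1" & res2$later_id == "R2"))
})

test_that("a reference to a later exam supersedes the skipped pair", {
  # brute-force scenario: R6 references R5; the (R3, R6) pair (within gap)
  # must not be flagged because R5 is on/after R3
  g <- missing_fixture(data.frame(
    src_report_id = "R6", dst_report_id = "R5", reference_class = "DATE",
    extracted_string = "x", confidence = 1L, stringsAsFactors = FALSE))
  res <- detect_missing_links(g, max_gap_days = 120)
  expect_false(any(res$earlier_id == "R3" & res$later_id == "R6"))
  # with the supersession clause disabled the pair is flagged
  res_all <- detect_missing_links(g, max_gap_days = 120,
                                  require_superseded = FALSE)
  expect_true(any(res_all$earlier_id == "R3" & res_all$later_id == "R6"))
})

test_that("repairing a flagged pair removes exactly that flag", {
  g <- missing_fixture()
  res <- detect_missing_links(g, max_gap_days = 45)
  expect_true(any(res$earlier_id == "R1" & res$later_id == "R2"))
  repaired <- rbind(g$links, data.frame(
    src_report_id = "R2", dst_report_id = "R1", reference_class = "DATE",
    extracted_string = "repair", confidence = 4L, stringsAsFactors = FALSE))
  g2 <- build_report_graph(g$reports, repaired)
  res2 <- detect_missing_links(g2, max_gap_days = 45)
  expect_false(any(res2$later_id == "R2"))
  gone <- setdiff(paste(res$earlier_id, res$later_id),
                  paste(res2$earlier_id, res2$later_id))
  expect_identical(gone, "R1 R2")
  expect_identical(setdiff(paste(res2$earlier_id, res2$later_id),
                           paste(res$earlier_id, res$later_id)),
                   character(0))
})

test_that("reasons distinguish silent and stated missing references", {
  g <- missing_fixture()
  statuses <- data.frame(report_id = sprintf("R%d", 1:6),
                         status = c("MISSING", "NO_PREVIOUS", "REFERENCED",
                                    "MISSING", "REFERENCED", "MISSING"),
                         stringsAsFactors = FALSE)
  res <- detect_missing_links(g, max_gap_days = 45, statuses = statuses)
  expect_identical(res$reason[res$later_id == "R2"], "no_previous_stated")
  expect_identical(res$reason[res$later_id == "R4"], "missing")
})

test_that("the referral matrix counts edges by group", {
  reports <- rbind(make_reports(c("M1", "M2"), patient = "P1",
                                modality = "MG", region = "breast",
                                dates = c("2015-01-01", "2016-01-01")))
  links <- data.frame(src_report_id = "M2", dst_report_id = "M1",
                      reference_class = "DATE", extracted_string = "x",
                      confidence = 1L, stringsAsFactors = FALSE)
  g <- build_report_graph(reports, links)
  m <- referral_matrix(g, "modality")
  expect_identical(m["MG", "MG"], 1L)
  expect_identical(sum(m), 1L)

  # empty graph -> zero matrix
  g0 <- build_report_graph(reports, links[0, ])
  expect_identical(sum(referral_matrix(g0, "modality")), 0L)

  # an 8-day-gap edge is excluded by a 7-day window
  r2 <- make_reports(c("A1", "A2"), patient = "P2",
                     dates = c("2015-01-01", "2015-01-09"))
  l2 <- data.frame(src_report_id = "A2", dst_report_id = "A1",
                   reference_class = "DATE", extracted_string = "x",
                   confidence = 1L, stringsAsFactors = FALSE)
  gw <- build_report_graph(r2, l2)
  expect_identical(sum(referral_matrix(gw, "modality", window_days = 7)), 0L)
  expect_identical(sum(referral_matrix(gw, "modality", window_days = 8)), 1L)
})

test_that("matrix totals and row sums match edge counts", {
  cx <- small_corpus()
  g <- build_report_graph(cx$reports, cx$links)
  m <- referral_matrix(g, "modality")
  expect_identical(sum(m), nrow(cx$links))
  out_counts <- table(factor(
    cx$reports$modality[match(cx$links$src_report_id,
                              cx$reports$report_id)],
    levels = rownames(m)))
  expect_identical(unname(rowSums(m)), as.numeric(out_counts))
  mr <- referral_matrix(g, "body_region")
  expect_identical(sum(mr), nrow(cx$links))
})
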