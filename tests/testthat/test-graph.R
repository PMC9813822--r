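chain_fixture <- function() {
  reports <- make_reports(c("R1", "R2", "R3"),
                          dates = c("2015-01-01", "2015-06-01", "2016-01-01"))
  links <- data.frame(
    src_report_id = c("R3", "R2"), dst_report_id = c("R2", "R1"),
    reference_class = "DATE", extracted_string = c("01.06.2015",
                                                   "01.01.2015"),
    confidence = c(1L, 3L), stringsAsFactors = FALSE)
  list(reports = reports, links = links)
}

test_that("graph construction preserves counts and validates endpoints", {
  fx <- chain_fixture()
  g <- build_report_graph(fx$reports, fx$links)
  expect_identical(as.integer(igraph::vcount(g$ig)), 3L)
  expect_identical(as.integer(igraph::ecount(g$ig)), 2L)
  # a 2-link chain is a path: every vertex reachable from R3
  expect_identical(length(igraph::subcomponent(g$ig, "R3", mode = "out")), 3L)

  g0 <- build_report_graph(fx$reports, fx$links[0, ])
  expect_identical(as.integer(igraph::ecount(g0$ig)), 0L)
  expect_identical(as.integer(igraph::vcount(g0$ig)), 3L)

  bad <- fx$links
  bad$dst_report_id[2] <- "R99"
  expect_error(build_report_graph(fx$reports, bad), "rows: 2")
})

test_that("time-forward edges and self-loops are rejected", {
  fx <- chain_fixture()
  fwd <- fx$links
  fwd$src_report_id[1] <- "R1"; fwd$dst_report_id[1] <- "R3"
  expect_error(build_report_graph(fx$reports, fwd), "backward in time")
  loop <- fx$links
  loop$dst_report_id[1] <- "R3"
  expect_error(build_report_graph(fx$reports, loop), "elf-loop")
})

test_that("per-patient subgraphs are acyclic", {
  cx <- small_corpus()
  g <- build_report_graph(cx$reports, cx$links)
  expect_true(igraph::is_dag(igraph::simplify(g$ig)))
})

test_that("the CSV pair round-trips the graph losslessly", {
  cx <- small_corpus()
  g <- build_report_graph(cx$reports, cx$links)
  d <- withr::local_tempdir()
  export_graph(g, d, format = "csv")
  g2 <- import_report_graph_csv(file.path(d, "nodes.csv"),
                                file.path(d, "edges.csv"))
  expect_identical(g2$reports$report_id, g$reports$report_id)
  expect_identical(g2$reports$text, g$reports$text)
  expect_identical(g2$reports$study_date, g$reports$study_date)
  expect_identical(g2$links, g$links)
  expect_identical(igraph::ecount(g2$ig), igraph::ecount(g$ig))
})

test_that("GraphML export validates and round-trips through igraph", {
  cx <- small_corpus()
  g <- build_report_graph(cx$reports, cx$links)
  p <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, p, format = "graphml")
  doc <- xml2::read_xml(p)
  expect_identical(xml2::xml_name(doc), "graphml")
  expect_match(unname(xml2::xml_ns(doc)[[1]]),
               "graphml.graphdrawing.org", fixed = TRUE)
  g2 <- igraph::read_graph(p, format = "graphml")
  expect_identical(igraph::vcount(g2), igraph::vcount(g$ig))
  expect_identical(igraph::ecount(g2), igraph::ecount(g$ig))
  expect_setequal(igraph::V(g2)$name, g$reports$report_id)
  expect_identical(sort(as.integer(igraph::E(g2)$confidence)),
                   sort(g$links$confidence))

  # an empty graph still yields valid GraphML
  g0 <- build_report_graph(cx$reports[0, ], cx$links[0, ])
  p0 <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g0, p0, format = "graphml")
  expect_identical(xml2::xml_name(xml2::read_xml(p0)), "graphml")
})

test_that("the Cypher script has one CREATE per node and edge", {
  fx <- chain_fixture()
  g <- build_report_graph(fx$reports[1:2, ], fx$links[2, ])
  p <- withr::local_tempfile(fileext = ".cypher")
  export_graph(g, p, format = "cypher")
  lines <- readLines(p, encoding = "UTF-8")
  expect_identical(sum(grepl("^CREATE ", lines)), 3L)
  expect_identical(sum(grepl("REFERS_TO", lines)), 1L)
  expect_match(lines[grepl("REFERS_TO", lines)],
               "reference_class:'DATE'.*confidence:3")
})

test_that("round-trips hold on randomized corpora", {
  for (seed in c(5, 17)) {
    cx <- generate_corpus(corpus_config(n_patients = 15, seed = seed))
    g <- build_report_graph(cx$reports, cx$links)
    d <- withr::local_tempdir()
    export_graph(g, d, format = "csv")
    g2 <- import_report_graph_csv(file.path(d, "nodes.csv"),
                                  file.path(d, "edges.csv"))
    expect_identical(g2$links, g$links)
    expect_identical(g2$reports$study_date, g$reports$study_date)
  }
})

test_that("derived links reproduce the gold graph's connectivity", {
  cx <- small_corpus()
  rs <- resolve_spans(cx$spans[cx$spans$cls %in%
                                 c("DATE", "TODAY", "YESTERDAY"), ],
                      cx$reports)
  lk <- build_links(rs, cx$reports)
  g_gold <- build_report_graph(cx$reports, cx$links)
  g_pred <- build_report_graph(cx$reports, lk)
  comp_g <- igraph::components(g_gold$ig, mode = "weak")$membership
  comp_p <- igraph::components(g_pred$ig, mode = "weak")$membership
  # identical partitions: same pairs grouped together
  split_g <- split(names(comp_g), comp_g)
  split_p <- split(names(comp_p), comp_p)
  norm <- function(s) sort(vapply(s, function(x) paste(sort(x),
                                                       collapse = ","), ""))
  expect_identical(norm(split_g), norm(split_p))
})
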