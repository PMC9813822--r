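# End-to-end composition: generate -> train -> predict -> normalize -> link
# -> graph -> statistics, with structured stage counts.

#' Run the full extraction pipeline on a synthetic corpus
#'
#' Generates a corpus, trains the tagger on a report-level training split,
#' applies it to every report, normalizes and links the predicted referrals,
#' builds the report graph and computes the referencing statistics. The
#' returned `log` records the counts at each stage (reports in, spans
#' predicted, entities discarded by the IOB2 filter, dates discarded by the
#' normalization rules, links discarded, edges created); every report
#' appears in exactly one status row.
#'
#' @param cfg A [corpus_config()].
#' @param tcfg A [train_config()].
#' @param train_fraction Fraction of reports used for training (the tagger
#'   is applied to all reports afterwards).
#' @param strict_year Passed to [resolve_spans()].
#' @param outdir Optional directory; when given, all intermediate artifacts
#'   are written (`reports.jsonl`, predicted `spans.jsonl`, `tagged.conll`,
#'   `resolved.csv`, `links.csv`, `nodes.csv`/`edges.csv`, `graph.graphml`,
#'   `graph.cypher`, `statuses.csv`, `status_summary.csv`,
#'   `intervals_modality.csv`, `referral_matrix_modality.csv`).
#' @param verbose Print stage progress.
#' @return List with `corpus`, `tagger`, `pred_spans`, `resolved`, `links`,
#'   `graph`, `statuses`, `stats` and `log`.
#' @export
run_pipeline <- function(cfg = corpus_config(), tcfg = train_config(),
                         train_fraction = 0.7, strict_year = FALSE,
                         outdir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("generating corpus (seed %d)", cfg$seed)
  corpus <- generate_corpus(cfg)
  reports <- corpus$reports

  set.seed(tcfg$seed)
  n_train <- max(2L, round(train_fraction * nrow(reports)))
  train_ids <- sample(reports$report_id, n_train)
  say("training tagger on %d reports", n_train)
  fit <- train_tagger(reports[reports$report_id %in% train_ids, ,
                              drop = FALSE],
                      corpus$spans[corpus$spans$report_id %in% train_ids, ,
                                   drop = FALSE],
                      tcfg)
  say("predicting on %d reports", nrow(reports))
  pred <- predict(fit, reports)
  n_removed <- attr(pred, "n_removed")

  say("normalizing %d spans", nrow(pred))
  datable <- pred[pred$cls %in% c("DATE", "TODAY", "YESTERDAY"), ,
                  drop = FALSE]
  resolved <- resolve_spans(datable, reports, strict_year = strict_year)
  n_discarded_dates <- sum(is.na(resolved$resolved))

  say("linking")
  links <- build_links(resolved, reports)
  n_resolvable <- sum(!is.na(resolved$resolved))
  n_links_discarded <- n_resolvable - nrow(links)

  g <- build_report_graph(reports, links)
  statuses <- classify_status(reports, pred)
  stats <- list(
    status = status_summary(statuses),
    status_by_modality = status_summary(statuses, reports, "modality"),
    status_by_region = status_summary(statuses, reports, "body_region"),
    status_by_year = status_summary(statuses, reports, "year"),
    intervals_modality = interval_summary(links, reports, "modality"),
    intervals_region = interval_summary(links, reports, "body_region"),
    matrix_modality = referral_matrix(g, "modality"))

  log <- list(
    reports_in = nrow(reports),
    train_reports = n_train,
    spans_predicted = nrow(pred),
    entities_removed_iob2 = n_removed,
    spans_datable = nrow(datable),
    dates_discarded = n_discarded_dates,
    dates_resolved = n_resolvable,
    links_discarded = n_links_discarded,
    edges_created = nrow(links),
    statuses = nrow(statuses))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_reports_jsonl(reports, file.path(outdir, "reports.jsonl"))
    write_spans_jsonl(pred, file.path(outdir, "spans.jsonl"))
    write_conll(predict(fit, reports, type = "tokens"),
                file.path(outdir, "tagged.conll"))
    write_resolved_csv(resolved, file.path(outdir, "resolved.csv"))
    utils::write.csv(links, file.path(outdir, "links.csv"),
                     row.names = FALSE)
    export_graph(g, outdir, format = "csv")
    export_graph(g, file.path(outdir, "graph.graphml"), format = "graphml")
    export_graph(g, file.path(outdir, "graph.cypher"), format = "cypher")
    utils::write.csv(statuses, file.path(outdir, "statuses.csv"),
                     row.names = FALSE)
    utils::write.csv(stats$status, file.path(outdir, "status_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(stats$intervals_modality,
                     file.path(outdir, "intervals_modality.csv"),
                     row.names = FALSE)
    utils::write.csv(stats$matrix_modality,
                     file.path(outdir, "referral_matrix_modality.csv"))
    writeLines(jsonlite::toJSON(log, auto_unbox = TRUE, pretty = TRUE),
               file.path(outdir, "log.json"))
  }

  list(corpus = corpus, tagger = fit, pred_spans = pred, resolved = resolved,
       links = links, graph = g, statuses = statuses, stats = stats,
       log = log)
}
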