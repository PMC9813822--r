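# Directed report graph: construction, persistence and export. The graph
# container is an igraph directed multigraph; reports are vertices with
# their metadata, referral links are edges carrying the reference class, the
# extracted string and the confidence grade.

#' Build the directed report graph
#'
#' Vertices are reports with their metadata; edges run from the referencing
#' report to the referenced report (backward in time). Parallel edges are
#' allowed (several spans may reference the same prior exam); self-loops and
#' edges pointing forward in time violate the graph invariants and raise an
#' error, as do links with endpoints not present in `reports`.
#'
#' @param reports Report table.
#' @param links Link table (`src_report_id`, `dst_report_id`,
#'   `reference_class`, `extracted_string`, `confidence`).
#' @return Object of class `report_graph` with elements `ig` (igraph),
#'   `reports`, `links`.
#' @export
build_report_graph <- function(reports, links) {
  bad_src <- which(!links$src_report_id %in% reports$report_id)
  bad_dst <- which(!links$dst_report_id %in% reports$report_id)
  if (length(bad_src) || length(bad_dst)) {
    stop("links reference unknown reports at rows: ",
         paste(sort(unique(c(bad_src, bad_dst))), collapse = ", "))
  }
  if (nrow(links)) {
    dates <- as.Date(stats::setNames(as.character(reports$study_date),
                                     reports$report_id))
    fwd <- which(dates[links$src_report_id] < dates[links$dst_report_id])
    if (length(fwd)) {
      stop("edges must point backward in time; offending rows: ",
           paste(fwd, collapse = ", "))
    }
    loops <- which(links$src_report_id == links$dst_report_id)
    if (length(loops)) {
      stop("self-loops are forbidden; offending rows: ",
           paste(loops, collapse = ", "))
    }
  }
  vertices <- data.frame(
    name = reports$report_id,
    patient_id = reports$patient_id,
    modality = reports$modality,
    body_region = reports$body_region,
    study_date = as.character(reports$study_date),
    exam_name = reports$exam_name,
    stringsAsFactors = FALSE)
  edges <- if (nrow(links)) {
    data.frame(from = links$src_report_id, to = links$dst_report_id,
               reference_class = links$reference_class,
               extracted_string = links$extracted_string,
               confidence = as.integer(links$confidence),
               stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), to = character(0),
               reference_class = character(0), extracted_string = character(0),
               confidence = integer(0), stringsAsFactors = FALSE)
  }
  ig <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                      vertices = vertices)
  structure(list(ig = ig, reports = reports, links = links),
            class = "report_graph")
}

#' @export
print.report_graph <- function(x, ...) {
  cat("Directed report graph\n")
  cat(sprintf("  nodes: %d reports (%d patients)\n",
              igraph::vcount(x$ig), length(unique(x$reports$patient_id))))
  cat(sprintf("  edges: %d referral links\n", igraph::ecount(x$ig)))
  if (nrow(x$links)) {
    conf <- table(x$links$confidence)
    cat("  confidence:", paste(sprintf("grade %s=%d", names(conf), conf),
                               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export a report graph
#'
#' Formats: `"graphml"` (standard GraphML via igraph), `"csv"` (a
#' `nodes.csv`/`edges.csv` pair that round-trips losslessly through
#' [import_report_graph_csv()]), or `"cypher"` (a UTF-8 script with one
#' `CREATE` statement per node and per edge, carrying the three edge
#' properties).
#'
#' @param g A `report_graph`.
#' @param path Output file path (for `csv`: a directory).
#' @param format One of `"graphml"`, `"csv"`, `"cypher"`.
#' @return The written path(s), invisibly.
#' @export
export_graph <- function(g, path, format = c("graphml", "csv", "cypher")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(g$ig, path, format = "graphml")
    return(invisible(path))
  }
  if (format == "csv") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    nodes <- g$reports
    nodes$study_date <- as.character(nodes$study_date)
    np <- file.path(path, "nodes.csv")
    ep <- file.path(path, "edges.csv")
    utils::write.csv(nodes, np, row.names = FALSE)
    utils::write.csv(g$links, ep, row.names = FALSE)
    return(invisible(c(np, ep)))
  }
  # cypher
  esc <- function(s) gsub("'", "\\\\'", gsub("\\\\", "\\\\\\\\", s))
  var <- stats::setNames(sprintf("n%d", seq_len(nrow(g$reports))),
                         g$reports$report_id)
  lines <- character(0)
  for (i in seq_len(nrow(g$reports))) {
    r <- g$reports[i, ]
    lines <- c(lines, sprintf(
      paste0("CREATE (%s:Report {report_id:'%s', patient_id:'%s', ",
             "modality:'%s', body_region:'%s', study_date:'%s', ",
             "exam_name:'%s'})"),
      var[[r$report_id]], esc(r$report_id), esc(r$patient_id),
      esc(r$modality), esc(r$body_region), as.character(r$study_date),
      esc(r$exam_name)))
  }
  for (i in seq_len(nrow(g$links))) {
    l <- g$links[i, ]
    lines <- c(lines, sprintf(
      paste0("CREATE (%s)-[:REFERS_TO {reference_class:'%s', ",
             "extracted_string:'%s', confidence:%d}]->(%s)"),
      var[[l$src_report_id]], esc(l$reference_class),
      esc(l$extracted_string), as.integer(l$confidence),
      var[[l$dst_report_id]]))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Import a report graph from a nodes/edges CSV pair
#'
#' @param nodes_path,edges_path Files written by
#'   [export_graph()] with `format = "csv"`. `nodes_path` must include a
#'   `text` column when the export did (the default export writes the full
#'   report table).
#' @return A `report_graph`.
#' @export
import_report_graph_csv <- function(nodes_path, edges_path) {
  reports <- utils::read.csv(nodes_path, stringsAsFactors = FALSE,
                             colClasses = "character", encoding = "UTF-8")
  reports$study_date <- as.Date(reports$study_date)
  links <- utils::read.csv(edges_path, stringsAsFactors = FALSE,
                           encoding = "UTF-8")
  if (nrow(links)) links$confidence <- as.integer(links$confidence)
  build_report_graph(reports, links)
}
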