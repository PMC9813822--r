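# Entity-level evaluation: exact-span, exact-class matching with per-class
# and micro/macro/weighted precision, recall and F1.

.f1 <- function(p, r) if (p + r > 0) 2 * p * r / (p + r) else 0

#' Entity-level NER evaluation
#'
#' An entity counts as a true positive only when report, character offsets
#' and class all match exactly. Precision with an empty prediction set is
#' reported as 0 (documented convention), as is recall with empty gold.
#' Macro and weighted averages run over classes with nonzero gold support;
#' the micro average pools TP/FP/FN over all classes. Symmetric in document
#' order.
#'
#' @param pred,gold Span tables (`report_id`, `start`, `end`, `cls`).
#' @return Object of class `ner_eval`: list with `by_class` (data frame),
#'   `micro`, `macro`, `weighted` (named vectors with `precision`,
#'   `recall`, `f1`), and `support`.
#' @section Errors: raises when `gold` contains no entities (zero support
#'   makes every metric undefined).
#' @export
ner_evaluate <- function(pred, gold) {
  if (!nrow(gold)) {
    stop("gold has zero entities: metrics are undefined at zero support")
  }
  keyify <- function(x) paste(x$report_id, x$start, x$end, x$cls, sep = "\r")
  pk <- keyify(pred); gk <- keyify(gold)
  if (anyDuplicated(gk)) gk <- unique(gk)
  if (anyDuplicated(pk)) pk <- unique(pk)
  classes <- sort(unique(c(gold$cls, pred$cls)))
  rows <- list(); tp_all <- 0L; fp_all <- 0L; fn_all <- 0L
  cls_of <- function(keys) vapply(strsplit(keys, "\r", fixed = TRUE),
                                  function(z) z[[4]], "")
  pc <- cls_of(pk); gc_ <- cls_of(gk)
  for (cl in classes) {
    p_cl <- pk[pc == cl]; g_cl <- gk[gc_ == cl]
    tp <- length(intersect(p_cl, g_cl))
    fp <- length(setdiff(p_cl, g_cl))
    fn <- length(setdiff(g_cl, p_cl))
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    rows[[cl]] <- data.frame(class = cl, precision = prec, recall = rec,
                             f1 = .f1(prec, rec), support = length(g_cl),
                             stringsAsFactors = FALSE)
    tp_all <- tp_all + tp; fp_all <- fp_all + fp; fn_all <- fn_all + fn
  }
  by_class <- do.call(rbind, rows)
  rownames(by_class) <- NULL
  micro_p <- if (tp_all + fp_all > 0) tp_all / (tp_all + fp_all) else 0
  micro_r <- if (tp_all + fn_all > 0) tp_all / (tp_all + fn_all) else 0
  sup <- by_class$support
  has <- sup > 0
  macro <- c(precision = mean(by_class$precision[has]),
             recall = mean(by_class$recall[has]),
             f1 = mean(by_class$f1[has]))
  weighted <- c(
    precision = sum(by_class$precision[has] * sup[has]) / sum(sup[has]),
    recall = sum(by_class$recall[has] * sup[has]) / sum(sup[has]),
    f1 = sum(by_class$f1[has] * sup[has]) / sum(sup[has]))
  structure(list(by_class = by_class,
                 micro = c(precision = micro_p, recall = micro_r,
                           f1 = .f1(micro_p, micro_r)),
                 macro = macro, weighted = weighted,
                 support = sum(sup),
                 counts = c(tp = tp_all, fp = fp_all, fn = fn_all)),
            class = "ner_eval")
}

#' @export
print.ner_eval <- function(x, ...) {
  fmt <- function(nm, v, s = NA) {
    cat(sprintf("  %-16s %9.3f %9.3f %9.3f %9s\n", nm, v["precision"],
                v["recall"], v["f1"], ifelse(is.na(s), "", s)))
  }
  cat(sprintf("  %-16s %9s %9s %9s %9s\n", "", "precision", "recall", "F1",
              "support"))
  for (i in seq_len(nrow(x$by_class))) {
    r <- x$by_class[i, ]
    fmt(r$class, c(precision = r$precision, recall = r$recall, f1 = r$f1),
        r$support)
  }
  fmt("micro avg", x$micro, x$support)
  fmt("macro avg", x$macro, x$support)
  fmt("weighted avg", x$weighted, x$support)
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param x A `ner_eval`.
#' @param path Output path.
#' @export
write_eval_json <- function(x, path) {
  obj <- list(by_class = x$by_class, micro = as.list(x$micro),
              macro = as.list(x$macro), weighted = as.list(x$weighted),
              support = x$support)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), path)
  invisible(path)
}
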