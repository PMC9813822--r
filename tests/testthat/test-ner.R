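test_that("the rule tagger matches dates and lexicon phrases", {
  r <- make_reports(c("R1", "R2", "R3"),
                    text = c("Verlaufskontrolle vom 12.3.15 unauffaellig.",
                             "Keine Voraufnahmen zum Vergleich vorhanden.",
                             "Befund unauffaellig."))
  sp <- rule_tagger(r)
  expect_identical(sp$cls[sp$report_id == "R1"], "DATE")
  expect_identical(sp$surface[sp$report_id == "R1"], "12.3.15")
  expect_identical(sp$cls[sp$report_id == "R2"], "NO_PREVIOUS")
  expect_identical(sum(sp$report_id == "R3"), 0L)
})

test_that("rule tagger recovers all gold spans on a noise-free corpus", {
  cx <- small_corpus()
  rt <- rule_tagger(cx$reports)
  expect_setequal(span_keys(rt), span_keys(cx$spans))
  ev <- ner_evaluate(rt, cx$spans)
  expect_identical(unname(ev$micro["f1"]), 1)
})

test_that("analytic gradients match finite differences", {
  ns <- asNamespace("radgraph")
  set.seed(3)
  V <- 6L; d <- 3L; H <- 2L; K <- 4L
  pm <- ns$.bilstm_init(V, d, H, K)
  batch <- list(ids = matrix(sample(1:V, 8, TRUE), 2, 4),
                mask = matrix(c(1, 1, 1, 1, 1, 0, 1, 0), 2, 4),
                y = matrix(c(1L, 2L, 3L, 1L, 4L, 0L, 2L, 0L), 2, 4))
  drop <- matrix(1, 2, 2 * H)
  fw <- ns$.bilstm_forward(pm, batch, H, drop = drop, need_cache = TRUE)
  gr <- ns$.bilstm_backward(pm, batch, fw, H, drop = drop)
  eps <- 1e-4
  for (nm in names(pm)) {
    idx <- seq_along(pm[[nm]])
    if (length(idx) > 25) idx <- sample(idx, 25)
    for (j in idx) {
      p2 <- pm
      p2[[nm]][j] <- p2[[nm]][j] + eps
      lp <- ns$.bilstm_forward(p2, batch, H, drop = drop)$loss
      p2[[nm]][j] <- p2[[nm]][j] - 2 * eps
      lm <- ns$.bilstm_forward(p2, batch, H, drop = drop)$loss
      num <- (lp - lm) / (2 * eps)
      rel <- abs(num - gr[[nm]][j]) / max(abs(num), abs(gr[[nm]][j]), 1e-6)
      expect_lt(rel, 1e-4, label = sprintf("%s[%d]", nm, j))
    }
  }
})

tiny_cfg <- function(max_epochs = 8, batch_size = 512, ...) {
  train_config(batch_size = batch_size, embedding_dim = 16, hidden_dim = 24,
               max_epochs = max_epochs, seed = 5, ...)
}

test_that("the tagger memorizes a small noise-free corpus", {
  cx <- generate_corpus(corpus_config(n_patients = 12, seed = 21))
  # capacity sanity check: 30 epochs, early stopping disabled, scored on
  # the reports the model actually trained on
  fit <- train_tagger(cx$reports, cx$spans,
                      tiny_cfg(max_epochs = 30, patience = 30,
                               batch_size = 128))
  seen <- cx$reports[!cx$reports$report_id %in% fit$val_report_ids, ,
                     drop = FALSE]
  pred <- predict(fit, seen)
  gold <- cx$spans[cx$spans$report_id %in% seen$report_id &
                     cx$spans$cls %in% fit$config$classes, , drop = FALSE]
  ev <- ner_evaluate(pred, gold)
  expect_identical(unname(ev$micro["f1"]), 1)
})

test_that("training is reproducible under a fixed seed", {
  cx <- generate_corpus(corpus_config(n_patients = 10, seed = 33))
  f1 <- train_tagger(cx$reports, cx$spans, tiny_cfg(max_epochs = 3))
  f2 <- train_tagger(cx$reports, cx$spans, tiny_cfg(max_epochs = 3))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$best_metric, f2$best_metric)
  p1 <- predict(f1, cx$reports)
  p2 <- predict(f2, cx$reports)
  expect_identical(p1, p2)
})

test_that("degenerate inputs are handled as contracts promise", {
  # all-O corpus trains (loss-driven early stopping) and predicts no spans
  r <- make_reports(sprintf("R%d", 1:6),
                    text = "Unauffaelliger Befund ohne Vergleich.")
  fit <- train_tagger(r, data.frame(report_id = character(0),
                                    start = integer(0), end = integer(0),
                                    cls = character(0),
                                    surface = character(0)),
                      tiny_cfg(max_epochs = 2))
  pred <- predict(fit, r)
  expect_identical(nrow(pred), 0L)
  # evaluation raises at zero gold support instead of returning NaN
  expect_error(ner_evaluate(pred, pred), "zero entities")

  # empty prediction input
  expect_identical(nrow(predict(fit, r[0, ])), 0L)
  # punctuation-only sentence tags all O
  punct <- make_reports("RP", text = ". ! ? ,")
  expect_identical(nrow(predict(fit, punct)), 0L)

  expect_error(train_tagger(r[0, ], data.frame()), "empty corpus")
  bad <- data.frame(report_id = "R1", start = 0L, end = 2L,
                    cls = "YESTERDAY", surface = "Un")
  expect_error(
    train_tagger(r, bad, tiny_cfg(classes = c("DATE", "YESTERDAY"))),
    NA)  # YESTERDAY allowed when configured in
})

test_that("cross-validation splits whole reports into disjoint folds", {
  cx <- generate_corpus(corpus_config(n_patients = 6, seed = 12))
  reports <- cx$reports[1:10, ]
  spans <- cx$spans[cx$spans$report_id %in% reports$report_id, ]
  res <- cross_validate(reports, spans,
                        tiny_cfg(max_epochs = 2, n_folds = 5))
  expect_length(res, 5L)
  fold <- attr(res, "fold")
  expect_identical(as.integer(table(fold)), rep(2L, 5))
  # no report is assigned to two folds
  expect_identical(length(fold), nrow(reports))
  expect_error(cross_validate(reports[1:3, ], spans,
                              tiny_cfg(n_folds = 5)),
               "fewer reports than folds")
})

test_that("entity-level evaluation matches closed forms", {
  gold <- data.frame(report_id = c("A", "A", "B"), start = c(0L, 10L, 0L),
                     end = c(5L, 15L, 5L), cls = "DATE",
                     surface = "x", stringsAsFactors = FALSE)
  # perfect agreement
  ev <- ner_evaluate(gold, gold)
  expect_identical(unname(ev$micro), c(1, 1, 1))
  # empty prediction: precision reported as 0, recall 0
  ev0 <- ner_evaluate(gold[0, ], gold)
  expect_identical(unname(ev0$micro), c(0, 0, 0))
  # 1 TP, 1 FP, 1 FN -> P = R = F1 = 0.5
  pred <- gold[1:2, ]
  pred$start[2] <- 99L  # FP; gold row 2 becomes FN... keep row3 as FN
  ev5 <- ner_evaluate(pred, gold[c(1, 3), ])
  expect_identical(unname(ev5$micro), c(0.5, 0.5, 0.5))
  # micro averages agree with pooled counts to 1e-9
  expect_lt(abs(ev5$micro[["precision"]] -
                  ev5$counts[["tp"]] /
                  (ev5$counts[["tp"]] + ev5$counts[["fp"]])), 1e-9)
  # symmetric under document order
  sh <- gold[c(3, 1, 2), ]
  expect_identical(ner_evaluate(sh, gold)$micro, ev$micro)
})
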