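# User-facing NER tagger: training protocol (validation split, per-epoch
# checkpointing, early stopping on validation micro-F1, best-epoch weights),
# prediction with IOB2 repair, report-level cross-validation and grid search.

#' Training configuration for the referral tagger
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Batch size, counted in `batch_unit`s.
#' @param batch_unit `"tokens"` (default) or `"sentences"`. With trainable
#'   randomly initialized embeddings, token-counted batches of 1024 give
#'   enough optimizer updates per epoch for the patience-based early stop to
#'   see a moving validation metric; sentence-counted batches are available
#'   for corpora with known-good pretraining.
#' @param max_epochs Maximum training epochs (early stopping usually ends
#'   training before the limit).
#' @param patience Epochs of validation-performance stagnation tolerated
#'   before stopping; the best-epoch weights become the final model.
#' @param n_folds Folds for [cross_validate()].
#' @param validation_fraction Fraction of reports held out (report-level)
#'   for the early-stopping validation split.
#' @param seed Integer seed; a fixed seed makes training reproducible
#'   run-to-run on the same platform.
#' @param embedding_dim,hidden_dim Embedding size and per-direction LSTM
#'   hidden size.
#' @param dropout Dropout rate on the concatenated hidden state.
#' @param classes Span classes trained as NER labels. `YESTERDAY` is
#'   excluded by default and left to the rule-based normalizer.
#' @param clip_norm Global gradient-norm clip.
#' @param checkpoint_dir Optional directory; when set, weights are saved
#'   after every epoch together with a JSON metadata file.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-2, batch_size = 1024,
                         batch_unit = c("tokens", "sentences"),
                         max_epochs = 30, patience = 3, n_folds = 5,
                         validation_fraction = 0.2, seed = 1L,
                         embedding_dim = 32, hidden_dim = 64,
                         dropout = 0.1,
                         classes = c("DATE", "TODAY", "NO_PREVIOUS"),
                         clip_norm = 5, checkpoint_dir = NULL) {
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop("validation_fraction must lie in (0, 1)")
  }
  counts <- c(batch_size, max_epochs, patience, n_folds, embedding_dim,
              hidden_dim)
  if (any(counts < 1) || learning_rate <= 0) {
    stop("counts and learning_rate must be positive")
  }
  batch_unit <- match.arg(batch_unit)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 batch_unit = batch_unit,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 n_folds = as.integer(n_folds),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed),
                 embedding_dim = as.integer(embedding_dim),
                 hidden_dim = as.integer(hidden_dim),
                 dropout = dropout, classes = classes,
                 clip_norm = clip_norm, checkpoint_dir = checkpoint_dir),
            class = "train_config")
}

.label_set <- function(classes) {
  c("O", as.vector(rbind(paste0("B-", classes), paste0("I-", classes))))
}

# Build per-sentence structures from a tagged token table.
.sentences_from_tokens <- function(tokens, vocab, labels) {
  key <- paste(tokens$report_id, tokens$sent_id, sep = "\r")
  idx <- split(seq_len(nrow(tokens)), factor(key, levels = unique(key)))
  lapply(idx, function(grp) {
    grp <- grp[order(tokens$start[grp])]
    y <- if ("tag" %in% names(tokens)) {
      match(tokens$tag[grp], labels)
    } else NULL
    list(ids = .token_ids(tokens$token[grp], vocab), y = y,
         report_id = tokens$report_id[grp[1]],
         sent_id = tokens$sent_id[grp[1]],
         tokens = tokens$token[grp],
         starts = tokens$start[grp], ends = tokens$end[grp])
  })
}

.decode_to_spans <- function(pm, H, sents, labels, texts = NULL,
                             batch_size = 256) {
  if (!length(sents)) {
    return(list(spans = iob2_to_spans(
      data.frame(report_id = character(0), sent_id = integer(0),
                 token = character(0), start = integer(0), end = integer(0),
                 tag = character(0), stringsAsFactors = FALSE)),
      n_removed = 0L))
  }
  batches <- .make_batches(sents, batch_size)
  rows <- list()
  for (bt in batches) {
    dec <- .bilstm_decode(pm, bt, H)
    for (b in seq_along(bt$sent_idx)) {
      s <- sents[[bt$sent_idx[b]]]
      L <- length(s$ids)
      rows[[length(rows) + 1L]] <- data.frame(
        report_id = s$report_id, sent_id = s$sent_id, token = s$tokens,
        start = s$starts, end = s$ends,
        tag = labels[dec[b, seq_len(L)]], stringsAsFactors = FALSE)
    }
  }
  tokens <- do.call(rbind, rows)
  fx <- filter_tokens_iob2(tokens)
  list(spans = iob2_to_spans(fx$tokens, texts), n_removed = fx$n_removed,
       tokens = fx$tokens)
}

#' Train the bidirectional LSTM referral tagger
#'
#' Fits a single-layer bidirectional LSTM with a per-token softmax over the
#' IOB2 label set, using trainable randomly initialized word embeddings
#' (digits are normalized to a common shape so unseen dates share the shape
#' of seen ones). A report-level validation split drives early stopping on
#' entity-level micro-F1; the best-performing epoch's weights are kept as
#' the final model.
#'
#' @param reports Report table (the training corpus).
#' @param spans Gold annotation spans for those reports.
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return Object of class `referral_tagger`.
#' @export
train_tagger <- function(reports, spans, config = train_config(),
                         verbose = FALSE) {
  if (!nrow(reports)) stop("empty corpus")
  set.seed(config$seed)
  labels <- .label_set(config$classes)
  spans <- spans[spans$cls %in% config$classes, , drop = FALSE]
  bad <- setdiff(unique(spans$cls), config$classes)
  if (length(bad)) stop("label set mismatch: ", paste(bad, collapse = ", "))
  tokens <- spans_to_iob2(report_tokens(reports), spans)

  rids <- reports$report_id
  n_val <- max(1L, min(length(rids) - 1L,
                       round(config$validation_fraction * length(rids))))
  val_ids <- if (length(rids) > 1L) sample(rids, n_val) else character(0)
  tr_tokens <- tokens[!tokens$report_id %in% val_ids, , drop = FALSE]
  val_tokens <- tokens[tokens$report_id %in% val_ids, , drop = FALSE]
  vocab <- .build_vocab(tr_tokens$token)
  V <- length(vocab) + 1L
  H <- config$hidden_dim

  tr_sents <- .sentences_from_tokens(tr_tokens, vocab, labels)
  val_sents <- .sentences_from_tokens(val_tokens, vocab, labels)
  val_gold <- iob2_to_spans(val_tokens)
  pm <- .bilstm_init(V, config$embedding_dim, H, length(labels))
  st <- .adam_init(pm)
  batches <- .make_batches(tr_sents, config$batch_size, config$batch_unit)
  val_batches <- .make_batches(val_sents, 256)

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_metric = numeric(0))
  # early stopping compares (entity micro-F1, -validation loss)
  # lexicographically: while no entity is predicted yet, a falling
  # validation loss still counts as progress; the loss tie-break needs a
  # material drop (1e-3 mean cross-entropy) so a converged model stops
  best <- list(f1 = -Inf, loss = Inf, pm = pm, epoch = 0L)
  stall <- 0L
  if (!is.null(config$checkpoint_dir)) {
    dir.create(config$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
  }

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(length(batches))
    ep_loss <- 0; ep_n <- 0
    for (bi in ord) {
      bt <- batches[[bi]]
      drop <- NULL
      if (config$dropout > 0) {
        drop <- matrix(
          (stats::runif(nrow(bt$ids) * 2 * H) >= config$dropout) /
            (1 - config$dropout), nrow(bt$ids), 2 * H)
      }
      fw <- .bilstm_forward(pm, bt, H, drop = drop, need_cache = TRUE)
      gr <- .bilstm_backward(pm, bt, fw, H, drop = drop)
      gr <- .clip_grads(gr, config$clip_norm)
      upd <- .adam_step(pm, gr, st, config$learning_rate)
      pm <- upd$pm; st <- upd$st
      ep_loss <- ep_loss + fw$loss * fw$n_valid
      ep_n <- ep_n + fw$n_valid
    }
    train_loss <- ep_loss / max(ep_n, 1)
    if (length(val_batches)) {
      val_loss <- 0; val_n <- 0
      for (vb in val_batches) {
        vf <- .bilstm_forward(pm, vb, H)
        val_loss <- val_loss + vf$loss * vf$n_valid
        val_n <- val_n + vf$n_valid
      }
      val_loss <- val_loss / max(val_n, 1)
    } else {
      val_loss <- train_loss
    }
    metric <- if (nrow(val_gold)) {
      pred <- .decode_to_spans(pm, H, val_sents, labels)$spans
      unname(ner_evaluate(pred, val_gold)$micro["f1"])
    } else {
      0
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = train_loss,
                                         val_loss = val_loss,
                                         val_metric = metric))
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f, val loss %.4f, val F1 %.4f",
                      epoch, train_loss, val_loss, metric))
    }
    if (!is.null(config$checkpoint_dir)) {
      saveRDS(pm, file.path(config$checkpoint_dir,
                            sprintf("epoch_%03d.rds", epoch)))
    }
    improved <- metric > best$f1 + 1e-9 ||
      (abs(metric - best$f1) <= 1e-9 && val_loss < best$loss - 1e-3)
    if (improved) {
      best <- list(f1 = metric, loss = val_loss, pm = pm, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }

  if (!is.null(config$checkpoint_dir)) {
    meta <- list(labels = labels, classes = config$classes,
                 vocab_size = V, best_epoch = best$epoch,
                 config = config[setdiff(names(config), "checkpoint_dir")])
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE),
               file.path(config$checkpoint_dir, "metadata.json"))
  }

  structure(list(params = best$pm, vocab = vocab, labels = labels,
                 config = config, history = history,
                 best_epoch = best$epoch, best_metric = best$f1,
                 n_train_reports = length(rids) - length(val_ids),
                 n_val_reports = length(val_ids),
                 val_report_ids = val_ids),
            class = "referral_tagger")
}

#' @export
print.referral_tagger <- function(x, ...) {
  cat("Bidirectional LSTM referral tagger\n")
  cat(sprintf("  classes: %s\n", paste(x$config$classes, collapse = ", ")))
  cat(sprintf("  vocab: %d token shapes; embedding %d; hidden %d/direction\n",
              length(x$vocab), x$config$embedding_dim, x$config$hidden_dim))
  cat(sprintf("  trained on %d reports (+%d validation), best epoch %d, validation micro-F1 %.3f\n",
              x$n_train_reports, x$n_val_reports, x$best_epoch,
              x$best_metric))
  invisible(x)
}

#' @export
summary.referral_tagger <- function(object, ...) {
  print(object)
  cat("\nTraining history:\n")
  print(object$history, row.names = FALSE)
  invisible(object)
}

#' @export
plot.referral_tagger <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$val_metric, type = "b", pch = 16,
                 xlab = "epoch", ylab = "validation micro-F1",
                 ylim = c(0, 1), ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}

#' Predict referral spans on new reports
#'
#' Tags tokens with the trained model, repairs IOB2-invalid runs (invalid
#' entities are removed, mirroring the training-data convention), and
#' converts the surviving entities to character spans.
#'
#' @param object A `referral_tagger`.
#' @param reports Report table.
#' @param type `"spans"` (default) or `"tokens"` (per-token IOB2 table).
#' @param ... Unused.
#' @return Span table (with an attribute `n_removed`: entities removed by
#'   the IOB2 filter) or tagged token table.
#' @export
predict.referral_tagger <- function(object, reports, type = c("spans",
                                                              "tokens"),
                                    ...) {
  type <- match.arg(type)
  if (is.null(object$params)) stop("untrained tagger")
  tokens <- report_tokens(reports)
  sents <- .sentences_from_tokens(tokens, object$vocab, object$labels)
  texts <- stats::setNames(reports$text, reports$report_id)
  res <- .decode_to_spans(object$params, object$config$hidden_dim, sents,
                          object$labels, texts)
  if (type == "tokens") return(res$tokens)
  out <- res$spans
  attr(out, "n_removed") <- res$n_removed
  out
}

#' Report-level k-fold cross-validation
#'
#' Reports are assigned whole to folds (no report is split across folds).
#' Each round trains on the remaining folds — with its own inner validation
#' split for early stopping — and is evaluated on the held-out fold.
#'
#' @param reports,spans Corpus and gold spans.
#' @param config A [train_config()]; `n_folds` and `seed` control the split.
#' @return List of `ner_eval` objects, one per fold.
#' @export
cross_validate <- function(reports, spans, config = train_config()) {
  k <- config$n_folds
  if (k < 2) stop("n_folds must be at least 2")
  if (nrow(reports) < k) stop("fewer reports than folds")
  set.seed(config$seed)
  fold <- sample(rep(seq_len(k), length.out = nrow(reports)))
  out <- vector("list", k)
  for (f in seq_len(k)) {
    te <- reports[fold == f, , drop = FALSE]
    tr <- reports[fold != f, , drop = FALSE]
    cfg <- config
    cfg$seed <- config$seed + f
    fit <- train_tagger(tr, spans[spans$report_id %in% tr$report_id, ,
                                  drop = FALSE], cfg)
    pred <- predict(fit, te)
    gold <- spans[spans$report_id %in% te$report_id &
                    spans$cls %in% config$classes, , drop = FALSE]
    out[[f]] <- ner_evaluate(pred, gold)
  }
  names(out) <- paste0("fold", seq_len(k))
  attr(out, "fold") <- fold
  out
}

#' Grid search over learning rates and batch sizes
#'
#' Trains one model per grid point and records the best validation micro-F1
#' reached, mirroring a hyperparameter search whose default grid contains
#' the chosen operating point (learning rate 1e-2, batch size 1024).
#'
#' @param reports,spans Corpus and gold spans.
#' @param grid Data frame with columns `learning_rate` and `batch_size`.
#' @param config Base [train_config()].
#' @return `grid` with an added `val_metric` column, ordered best first.
#' @export
grid_search_tagger <- function(reports, spans,
                               grid = expand.grid(
                                 learning_rate = c(1e-3, 1e-2),
                                 batch_size = c(256, 1024)),
                               config = train_config()) {
  grid$val_metric <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    cfg$learning_rate <- grid$learning_rate[i]
    cfg$batch_size <- as.integer(grid$batch_size[i])
    fit <- train_tagger(reports, spans, cfg)
    grid$val_metric[i] <- fit$best_metric
  }
  grid[order(-grid$val_metric), , drop = FALSE]
}
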