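# Sentence splitting, tokenization, span <-> IOB2 conversion and IOB2 repair.
# All character offsets are 0-based, half-open.

.token_pattern <- paste(
  "\\d{1,2}\\.[–-]\\d{1,2}\\.\\d{1,2}\\.\\d{2,4}",  # day range 12.-14.03.2015
  "\\d{1,2}\\.\\d{1,2}\\.\\d{2,4}",                      # 12.03.2015 / 12.3.15
  "\\d{1,2}\\.\\d{1,2}\\.",                              # 12.03. (year omitted)
  "\\d{1,2}/\\d{1,2}/\\d{2,4}",                          # 12/03/2015
  "\\d{1,2}/\\d{4}",                                     # 03/2019 (day omitted)
  "\\d{4}-\\d{2}-\\d{2}",                                # ISO 2015-03-12
  "\\d+,\\d+",                                           # decimal comma 3,5
  "[\\p{L}\\p{N}]+(?:-[\\p{L}\\p{N}]+)*",                # words incl. CT-Thorax
  "\\S",                                                 # any other glyph
  sep = "|")

#' Split a report text into sentences
#'
#' Period/question/exclamation marks followed by whitespace end a sentence
#' only when the next non-blank character is an uppercase letter or a digit
#' and the preceding token is not a known abbreviation; newlines always end a
#' sentence. A period inside a numeric date ("12.03.2015") is never a
#' boundary because no whitespace follows it. The concatenation of the
#' returned sentences with their original inter-sentence gaps reconstructs
#' the input.
#'
#' @param text Report text.
#' @return Data frame with columns `sent_id`, `start`, `end` (0-based,
#'   half-open offsets into `text`), `text` (the trimmed sentence).
#' @export
split_sentences <- function(text) {
  empty <- data.frame(sent_id = integer(), start = integer(),
                      end = integer(), text = character(),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  n <- nchar(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  cuts <- integer(0)  # 1-based position after which a sentence ends
  for (p in which(chars %in% c(".", "!", "?", "\n"))) {
    ch <- chars[p]
    if (ch == "\n") { cuts <- c(cuts, p); next }
    if (p == n) { cuts <- c(cuts, p); next }
    if (!grepl("^[ \t]$", chars[p + 1L])) next
    # next non-blank character must open a new sentence
    rest <- substr(text, p + 1L, n)
    nxt <- sub("^[ \t\n]*", "", rest)
    if (!nzchar(nxt)) { cuts <- c(cuts, p); next }
    first <- substr(nxt, 1L, 1L)
    if (!grepl("[[:upper:]ÄÖÜ0-9]", first)) next
    tok <- sub(".*[ \t\n]", "", substr(text, 1L, p))
    if (tok %in% .radgraph_abbrev) next
    cuts <- c(cuts, p)
  }
  cuts <- sort(unique(c(cuts, n)))
  out <- list(); sid <- 0L; begin <- 1L
  for (cut in cuts) {
    seg <- substr(text, begin, cut)
    # trim while tracking offsets
    lead <- attr(regexpr("^[ \t\n]*", seg), "match.length")
    trail <- attr(regexpr("[ \t\n]*$", seg), "match.length")
    s <- begin + lead
    e <- cut - trail
    if (e >= s) {
      sid <- sid + 1L
      out[[sid]] <- data.frame(
        sent_id = sid, start = s - 1L, end = e,
        text = substr(text, s, e), stringsAsFactors = FALSE)
    }
    begin <- cut + 1L
  }
  if (length(out)) do.call(rbind, out) else empty
}

#' Tokenize a sentence
#'
#' Whitespace/punctuation tokenization that keeps numeric dates
#' ("12.03.2015", "12.3.15", "12.03.", "12/03/2015", "2015-03-12"),
#' day ranges ("12.-14.03.2015"), decimal-comma numbers ("3,5") and
#' hyphenated words ("CT-Thorax") as single tokens.
#'
#' @param text Sentence text.
#' @param base Offset (0-based) of `text` within its report; added to the
#'   returned token offsets.
#' @return Data frame with columns `token`, `start`, `end`.
#' @export
tokenize <- function(text, base = 0L) {
  m <- gregexpr(.token_pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(token = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  data.frame(
    token = substring(text, starts, starts + lens - 1L),
    start = base + starts - 1L,
    end = base + starts + lens - 1L,
    stringsAsFactors = FALSE)
}

#' Tokenize whole reports into a token table
#'
#' Splits each report into sentences and tokens; offsets are 0-based into the
#' report text.
#'
#' @param reports Report table.
#' @return Data frame with columns `report_id`, `sent_id`, `token`,
#'   `start`, `end`.
#' @export
report_tokens <- function(reports) {
  out <- vector("list", nrow(reports))
  for (i in seq_len(nrow(reports))) {
    sents <- split_sentences(reports$text[i])
    if (!nrow(sents)) next
    toks <- lapply(seq_len(nrow(sents)), function(j) {
      tk <- tokenize(sents$text[j], base = sents$start[j])
      if (nrow(tk)) tk$sent_id <- sents$sent_id[j]
      tk
    })
    toks <- do.call(rbind, toks[vapply(toks, nrow, 1L) > 0])
    if (is.null(toks) || !nrow(toks)) next
    toks$report_id <- reports$report_id[i]
    out[[i]] <- toks[, c("report_id", "sent_id", "token", "start", "end")]
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out)) do.call(rbind, out) else
    data.frame(report_id = character(), sent_id = integer(),
               token = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
}

#' Project annotation spans onto tokens as IOB2 tags
#'
#' The first token overlapping a span receives `B-<cls>`, subsequent tokens
#' `I-<cls>`, everything else `O`.
#'
#' @param tokens Token table from [report_tokens()].
#' @param spans Span table (`report_id`, `start`, `end`, `cls`).
#' @return `tokens` with an added `tag` column.
#' @section Errors: overlapping spans and spans crossing a sentence boundary
#'   raise an error.
#' @export
spans_to_iob2 <- function(tokens, spans) {
  tokens$tag <- "O"
  if (!nrow(spans)) return(tokens)
  for (i in seq_len(nrow(spans))) {
    idx <- which(tokens$report_id == spans$report_id[i] &
                   tokens$start < spans$end[i] &
                   tokens$end > spans$start[i])
    if (!length(idx)) next
    if (length(unique(tokens$sent_id[idx])) > 1L) {
      stop(sprintf("span [%d,%d) of report %s crosses a sentence boundary",
                   spans$start[i], spans$end[i], spans$report_id[i]))
    }
    if (any(tokens$tag[idx] != "O")) {
      stop(sprintf("overlapping spans in report %s at [%d,%d)",
                   spans$report_id[i], spans$start[i], spans$end[i]))
    }
    tokens$tag[idx] <- c(paste0("B-", spans$cls[i]),
                         rep(paste0("I-", spans$cls[i]), length(idx) - 1L))
  }
  tokens
}

#' Recover annotation spans from IOB2-tagged tokens
#'
#' Inverse of [spans_to_iob2()] on valid tag sequences. A `B-` tag opens an
#' entity; adjacent `B-` tags yield adjacent single-token entities.
#'
#' @param tokens Token table with a `tag` column.
#' @param texts Optional named character vector (report_id -> report text)
#'   used to reconstruct exact surfaces; without it the surface is the tokens
#'   joined by single spaces.
#' @return Span table (`report_id`, `start`, `end`, `cls`, `surface`).
#' @export
iob2_to_spans <- function(tokens, texts = NULL) {
  res <- list()
  if (nrow(tokens)) {
    key <- paste(tokens$report_id, tokens$sent_id, sep = "\r")
    for (grp in split(seq_len(nrow(tokens)), key)) {
      grp <- grp[order(tokens$start[grp])]
      tg <- tokens$tag[grp]
      open <- NULL
      flush <- function(first, last, cls) {
        s <- tokens$start[first]; e <- tokens$end[last]
        id <- tokens$report_id[first]
        surf <- if (!is.null(texts) && id %in% names(texts)) {
          substr(texts[[id]], s + 1L, e)
        } else {
          paste(tokens$token[tokens$report_id == id & tokens$start >= s &
                               tokens$end <= e], collapse = " ")
        }
        res[[length(res) + 1L]] <<- data.frame(
          report_id = id, start = s, end = e, cls = cls, surface = surf,
          stringsAsFactors = FALSE)
      }
      for (k in seq_along(tg)) {
        t <- tg[k]
        if (startsWith(t, "B-")) {
          if (!is.null(open)) flush(open$first, open$last, open$cls)
          open <- list(first = grp[k], last = grp[k], cls = sub("^B-", "", t))
        } else if (startsWith(t, "I-") && !is.null(open) &&
                     sub("^I-", "", t) == open$cls) {
          open$last <- grp[k]
        } else {
          if (!is.null(open)) flush(open$first, open$last, open$cls)
          open <- NULL
        }
      }
      if (!is.null(open)) flush(open$first, open$last, open$cls)
    }
  }
  if (length(res)) {
    out <- do.call(rbind, res)
    out[order(out$report_id, out$start), , drop = FALSE]
  } else {
    data.frame(report_id = character(), start = integer(), end = integer(),
               cls = character(), surface = character(),
               stringsAsFactors = FALSE)
  }
}

#' Remove IOB2-invalid entity runs from a tag sequence
#'
#' An `I-x` tag preceded by neither `B-x` nor `I-x` opens an invalid run; the
#' whole run of consecutive `I-x` tags is replaced by `O` and counted as one
#' removed entity. Valid entities are kept unchanged, so the repair is
#' idempotent.
#'
#' @param tags Character vector of IOB2 tags for one sentence.
#' @return List with elements `tags` (repaired vector) and `n_removed`.
#' @export
filter_invalid_iob2 <- function(tags) {
  n_removed <- 0L
  k <- 1L
  n <- length(tags)
  while (k <= n) {
    t <- tags[k]
    if (startsWith(t, "I-")) {
      cls <- sub("^I-", "", t)
      prev_ok <- k > 1L && tags[k - 1L] %in% paste0(c("B-", "I-"), cls)
      if (!prev_ok) {
        j <- k
        while (j <= n && tags[j] == t) j <- j + 1L
        tags[k:(j - 1L)] <- "O"
        n_removed <- n_removed + 1L
        k <- j
        next
      }
    }
    k <- k + 1L
  }
  list(tags = tags, n_removed = n_removed)
}

#' Apply IOB2 repair to a whole token table
#'
#' Runs [filter_invalid_iob2()] per sentence.
#'
#' @param tokens Token table with a `tag` column.
#' @return List with `tokens` (repaired) and `n_removed` (total entities
#'   removed).
#' @export
filter_tokens_iob2 <- function(tokens) {
  total <- 0L
  if (nrow(tokens)) {
    key <- paste(tokens$report_id, tokens$sent_id, sep = "\r")
    for (grp in split(seq_len(nrow(tokens)), key)) {
      grp <- grp[order(tokens$start[grp])]
      fx <- filter_invalid_iob2(tokens$tag[grp])
      tokens$tag[grp] <- fx$tags
      total <- total + fx$n_removed
    }
  }
  list(tokens = tokens, n_removed = total)
}

#' Write tagged tokens in CoNLL-style two-column format
#'
#' One `token<TAB>tag` line per token, a blank line between sentences, and a
#' `# <report_id> <sent_id>` comment opening each sentence.
#'
#' @param tokens Token table with a `tag` column.
#' @param path Output path.
#' @export
write_conll <- function(tokens, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  key <- paste(tokens$report_id, tokens$sent_id, sep = "\r")
  for (grp in split(seq_len(nrow(tokens)), factor(key, levels = unique(key)))) {
    grp <- grp[order(tokens$start[grp])]
    writeLines(sprintf("# %s %d", tokens$report_id[grp[1]],
                       tokens$sent_id[grp[1]]), con, useBytes = TRUE)
    writeLines(paste(tokens$token[grp], tokens$tag[grp], sep = "\t"),
               con, useBytes = TRUE)
    writeLines("", con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read a CoNLL-style two-column file
#'
#' @param path File written by [write_conll()].
#' @return Token table (`report_id`, `sent_id`, `token`, `tag`); character
#'   offsets are not stored in the CoNLL format.
#' @export
read_conll <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  out <- list(); rid <- NA_character_; sid <- NA_integer_
  for (ln in lines) {
    if (startsWith(ln, "# ")) {
      parts <- strsplit(sub("^# ", "", ln), " ")[[1]]
      rid <- parts[1]; sid <- as.integer(parts[2])
    } else if (nzchar(ln)) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      out[[length(out) + 1L]] <- data.frame(
        report_id = rid, sent_id = sid, token = parts[1], tag = parts[2],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(report_id = character(), sent_id = integer(),
               token = character(), tag = character(), stringsAsFactors = FALSE)
}
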