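# Native bidirectional LSTM sequence tagger: vectorized batched forward and
# backward passes in base R (BLAS matrix products), Adam updates, masking
# for padded positions and variational dropout on the concatenated hidden
# state. Gate order in the 4H blocks: input, forget, output, cell.

.sigm <- function(x) 1 / (1 + exp(-x))

.norm_token <- function(x) gsub("[0-9]", "9", x)

.build_vocab <- function(tokens) {
  toks <- unique(.norm_token(tokens))
  stats::setNames(seq_along(toks) + 1L, toks)  # index 1 is <unk>/<pad>
}

.token_ids <- function(tokens, vocab) {
  ids <- unname(vocab[.norm_token(tokens)])
  ids[is.na(ids)] <- 1L
  ids
}

.bilstm_init <- function(V, d, H, K) {
  gl <- function(nr, nc) {
    r <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -r, r), nr, nc)
  }
  pm <- list(E = gl(V, d),
             Wxf = gl(d, 4 * H), Whf = gl(H, 4 * H), bf = rep(0, 4 * H),
             Wxb = gl(d, 4 * H), Whb = gl(H, 4 * H), bb = rep(0, 4 * H),
             Wo = gl(2 * H, K), bo = rep(0, K))
  pm$bf[(H + 1):(2 * H)] <- 1  # forget-gate bias
  pm$bb[(H + 1):(2 * H)] <- 1
  pm
}

# sents: list of list(ids, y, report_id, sent_id, starts, ends, tokens)
# batch_size is counted in tokens or sentences; sentences are length-sorted
# first so padding within a batch stays small either way.
.make_batches <- function(sents, batch_size, unit = "sentences") {
  if (!length(sents)) return(list())
  lens <- vapply(sents, function(s) length(s$ids), 1L)
  ord <- order(lens)
  if (unit == "tokens") {
    grp <- cumsum(lens[ord])
    chunks <- split(ord, (grp - 1) %/% batch_size)
  } else {
    chunks <- split(ord, ceiling(seq_along(ord) / batch_size))
  }
  lapply(chunks, function(idx) {
    B <- length(idx)
    Tm <- max(lens[idx])
    ids <- matrix(1L, B, Tm); mask <- matrix(0, B, Tm)
    y <- matrix(0L, B, Tm)
    for (b in seq_len(B)) {
      s <- sents[[idx[b]]]
      L <- length(s$ids)
      ids[b, seq_len(L)] <- s$ids
      mask[b, seq_len(L)] <- 1
      if (!is.null(s$y)) y[b, seq_len(L)] <- s$y
    }
    list(ids = ids, mask = mask, y = y, sent_idx = idx)
  })
}

.lstm_dir <- function(pm, ids, mask, Wx, Wh, b, H, need_cache) {
  B <- nrow(ids); Tm <- ncol(ids)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  Hs <- vector("list", Tm)
  cache <- if (need_cache) vector("list", Tm) else NULL
  for (t in seq_len(Tm)) {
    x <- pm$E[ids[, t], , drop = FALSE]
    z <- x %*% Wx + h %*% Wh
    z <- sweep(z, 2, b, "+")
    gi <- .sigm(z[, 1:H, drop = FALSE])
    gf <- .sigm(z[, (H + 1):(2 * H), drop = FALSE])
    go <- .sigm(z[, (2 * H + 1):(3 * H), drop = FALSE])
    gg <- tanh(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- gf * cc + gi * gg
    tc <- tanh(c_new)
    h_new <- go * tc
    m <- mask[, t]
    if (need_cache) {
      cache[[t]] <- list(ids = ids[, t], gi = gi, gf = gf, go = go, gg = gg,
                         tc = tc, c_prev = cc, h_prev = h, m = m)
    }
    h <- h_new * m + h * (1 - m)
    cc <- c_new * m + cc * (1 - m)
    Hs[[t]] <- h
  }
  list(Hs = Hs, cache = cache)
}

.lstm_dir_backward <- function(pm, dHs, cache, Wx, Wh, H, order_fwd) {
  B <- nrow(dHs[[1]]); d <- ncol(pm$E)
  dWx <- matrix(0, d, 4 * H); dWh <- matrix(0, H, 4 * H); db <- rep(0, 4 * H)
  dh_rec <- matrix(0, B, H); dc_rec <- matrix(0, B, H)
  ids_all <- list(); dx_all <- list()
  for (t in rev(order_fwd)) {
    ch <- cache[[t]]
    dh <- dHs[[t]] + dh_rec
    m <- ch$m
    dh_raw <- dh * m
    dh_pass <- dh * (1 - m)
    dc_new <- dc_rec * m
    dc_pass <- dc_rec * (1 - m)
    do_ <- dh_raw * ch$tc
    dc <- dc_new + dh_raw * ch$go * (1 - ch$tc^2)
    di <- dc * ch$gg
    dg <- dc * ch$gi
    df <- dc * ch$c_prev
    dc_prev <- dc * ch$gf + dc_pass
    da <- cbind(di * ch$gi * (1 - ch$gi),
                df * ch$gf * (1 - ch$gf),
                do_ * ch$go * (1 - ch$go),
                dg * (1 - ch$gg^2))
    x <- pm$E[ch$ids, , drop = FALSE]
    dWx <- dWx + crossprod(x, da)
    dWh <- dWh + crossprod(ch$h_prev, da)
    db <- db + colSums(da)
    dx_all[[length(dx_all) + 1L]] <- da %*% t(Wx)
    ids_all[[length(ids_all) + 1L]] <- ch$ids
    dh_rec <- da %*% t(Wh) + dh_pass
    dc_rec <- dc_prev
  }
  list(dWx = dWx, dWh = dWh, db = db,
       dx = do.call(rbind, dx_all), ids = unlist(ids_all))
}

# Forward pass over one batch. Returns the mean cross-entropy over valid
# tokens, per-token class probabilities, and (optionally) caches for
# backpropagation.
.bilstm_forward <- function(pm, batch, H, drop = NULL, need_cache = FALSE) {
  ids <- batch$ids; mask <- batch$mask; y <- batch$y
  B <- nrow(ids); Tm <- ncol(ids); K <- length(pm$bo)
  fwd <- .lstm_dir(pm, ids, mask, pm$Wxf, pm$Whf, pm$bf, H, need_cache)
  rid <- ids[, rev(seq_len(Tm)), drop = FALSE]
  rmask <- mask[, rev(seq_len(Tm)), drop = FALSE]
  bwd <- .lstm_dir(pm, rid, rmask, pm$Wxb, pm$Whb, pm$bb, H, need_cache)
  n_valid <- sum(mask)
  loss <- 0
  P <- vector("list", Tm)
  Hc <- vector("list", Tm)
  for (t in seq_len(Tm)) {
    hc <- cbind(fwd$Hs[[t]], bwd$Hs[[Tm - t + 1L]])
    if (!is.null(drop)) hc <- hc * drop
    logits <- hc %*% pm$Wo
    logits <- sweep(logits, 2, pm$bo, "+")
    mx <- apply(logits, 1, max)
    ex <- exp(logits - mx)
    p <- ex / rowSums(ex)
    P[[t]] <- p
    Hc[[t]] <- hc
    valid <- which(mask[, t] > 0 & y[, t] > 0L)
    if (length(valid)) {
      loss <- loss - sum(log(pmax(p[cbind(valid, y[valid, t])], 1e-12)))
    }
  }
  loss <- loss / max(n_valid, 1)
  list(loss = loss, P = P, Hc = Hc, fwd = fwd, bwd = bwd,
       n_valid = n_valid)
}

.bilstm_backward <- function(pm, batch, fw, H, drop = NULL) {
  ids <- batch$ids; mask <- batch$mask; y <- batch$y
  B <- nrow(ids); Tm <- ncol(ids); K <- length(pm$bo)
  n <- max(fw$n_valid, 1)
  dWo <- matrix(0, 2 * H, K); dbo <- rep(0, K)
  dHf <- vector("list", Tm); dHb <- vector("list", Tm)
  for (t in seq_len(Tm)) {
    dlog <- fw$P[[t]]
    sel <- cbind(seq_len(B), ifelse(y[, t] > 0L, y[, t], 1L))
    dlog[sel] <- dlog[sel] - as.numeric(y[, t] > 0L)
    dlog <- dlog * (mask[, t] * (y[, t] > 0L)) / n
    dWo <- dWo + crossprod(fw$Hc[[t]], dlog)
    dbo <- dbo + colSums(dlog)
    dhc <- dlog %*% t(pm$Wo)
    if (!is.null(drop)) dhc <- dhc * drop
    dHf[[t]] <- dhc[, 1:H, drop = FALSE]
    dHb[[Tm - t + 1L]] <- dhc[, (H + 1):(2 * H), drop = FALSE]
  }
  gf <- .lstm_dir_backward(pm, dHf, fw$fwd$cache, pm$Wxf, pm$Whf, H,
                           seq_len(Tm))
  gb <- .lstm_dir_backward(pm, dHb, fw$bwd$cache, pm$Wxb, pm$Whb, H,
                           seq_len(Tm))
  dE <- matrix(0, nrow(pm$E), ncol(pm$E))
  dx <- rbind(gf$dx, gb$dx)
  idv <- c(gf$ids, gb$ids)
  rs <- rowsum(dx, idv)
  dE[as.integer(rownames(rs)), ] <- dE[as.integer(rownames(rs)), ] + rs
  list(E = dE,
       Wxf = gf$dWx, Whf = gf$dWh, bf = gf$db,
       Wxb = gb$dWx, Whb = gb$dWh, bb = gb$db,
       Wo = dWo, bo = dbo)
}

.clip_grads <- function(gr, max_norm = 5) {
  total <- sqrt(sum(vapply(gr, function(g) sum(g^2), 0)))
  if (is.finite(total) && total > max_norm) {
    gr <- lapply(gr, function(g) g * (max_norm / total))
  }
  gr
}

.adam_init <- function(pm) {
  list(m = lapply(pm, function(p) p * 0),
       v = lapply(pm, function(p) p * 0), t = 0L)
}

.adam_step <- function(pm, gr, st, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1L
  b1c <- 1 - beta1^st$t
  b2c <- 1 - beta2^st$t
  for (nm in names(pm)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * gr[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * gr[[nm]]^2
    pm[[nm]] <- pm[[nm]] - lr * (st$m[[nm]] / b1c) /
      (sqrt(st$v[[nm]] / b2c) + eps)
  }
  list(pm = pm, st = st)
}

# Greedy per-token decode of a batch; returns an integer matrix of label
# indices (0 on padding).
.bilstm_decode <- function(pm, batch, H) {
  fw <- .bilstm_forward(pm, batch, H, drop = NULL, need_cache = FALSE)
  Tm <- ncol(batch$ids)
  out <- matrix(0L, nrow(batch$ids), Tm)
  for (t in seq_len(Tm)) {
    out[, t] <- max.col(fw$P[[t]], ties.method = "first") *
      (batch$mask[, t] > 0)
  }
  out
}
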