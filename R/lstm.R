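# Vectorized LSTM language model over SMILES tokens, in plain R matrix
# algebra: learned token embeddings, one or more LSTM layers, a softmax
# output head, Adam updates and full back-propagation through time. Model
# sizes here are small (tens of tokens, hundreds of hidden units), where
# BLAS-backed R is entirely adequate.

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Parameter initialization: uniform +-scale, seeded.
.lstm_init <- function(vocab_size, embed_size, hidden_size, n_layers, seed) {
  set.seed(seed)
  ru <- function(nr, nc, scale) {
    matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
  }
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    d_in <- if (l == 1L) embed_size else hidden_size
    s <- sqrt(1 / hidden_size)
    layers[[l]] <- list(W = ru(d_in, 4L * hidden_size, s),
                        U = ru(hidden_size, 4L * hidden_size, s),
                        b = {
                          b <- rep(0, 4L * hidden_size)
                          # forget-gate bias starts at 1 for gradient flow
                          b[hidden_size + seq_len(hidden_size)] <- 1
                          b
                        })
  }
  list(E = ru(vocab_size, embed_size, sqrt(1 / embed_size)),
       layers = layers,
       Wo = ru(hidden_size, vocab_size, sqrt(1 / hidden_size)),
       bo = rep(0, vocab_size))
}

# One forward pass over a batch. `ids` is B x T of token indices; inputs are
# ids[, t], targets ids[, t+1]; pad targets are masked out of the loss.
# Returns loss and, if `grad`, the full gradient set (same shapes as params).
.lstm_loss_grad <- function(params, ids, grad = TRUE) {
  B <- nrow(ids)
  Tm <- ncol(ids) - 1L
  H <- nrow(params$Wo)
  V <- ncol(params$Wo)
  L <- length(params$layers)
  gates <- function(z, H) {
    list(i = .sigmoid(z[, seq_len(H), drop = FALSE]),
         f = .sigmoid(z[, H + seq_len(H), drop = FALSE]),
         g = tanh(z[, 2L * H + seq_len(H), drop = FALSE]),
         o = .sigmoid(z[, 3L * H + seq_len(H), drop = FALSE]))
  }
  cache <- if (grad) vector("list", Tm) else NULL
  h <- lapply(seq_len(L), function(l) matrix(0, B, H))
  cc <- lapply(seq_len(L), function(l) matrix(0, B, H))
  loss <- 0
  n_tok <- 0L
  dWo <- if (grad) matrix(0, H, V)
  dbo <- if (grad) rep(0, V)
  dlogit_cache <- if (grad) vector("list", Tm)
  for (t in seq_len(Tm)) {
    x <- params$E[ids[, t], , drop = FALSE]
    step <- if (grad) vector("list", L)
    for (l in seq_len(L)) {
      p <- params$layers[[l]]
      z <- x %*% p$W + h[[l]] %*% p$U +
        matrix(p$b, B, 4L * H, byrow = TRUE)
      gt <- gates(z, H)
      c_new <- gt$f * cc[[l]] + gt$i * gt$g
      tc <- tanh(c_new)
      h_new <- gt$o * tc
      if (grad) {
        step[[l]] <- list(x = x, h_prev = h[[l]], c_prev = cc[[l]],
                          i = gt$i, f = gt$f, g = gt$g, o = gt$o,
                          c = c_new, tc = tc)
      }
      cc[[l]] <- c_new
      h[[l]] <- h_new
      x <- h_new
    }
    logits <- x %*% params$Wo + matrix(params$bo, B, V, byrow = TRUE)
    target <- ids[, t + 1L]
    mask <- target != .PAD
    if (any(mask)) {
      m <- apply(logits, 1L, max)
      lse <- m + log(rowSums(exp(logits - m)))
      logp <- logits[cbind(seq_len(B), target)] - lse
      loss <- loss - sum(logp[mask])
      n_tok <- n_tok + sum(mask)
      if (grad) {
        probs <- exp(logits - lse)  # lse recycles by column: B x V ok
        dlog <- probs
        dlog[cbind(seq_len(B), target)] <-
          dlog[cbind(seq_len(B), target)] - 1
        dlog[!mask, ] <- 0
        dWo <- dWo + crossprod(x, dlog)
        dbo <- dbo + colSums(dlog)
        dlogit_cache[[t]] <- dlog
      }
    } else if (grad) {
      dlogit_cache[[t]] <- matrix(0, B, V)
    }
    if (grad) cache[[t]] <- step
  }
  n_tok <- max(n_tok, 1L)
  if (!grad) return(list(loss = loss / n_tok))

  gl <- lapply(params$layers, function(p) {
    list(W = matrix(0, nrow(p$W), ncol(p$W)),
         U = matrix(0, nrow(p$U), ncol(p$U)),
         b = rep(0, length(p$b)))
  })
  dE <- matrix(0, nrow(params$E), ncol(params$E))
  dh_next <- lapply(seq_len(L), function(l) matrix(0, B, H))
  dc_next <- lapply(seq_len(L), function(l) matrix(0, B, H))
  for (t in rev(seq_len(Tm))) {
    # gradient entering the top hidden state from the output head
    dx_upper <- dlogit_cache[[t]] %*% t(params$Wo)
    for (l in rev(seq_len(L))) {
      s <- cache[[t]][[l]]
      p <- params$layers[[l]]
      dh <- dx_upper + dh_next[[l]]
      dc <- dh * s$o * (1 - s$tc^2) + dc_next[[l]]
      di <- dc * s$g
      df <- dc * s$c_prev
      dg <- dc * s$i
      do_ <- dh * s$tc
      dz <- cbind(di * s$i * (1 - s$i),
                  df * s$f * (1 - s$f),
                  dg * (1 - s$g^2),
                  do_ * s$o * (1 - s$o))
      gl[[l]]$W <- gl[[l]]$W + crossprod(s$x, dz)
      gl[[l]]$U <- gl[[l]]$U + crossprod(s$h_prev, dz)
      gl[[l]]$b <- gl[[l]]$b + colSums(dz)
      dh_next[[l]] <- dz %*% t(p$U)
      dc_next[[l]] <- dc * s$f
      dx_upper <- dz %*% t(p$W)   # into lower layer h (or the embedding)
    }
    dE_rows <- rowsum(dx_upper, group = ids[, t])
    ridx <- as.integer(rownames(dE_rows))
    dE[ridx, ] <- dE[ridx, ] + dE_rows
  }
  scale <- 1 / n_tok
  list(loss = loss / n_tok,
       grads = list(E = dE * scale,
                    layers = lapply(gl, function(g)
                      list(W = g$W * scale, U = g$U * scale,
                           b = g$b * scale)),
                    Wo = dWo * scale, bo = dbo * scale))
}

# Flatten/unflatten parameter trees for the Adam state.
.param_walk <- function(params, grads, fun) {
  params$E <- fun("E", params$E, grads$E)
  for (l in seq_along(params$layers)) {
    for (nm in c("W", "U", "b")) {
      params$layers[[l]][[nm]] <- fun(paste0("L", l, nm),
                                      params$layers[[l]][[nm]],
                                      grads$layers[[l]][[nm]])
    }
  }
  params$Wo <- fun("Wo", params$Wo, grads$Wo)
  params$bo <- fun("bo", params$bo, grads$bo)
  params
}

.adam_new <- function() new.env(parent = emptyenv())

.adam_step <- function(state, params, grads, lr, beta1, beta2, eps = 1e-8) {
  state$t <- (if (is.null(state$t)) 0L else state$t) + 1L
  tt <- state$t
  .param_walk(params, grads, function(key, p, g) {
    m <- state[[paste0("m.", key)]]
    v <- state[[paste0("v.", key)]]
    if (is.null(m)) { m <- p * 0; v <- p * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    state[[paste0("m.", key)]] <- m
    state[[paste0("v.", key)]] <- v
    mh <- m / (1 - beta1^tt)
    vh <- v / (1 - beta2^tt)
    p - lr * mh / (sqrt(vh) + eps)
  })
}

# Train the language model on encoded sequences with early stopping on a
# validation split. Returns params and the loss history.
.lstm_train <- function(ids_train, ids_val, vocab_size, config) {
  params <- .lstm_init(vocab_size, config$embed_size, config$hidden_size,
                       config$n_layers, config$seed)
  state <- .adam_new()
  n <- nrow(ids_train)
  bs <- min(config$batch_size, n)
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  set.seed(config$seed + 1L)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    tr_loss <- 0
    nb <- 0L
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      out <- .lstm_loss_grad(params, ids_train[idx, , drop = FALSE])
      params <- .adam_step(state, params, out$grads, config$learning_rate,
                           config$beta1, config$beta2)
      tr_loss <- tr_loss + out$loss
      nb <- nb + 1L
    }
    val <- if (is.null(ids_val)) NA_real_ else {
      .lstm_loss_grad(params, ids_val, grad = FALSE)$loss
    }
    monitor <- if (is.na(val)) tr_loss / nb else val
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = tr_loss / nb,
                                         val_loss = val))
    if (monitor < best$loss - config$min_delta) {
      best <- list(loss = monitor, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  list(params = best$params, history = history, best_epoch = best$epoch)
}

# Batched ancestral sampling. Returns a character vector of raw generated
# strings (token concatenations, begin/end stripped). `temperature` scales
# the logits; values near zero reduce to greedy argmax decoding.
.lstm_sample <- function(params, vocab, count, max_len, temperature, seed) {
  set.seed(seed)
  V <- length(vocab$tokens)
  H <- nrow(params$Wo)
  L <- length(params$layers)
  out <- character(count)
  chunk <- 512L
  done <- 0L
  while (done < count) {
    B <- min(chunk, count - done)
    h <- lapply(seq_len(L), function(l) matrix(0, B, H))
    cc <- lapply(seq_len(L), function(l) matrix(0, B, H))
    cur <- rep(.BOS, B)
    alive <- rep(TRUE, B)
    seqs <- matrix(.PAD, B, max_len)
    for (t in seq_len(max_len)) {
      x <- params$E[cur, , drop = FALSE]
      for (l in seq_len(L)) {
        p <- params$layers[[l]]
        z <- x %*% p$W + h[[l]] %*% p$U +
          matrix(p$b, B, 4L * H, byrow = TRUE)
        i <- .sigmoid(z[, seq_len(H), drop = FALSE])
        f <- .sigmoid(z[, H + seq_len(H), drop = FALSE])
        g <- tanh(z[, 2L * H + seq_len(H), drop = FALSE])
        o <- .sigmoid(z[, 3L * H + seq_len(H), drop = FALSE])
        cc[[l]] <- f * cc[[l]] + i * g
        h[[l]] <- o * tanh(cc[[l]])
        x <- h[[l]]
      }
      logits <- x %*% params$Wo + matrix(params$bo, B, V, byrow = TRUE)
      logits[, .PAD] <- -Inf
      logits[, .BOS] <- -Inf
      nxt <- integer(B)
      if (temperature < 1e-6) {
        nxt <- max.col(logits, ties.method = "first")
      } else {
        sl <- logits / temperature
        m <- apply(sl, 1L, max)
        pr <- exp(sl - m)
        pr <- pr / rowSums(pr)
        for (b in seq_len(B)) {
          nxt[b] <- sample.int(V, 1L, prob = pr[b, ])
        }
      }
      nxt[!alive] <- .PAD
      seqs[, t] <- nxt
      alive <- alive & nxt != .EOS
      cur <- ifelse(nxt == .PAD, .EOS, nxt)  # frozen rows feed a dummy token
      if (!any(alive)) break
    }
    for (b in seq_len(B)) {
      row <- seqs[b, ]
      stop_at <- which(row == .EOS)
      keep <- if (length(stop_at)) row[seq_len(stop_at[1L] - 1L)] else row
      out[done + b] <- decode_ids(keep, vocab)
    }
    done <- done + B
  }
  out
}
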