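#' Sequence-model configuration
#'
#' Architecture of the recurrent classifier: a first recurrent layer
#' reading the 7-step audiogram sequence (bidirectional by default, with
#' forward and backward passes concatenated), a dropout layer, a second
#' unidirectional LSTM layer whose final hidden state feeds a dense softmax
#' output over the four classes. Training minimizes class-weighted
#' cross-entropy with Adam, mini-batches, and early stopping on a held-out
#' validation split of the training data.
#'
#' @param architecture `"bilstm"` (bidirectional first layer) or `"lstm"`.
#' @param units1,units2 Recurrent units in layers 1 and 2 (defaults 64, 32;
#'   a bidirectional layer 1 has `units1` per direction).
#' @param dropout Two dropout rates in `[0, 1)` applied after layers 1 and
#'   2 (default 0.2, 0.2).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size Mini-batch size (default 32).
#' @param max_epochs Maximum training epochs (default 150).
#' @param patience Early-stopping patience on validation loss (default 10).
#' @param val_fraction Fraction of the training data held out as the
#'   early-stopping validation split (default 0.1).
#' @param use_mask_channel Add the bone-present flags as a third input
#'   channel (default `FALSE`, matching the two-feature encoding).
#' @param seed Integer seed driving initialization, shuffling, the
#'   validation split and dropout.
#' @return A list of class `model_config`.
#' @export
model_config <- function(architecture = c("bilstm", "lstm"),
                         units1 = 64L, units2 = 32L,
                         dropout = c(0.2, 0.2),
                         learning_rate = 1e-3, batch_size = 32L,
                         max_epochs = 150L, patience = 10L,
                         val_fraction = 0.1,
                         use_mask_channel = FALSE,
                         seed = 1L) {
  architecture <- match.arg(architecture)
  stopifnot(units1 >= 1, units2 >= 1, length(dropout) == 2,
            all(dropout >= 0 & dropout < 1),
            learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1, val_fraction > 0, val_fraction < 0.5)
  cfg <- list(architecture = architecture, units1 = as.integer(units1),
              units2 = as.integer(units2), dropout = dropout,
              learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience),
              val_fraction = val_fraction,
              use_mask_channel = isTRUE(use_mask_channel),
              seed = as.integer(seed))
  class(cfg) <- "model_config"
  cfg
}

## ---- LSTM primitives (pure R, batch-vectorized) -------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

init_lstm <- function(D, H) {
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1            # forget-gate bias at 1
  list(Wx = glorot(D, 4 * H), Wh = glorot(H, 4 * H), b = b)
}

# X: B x T x D array. Returns hidden states (B x T x H) and caches for BPTT.
lstm_forward <- function(p, X, keep_cache = TRUE) {
  B <- dim(X)[1]; Tn <- dim(X)[2]; D <- dim(X)[3]
  H <- nrow(p$Wh)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  Hs <- array(0, dim = c(B, Tn, H))
  cache <- if (keep_cache) vector("list", Tn) else NULL
  bmat <- matrix(p$b, B, 4 * H, byrow = TRUE)
  for (t in seq_len(Tn)) {
    xt <- matrix(X[, t, ], B, D)
    z <- xt %*% p$Wx + h %*% p$Wh + bmat
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    if (keep_cache)
      cache[[t]] <- list(xt = xt, h_prev = h, c_prev = cc, i = i, f = f,
                         g = g, o = o, tc = tc)
    h <- h_new; cc <- c_new
    Hs[, t, ] <- h
  }
  list(H = Hs, cache = cache)
}

# dH: B x T x H gradient on the hidden-state outputs.
lstm_backward <- function(p, X, fwd, dH) {
  B <- dim(X)[1]; Tn <- dim(X)[2]; D <- dim(X)[3]
  H <- nrow(p$Wh)
  dWx <- matrix(0, D, 4 * H); dWh <- matrix(0, H, 4 * H); db <- numeric(4 * H)
  dX <- array(0, dim = c(B, Tn, D))
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  for (t in rev(seq_len(Tn))) {
    ca <- fwd$cache[[t]]
    dh <- matrix(dH[, t, ], B, H) + dh_next
    do <- dh * ca$tc
    dc <- dc_next + dh * ca$o * (1 - ca$tc^2)
    df <- dc * ca$c_prev
    di <- dc * ca$g
    dg <- dc * ca$i
    dc_next <- dc * ca$f
    dz <- cbind(di * ca$i * (1 - ca$i),
                df * ca$f * (1 - ca$f),
                dg * (1 - ca$g^2),
                do * ca$o * (1 - ca$o))
    dWx <- dWx + crossprod(ca$xt, dz)
    dWh <- dWh + crossprod(ca$h_prev, dz)
    db <- db + colSums(dz)
    dX[, t, ] <- dz %*% t(p$Wx)
    dh_next <- dz %*% t(p$Wh)
  }
  list(Wx = dWx, Wh = dWh, b = db, dX = dX)
}

rev_time <- function(X) X[, rev(seq_len(dim(X)[2])), , drop = FALSE]

## ---- network assembly ----------------------------------------------------

init_network <- function(cfg, D) {
  H1 <- cfg$units1; H2 <- cfg$units2
  p <- list(l1f = init_lstm(D, H1))
  feat1 <- H1
  if (cfg$architecture == "bilstm") {
    p$l1b <- init_lstm(D, H1)
    feat1 <- 2L * H1
  }
  p$l2 <- init_lstm(feat1, H2)
  p$Wd <- glorot(H2, 4L)
  p$bd <- numeric(4L)
  p
}

# Forward pass; when training, drop1/drop2 are inverted-dropout masks.
net_forward <- function(p, cfg, X, drop1 = NULL, drop2 = NULL,
                        keep_cache = FALSE) {
  f1 <- lstm_forward(p$l1f, X, keep_cache)
  if (cfg$architecture == "bilstm") {
    Xr <- rev_time(X)
    b1 <- lstm_forward(p$l1b, Xr, keep_cache)
    H1 <- abind3(f1$H, rev_time(b1$H))
  } else {
    b1 <- NULL
    H1 <- f1$H
  }
  H1d <- if (is.null(drop1)) H1 else H1 * drop1
  f2 <- lstm_forward(p$l2, H1d, keep_cache)
  B <- dim(X)[1]; Tn <- dim(X)[2]
  h_last <- matrix(f2$H[, Tn, ], B, cfg$units2)
  h_last_d <- if (is.null(drop2)) h_last else h_last * drop2
  logits <- h_last_d %*% p$Wd + matrix(p$bd, B, 4L, byrow = TRUE)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  P <- e / rowSums(e)
  list(P = P, f1 = f1, b1 = b1, H1 = H1, H1d = H1d, f2 = f2,
       h_last = h_last, h_last_d = h_last_d)
}

abind3 <- function(a, b) {
  d <- dim(a)
  out <- array(0, dim = c(d[1], d[2], d[3] + dim(b)[3]))
  out[, , seq_len(d[3])] <- a
  out[, , d[3] + seq_len(dim(b)[3])] <- b
  out
}

# Gradient of the weighted cross-entropy wrt all parameters.
net_backward <- function(p, cfg, X, fwd, Y, w, drop1, drop2) {
  B <- dim(X)[1]; Tn <- dim(X)[2]
  wsum <- sum(w)
  dlogits <- (fwd$P - Y) * (w / wsum)
  g <- list()
  g$Wd <- crossprod(fwd$h_last_d, dlogits)
  g$bd <- colSums(dlogits)
  dh_last <- dlogits %*% t(p$Wd)
  if (!is.null(drop2)) dh_last <- dh_last * drop2
  dH2 <- array(0, dim = dim(fwd$f2$H))
  dH2[, Tn, ] <- dh_last
  bk2 <- lstm_backward(p$l2, fwd$H1d, fwd$f2, dH2)
  g$l2 <- bk2[c("Wx", "Wh", "b")]
  dH1 <- bk2$dX
  if (!is.null(drop1)) dH1 <- dH1 * drop1
  H1f <- cfg$units1
  dHf <- dH1[, , seq_len(H1f), drop = FALSE]
  bkf <- lstm_backward(p$l1f, X, fwd$f1, dHf)
  g$l1f <- bkf[c("Wx", "Wh", "b")]
  if (cfg$architecture == "bilstm") {
    dHb <- rev_time(dH1[, , H1f + seq_len(H1f), drop = FALSE])
    bkb <- lstm_backward(p$l1b, rev_time(X), fwd$b1, dHb)
    g$l1b <- bkb[c("Wx", "Wh", "b")]
  }
  g
}

weighted_ce <- function(P, y_idx, w) {
  eps <- 1e-12
  -sum(w * log(pmax(P[cbind(seq_along(y_idx), y_idx)], eps))) / sum(w)
}

## ---- Adam ----------------------------------------------------------------

flatten_params <- function(p) {
  out <- list()
  walk <- function(x, prefix) {
    if (is.list(x)) for (nm in names(x)) walk(x[[nm]], paste0(prefix, ".", nm))
    else out[[substring(prefix, 2)]] <<- x
  }
  walk(p, "")
  out
}

adam_step <- function(p, g, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  fp <- flatten_params(p); fg <- flatten_params(g)
  for (nm in names(fg)) {
    grad <- fg[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grad
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grad^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    fp[[nm]] <- fp[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  # write back into the nested structure
  p2 <- p
  for (nm in names(fg)) {
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(path) == 1L) p2[[path]] <- fp[[nm]]
    else p2[[path[1]]][[path[2]]] <- fp[[nm]]
  }
  list(p = p2, state = state)
}

init_adam <- function(p) {
  fp <- flatten_params(p)
  list(m = lapply(fp, function(x) x * 0), v = lapply(fp, function(x) x * 0))
}

## ---- training ------------------------------------------------------------

labels_to_index <- function(labels) {
  lv <- hearing_loss_levels(clinical_only = TRUE)
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), lv)
  if (length(bad))
    stop("labels outside the clinical classes: ", paste(bad, collapse = ", "))
  match(labels, lv)
}

model_input <- function(enc, cfg) {
  stopifnot(inherits(enc, "encoded_sequences"))
  if (!cfg$use_mask_channel) return(enc$x)
  d <- dim(enc$x)
  X <- array(0, dim = c(d[1], d[2], 3))
  X[, , 1:2] <- enc$x
  X[, , 3] <- enc$bone_present * 1
  X
}

#' Train the recurrent sequence classifier
#'
#' Trains the (Bi-)LSTM of [model_config()] on normalized, encoded
#' audiogram sequences, minimizing class-weighted cross-entropy with Adam.
#' A validation split of the training data drives early stopping: training
#' halts once validation loss has not improved for `patience` epochs, and
#' the best-validation weights are restored. All stochastic elements
#' (weight initialization, shuffling, the split, dropout) are driven by
#' `cfg$seed`; the same data, configuration and seed reproduce the model
#' exactly.
#'
#' @param enc An `encoded_sequences` object from [apply_normalizer()].
#' @param labels Clinical class labels, parallel to the sequences.
#' @param class_weights Optional named weights from
#'   [compute_class_weights()]; `NULL` = unweighted.
#' @param cfg A [model_config()].
#' @return A list of class `audiotype_model` with the trained parameters,
#'   configuration, normalization tag and training history (epochs run,
#'   per-epoch train/validation loss).
#' @export
train_sequence_model <- function(enc, labels, class_weights = NULL,
                                 cfg = model_config()) {
  X <- model_input(enc, cfg)
  y_idx <- labels_to_index(labels)
  n <- dim(X)[1]
  if (length(y_idx) != n) stop("labels length must match sequence count")
  if (n < 4L) stop("need at least 4 training sequences")
  lv <- hearing_loss_levels(clinical_only = TRUE)
  w_class <- if (is.null(class_weights)) stats::setNames(rep(1, 4), lv)
             else class_weights[lv]
  if (anyNA(w_class)) stop("class_weights must be named by the four classes")
  w <- as.numeric(w_class[y_idx])
  Y <- matrix(0, n, 4); Y[cbind(seq_len(n), y_idx)] <- 1

  with_private_seed(cfg$seed, {
    D <- dim(X)[3]
    p <- init_network(cfg, D)
    state <- init_adam(p)
    n_val <- max(1L, round(cfg$val_fraction * n))
    val_idx <- sample(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (length(tr_idx) < 2L) stop("training split too small")
    Xv <- X[val_idx, , , drop = FALSE]
    yv <- y_idx[val_idx]; wv <- w[val_idx]

    best <- list(loss = Inf, p = p, epoch = 0L)
    hist_tr <- numeric(0); hist_val <- numeric(0)
    tstep <- 0L
    stale <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0; ep_w <- 0
      for (start in seq(1L, length(ord), by = cfg$batch_size)) {
        bi <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        Xb <- X[bi, , , drop = FALSE]
        B <- length(bi); Tn <- dim(Xb)[2]
        feat1 <- if (cfg$architecture == "bilstm") 2L * cfg$units1 else cfg$units1
        drop1 <- if (cfg$dropout[1] > 0)
          array(stats::rbinom(B * Tn * feat1, 1, 1 - cfg$dropout[1]) /
                  (1 - cfg$dropout[1]), dim = c(B, Tn, feat1)) else NULL
        drop2 <- if (cfg$dropout[2] > 0)
          matrix(stats::rbinom(B * cfg$units2, 1, 1 - cfg$dropout[2]) /
                   (1 - cfg$dropout[2]), B, cfg$units2) else NULL
        fwd <- net_forward(p, cfg, Xb, drop1, drop2, keep_cache = TRUE)
        loss <- weighted_ce(fwd$P, y_idx[bi], w[bi])
        if (!is.finite(loss)) stop("non-finite training loss at epoch ", epoch)
        g <- net_backward(p, cfg, Xb, fwd, Y[bi, , drop = FALSE], w[bi],
                          drop1, drop2)
        tstep <- tstep + 1L
        upd <- adam_step(p, g, state, cfg$learning_rate, tstep)
        p <- upd$p; state <- upd$state
        ep_loss <- ep_loss + loss * sum(w[bi]); ep_w <- ep_w + sum(w[bi])
      }
      val_fwd <- net_forward(p, cfg, Xv)
      val_loss <- weighted_ce(val_fwd$P, yv, wv)
      hist_tr <- c(hist_tr, ep_loss / ep_w)
      hist_val <- c(hist_val, val_loss)
      if (val_loss < best$loss - 1e-5) {
        best <- list(loss = val_loss, p = p, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= cfg$patience) break
      }
    }
    model <- list(params = best$p, config = cfg,
                  norm_method = enc$method,
                  classes = lv,
                  history = list(epochs_run = length(hist_tr),
                                 best_epoch = best$epoch,
                                 train_loss = hist_tr,
                                 val_loss = hist_val))
    class(model) <- "audiotype_model"
    model
  })
}

#' Class-probability predictions
#'
#' Deterministic forward pass (no dropout); each output row is a point on
#' the 4-class probability simplex.
#'
#' @param model A trained `audiotype_model`.
#' @param enc An `encoded_sequences` object normalized with the same
#'   scheme the model was trained with.
#' @param chunk Number of sequences per forward pass (memory control).
#' @return An n x 4 matrix of probabilities, columns in fixed class order.
#' @export
predict_proba <- function(model, enc, chunk = 2048L) {
  stopifnot(inherits(model, "audiotype_model"))
  if (!inherits(enc, "encoded_sequences"))
    stop("input must be encoded_sequences (run apply_normalizer first)")
  if (!identical(enc$method, model$norm_method))
    stop(sprintf("normalization mismatch: model trained with '%s', input is '%s'",
                 model$norm_method, enc$method))
  X <- model_input(enc, model$config)
  n <- dim(X)[1]
  P <- matrix(0, n, 4,
              dimnames = list(NULL, model$classes))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fwd <- net_forward(model$params, model$config,
                       X[idx, , , drop = FALSE])
    P[idx, ] <- fwd$P
  }
  P
}

#' Hard label predictions
#'
#' Argmax of [predict_proba()]; exact ties resolve to the first class in
#' fixed order (normal, conductive, mixed, sensorineural).
#'
#' @inheritParams predict_proba
#' @return Factor of predicted labels.
#' @export
predict_label <- function(model, enc) {
  P <- predict_proba(model, enc)
  proba_to_label(P)
}

#' Convert a probability matrix to labels
#'
#' @param P n x 4 probability matrix in fixed class order.
#' @return Factor of labels; ties go to the earlier class.
#' @export
proba_to_label <- function(P) {
  lv <- hearing_loss_levels(clinical_only = TRUE)
  factor(lv[max.col(P, ties.method = "first")], levels = lv)
}
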