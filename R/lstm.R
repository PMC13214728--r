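#' Classifier hyperparameters
#'
#' Defaults mirror the reference configuration: a single 50-unit LSTM
#' layer (tanh), 20% dropout, batch normalization, a 3-unit softmax
#' head, Adam at learning rate 0.001, batch size 32, up to 100 epochs
#' with early stopping on validation loss.
#'
#' @param window_length Sliding-window length T.
#' @param hidden_units LSTM hidden-state size.
#' @param dropout Dropout rate on the final hidden state, in \[0, 1).
#' @param batch_norm Apply batch normalization before the dense head.
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param val_frac Fraction of training participants held out for
#'   validation (grouped by participant to stay subject-aware).
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return List of class `"hyperparams"`.
#' @export
hyperparams <- function(window_length = 10, hidden_units = 50,
                        dropout = 0.2, batch_norm = TRUE,
                        learning_rate = 0.001, batch_size = 32,
                        max_epochs = 100, patience = 10,
                        val_frac = 0.1, seed = 1) {
  stopifnot(window_length > 0, hidden_units > 0,
            dropout >= 0, dropout < 1, learning_rate > 0,
            batch_size > 0, max_epochs > 0, patience > 0,
            val_frac >= 0, val_frac < 1)
  structure(as.list(environment()), class = "hyperparams")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_init <- function(F_, H) {
  k <- 1 / sqrt(H)
  u <- function(nr, nc) matrix(stats::runif(nr * nc, -k, k), nr, nc)
  b <- rep(0, 4 * H)
  b[(H + 1):(2 * H)] <- 1  # forget-gate bias
  list(Wx = u(F_, 4 * H), Wh = u(H, 4 * H), b = b,
       Wd = u(H, 3), bd = rep(0, 3),
       gamma = rep(1, H), beta = rep(0, H),
       run_mean = rep(0, H), run_var = rep(1, H))
}

lstm_forward <- function(p, X, H, train = FALSE, dropout = 0,
                         batch_norm = TRUE, bn_momentum = 0.9) {
  n <- dim(X)[1]; T_ <- dim(X)[2]
  h <- matrix(0, n, H); c_ <- matrix(0, n, H)
  cache <- if (train) vector("list", T_) else NULL
  for (t in seq_len(T_)) {
    Xt <- matrix(X[, t, ], n)
    Z <- Xt %*% p$Wx + h %*% p$Wh
    Z <- sweep(Z, 2, p$b, `+`)
    i <- sigmoid(Z[, 1:H, drop = FALSE])
    f <- sigmoid(Z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(Z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(Z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- c_
    c_ <- f * c_prev + i * g
    tc <- tanh(c_)
    h_prev <- h
    h <- o * tc
    if (train) cache[[t]] <- list(Xt = Xt, i = i, f = f, g = g, o = o,
                                  c_prev = c_prev, tc = tc,
                                  h_prev = h_prev)
  }
  hT <- h
  mask <- NULL
  if (train && dropout > 0) {
    mask <- matrix(stats::rbinom(n * H, 1, 1 - dropout) / (1 - dropout),
                   n, H)
    hT <- hT * mask
  }
  bn <- NULL
  if (batch_norm) {
    eps <- 1e-5
    if (train) {
      mu <- colMeans(hT)
      va <- colMeans(sweep(hT, 2, mu)^2)
      p$run_mean <- bn_momentum * p$run_mean + (1 - bn_momentum) * mu
      p$run_var <- bn_momentum * p$run_var + (1 - bn_momentum) * va
    } else {
      mu <- p$run_mean; va <- p$run_var
    }
    xhat <- sweep(sweep(hT, 2, mu), 2, sqrt(va + eps), `/`)
    y <- sweep(sweep(xhat, 2, p$gamma, `*`), 2, p$beta, `+`)
    bn <- list(xhat = xhat, mu = mu, va = va, eps = eps, x_in = hT)
  } else {
    y <- hT
  }
  logits <- sweep(y %*% p$Wd, 2, p$bd, `+`)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  prob <- e / rowSums(e)
  list(prob = prob, params = p, cache = cache, hT_raw = h, mask = mask,
       bn = bn, y = y)
}

lstm_backward <- function(p, fw, X, y_true, H, batch_norm = TRUE) {
  n <- dim(X)[1]; T_ <- dim(X)[2]
  grads <- list(Wx = 0 * p$Wx, Wh = 0 * p$Wh, b = 0 * p$b,
                Wd = 0 * p$Wd, bd = 0 * p$bd,
                gamma = 0 * p$gamma, beta = 0 * p$beta)
  dlogits <- fw$prob
  dlogits[cbind(seq_len(n), y_true + 1L)] <-
    dlogits[cbind(seq_len(n), y_true + 1L)] - 1
  dlogits <- dlogits / n
  grads$Wd <- crossprod(fw$y, dlogits)
  grads$bd <- colSums(dlogits)
  dy <- tcrossprod(dlogits, p$Wd)
  if (batch_norm) {
    bn <- fw$bn
    grads$beta <- colSums(dy)
    grads$gamma <- colSums(dy * bn$xhat)
    dxhat <- sweep(dy, 2, p$gamma, `*`)
    inv_sd <- 1 / sqrt(bn$va + bn$eps)
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * bn$xhat)
    dh <- sweep(
      dxhat - sweep(matrix(1, n, 1) %*% t(s1), 2, rep(n, H), `/`) -
        sweep(bn$xhat, 2, s2 / n, `*`),
      2, inv_sd, `*`)
  } else {
    dh <- dy
  }
  if (!is.null(fw$mask)) dh <- dh * fw$mask
  dc_next <- matrix(0, n, H)
  dh_rec <- dh
  for (t in rev(seq_len(T_))) {
    cc <- fw$cache[[t]]
    dht <- dh_rec
    do_ <- dht * cc$tc
    dct <- dht * cc$o * (1 - cc$tc^2) + dc_next
    di <- dct * cc$g
    dg <- dct * cc$i
    df <- dct * cc$c_prev
    dc_next <- dct * cc$f
    dZ <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    grads$Wx <- grads$Wx + crossprod(cc$Xt, dZ)
    grads$Wh <- grads$Wh + crossprod(cc$h_prev, dZ)
    grads$b <- grads$b + colSums(dZ)
    dh_rec <- tcrossprod(dZ, p$Wh)
  }
  grads
}

adam_step <- function(p, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(p = p, state = state)
}

ce_loss <- function(prob, y) {
  -mean(log(pmax(prob[cbind(seq_along(y), y + 1L)], 1e-12)))
}

#' Train the LSTM cognitive-state classifier
#'
#' Single recurrent layer (tanh gates), dropout on the final hidden
#' state, batch normalization, 3-unit softmax head trained with
#' integer-label cross-entropy and Adam. A participant-grouped
#' validation split drives early stopping; the parameters from the best
#' validation-loss epoch are restored. When the training set has too
#' few participants for a split, a random window split is used instead.
#'
#' @param x Array n x T x F of training windows.
#' @param y Integer labels (0, 1, 2).
#' @param pid Participant id per window (for the grouped validation
#'   split).
#' @param hp A [hyperparams()].
#' @param verbose Print per-epoch losses.
#' @return List of class `"lstm_model"` with the learned parameters.
#' @export
train_lstm <- function(x, y, pid = NULL, hp = hyperparams(),
                       verbose = FALSE) {
  stopifnot(length(dim(x)) == 3, dim(x)[1] == length(y))
  if (length(unique(y)) < 3) {
    stop("training set must contain at least one window per class")
  }
  set.seed(hp$seed)
  n <- dim(x)[1]; F_ <- dim(x)[3]; H <- hp$hidden_units
  # participant-grouped validation split
  val_idx <- integer(0)
  if (hp$val_frac > 0) {
    if (!is.null(pid) && length(unique(pid)) >= 3) {
      ids <- unique(pid)
      n_val <- max(1, round(hp$val_frac * length(ids)))
      val_ids <- sample(ids, n_val)
      val_idx <- which(pid %in% val_ids)
      if (length(unique(y[-val_idx])) < 3) val_idx <- integer(0)
    }
    if (length(val_idx) == 0) {
      val_idx <- sample(n, max(1, round(hp$val_frac * n)))
    }
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  p <- lstm_init(F_, H)
  zero <- lapply(p[c("Wx", "Wh", "b", "Wd", "bd", "gamma", "beta")],
                 function(z) 0 * z)
  state <- list(m = zero, v = zero)
  best <- list(loss = Inf, p = p, epoch = 0)
  step <- 0
  wait <- 0
  for (epoch in seq_len(hp$max_epochs)) {
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / hp$batch_size))
    for (bi in batches) {
      Xb <- x[bi, , , drop = FALSE]
      fw <- lstm_forward(p, Xb, H, train = TRUE, dropout = hp$dropout,
                         batch_norm = hp$batch_norm)
      p <- fw$params  # running BN statistics updated in-place
      grads <- lstm_backward(p, fw, Xb, y[bi], H, hp$batch_norm)
      step <- step + 1
      up <- adam_step(p, grads, state, hp$learning_rate, step)
      # keep BN running stats through the optimizer update
      up$p$run_mean <- p$run_mean; up$p$run_var <- p$run_var
      p <- up$p; state <- up$state
    }
    mon_idx <- if (length(val_idx) > 0) val_idx else tr_idx
    mon <- lstm_forward(p, x[mon_idx, , , drop = FALSE], H,
                        train = FALSE, batch_norm = hp$batch_norm)
    mon_loss <- ce_loss(mon$prob, y[mon_idx])
    if (verbose) {
      message(sprintf("epoch %3d  monitored loss %.4f", epoch, mon_loss))
    }
    if (mon_loss < best$loss - 1e-6) {
      best <- list(loss = mon_loss, p = p, epoch = epoch)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= hp$patience) break
    }
  }
  structure(list(params = best$p, hp = hp, val_loss = best$loss,
                 best_epoch = best$epoch, n_features = F_),
            class = "lstm_model")
}

#' Predict class probabilities with a trained LSTM
#'
#' @param model An `"lstm_model"` from [train_lstm()].
#' @param x Array n x T x F.
#' @return n x 3 matrix of softmax class probabilities.
#' @export
predict_lstm <- function(model, x) {
  fw <- lstm_forward(model$params, x, model$hp$hidden_units,
                     train = FALSE, batch_norm = model$hp$batch_norm)
  fw$prob
}
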