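# Phase 2: the supervised recurrent backbone. A token embedding feeds a
# recurrent layer (GRU / BiGRU / LSTM / BiLSTM); the final hidden state
# passes through a dense relu stack with dropout and a one-unit sigmoid
# head trained on binary cross-entropy. The latent representation handed to
# the clustering predictor is the activation of a configurable internal
# layer (default: the fourth feature layer, width 32 under the default
# stack).

#' Single GRU cell parameters
#'
#' Holds the update-gate, reset-gate and candidate-state weights of one
#' gated recurrent unit in the row-vector convention: for an input row
#' vector `x_t` (length `input_dim`) and hidden row vector `h_prev`
#' (length `hidden_dim`),
#' \deqn{z_t = \sigma(x_t W_z + h_{t-1} V_z + b_z)}
#' \deqn{r_t = \sigma(x_t W_r + h_{t-1} V_r + b_r)}
#' \deqn{\hat{C}_t = \tanh(x_t W_C + (r_t \odot h_{t-1}) V_C + b_C)}
#' \deqn{h_t = z_t \odot h_{t-1} + (1 - z_t) \odot \hat{C}_t}
#'
#' @param W_z,W_r,W_C `input_dim x hidden_dim` input weight matrices.
#' @param V_z,V_r,V_C `hidden_dim x hidden_dim` recurrent weight matrices.
#' @param b_z,b_r,b_C Bias vectors of length `hidden_dim`.
#' @return A validated parameter list of class `gmean_gru_params`.
#' @export
gru_params <- function(W_z, V_z, b_z, W_r, V_r, b_r, W_C, V_C, b_C) {
  W <- list(W_z = W_z, W_r = W_r, W_C = W_C)
  V <- list(V_z = V_z, V_r = V_r, V_C = V_C)
  b <- list(b_z = b_z, b_r = b_r, b_C = b_C)
  H <- ncol(W_z)
  E <- nrow(W_z)
  for (nm in names(W)) {
    if (!is.matrix(W[[nm]]) || !identical(dim(W[[nm]]), c(E, H))) {
      stopf("gru_params: %s must be a %d x %d matrix", nm, E, H)
    }
  }
  for (nm in names(V)) {
    if (!is.matrix(V[[nm]]) || !identical(dim(V[[nm]]), c(H, H))) {
      stopf("gru_params: %s must be a %d x %d matrix", nm, H, H)
    }
  }
  for (nm in names(b)) {
    if (length(b[[nm]]) != H) stopf("gru_params: %s must have length %d", nm, H)
  }
  all_par <- c(W, V, b)
  if (!all(vapply(all_par, function(p) all(is.finite(p)), logical(1)))) {
    stopf("gru_params: all entries must be finite")
  }
  structure(c(all_par, list(input_dim = E, hidden_dim = H)),
            class = "gmean_gru_params")
}

#' One GRU cell step
#'
#' Evaluates the update gate, reset gate, candidate hidden state and new
#' hidden state for a single time step (see [gru_params()] for the
#' equations). The update gate interpolates between retaining the old state
#' (`z` near 1) and adopting the candidate state (`z` near 0), so `h_t`
#' always lies componentwise between `h_prev` and the candidate.
#'
#' @param x_t Input vector (length `input_dim`).
#' @param h_prev Previous hidden state (length `hidden_dim`).
#' @param params A [gru_params()] object.
#' @return List of class `gmean_gru_state` with `x_t`, `h_prev`, `z_t`,
#'   `r_t`, `C_hat_t`, `h_t`.
#' @export
gru_cell_step <- function(x_t, h_prev, params) {
  stopifnot(inherits(params, "gmean_gru_params"))
  if (length(x_t) != params$input_dim) {
    stopf("gru_cell_step: x_t has length %d, expected %d",
          length(x_t), params$input_dim)
  }
  if (length(h_prev) != params$hidden_dim) {
    stopf("gru_cell_step: h_prev has length %d, expected %d",
          length(h_prev), params$hidden_dim)
  }
  x <- matrix(x_t, nrow = 1L)
  h <- matrix(h_prev, nrow = 1L)
  z <- sigmoid(drop(x %*% params$W_z + h %*% params$V_z) + params$b_z)
  r <- sigmoid(drop(x %*% params$W_r + h %*% params$V_r) + params$b_r)
  C_hat <- tanh(drop(x %*% params$W_C +
                       matrix(r * h_prev, nrow = 1L) %*% params$V_C) +
                  params$b_C)
  h_t <- z * h_prev + (1 - z) * C_hat
  structure(list(x_t = x_t, h_prev = h_prev, z_t = z, r_t = r,
                 C_hat_t = C_hat, h_t = h_t),
            class = "gmean_gru_state")
}

#' Backbone architecture configuration
#'
#' @param vocab_size Number of k-mer ids (the reserved id 0 is handled
#'   automatically).
#' @param embedding_dim Width of the learned token embedding.
#' @param gru_units Hidden units of the recurrent layer (per direction for
#'   bidirectional kinds).
#' @param dense_units Widths of the dense relu stack between the recurrent
#'   layer and the sigmoid head.
#' @param dropout_rate Dropout probability applied after each dense relu
#'   activation during training.
#' @param latent_layer_index 1-based index into the feature layers
#'   `[recurrent, dense_1, ..., dense_m]` whose activation is the latent
#'   representation; the default 4 selects `dense_3` (width 32 under the
#'   default stack).
#' @param backbone_kind One of `"gru"`, `"bigru"`, `"lstm"`, `"bilstm"`.
#' @param input_encoding `"embedding"` (learned, default) or `"onehot"`
#'   (fixed indicator rows of width `vocab_size + 1`).
#' @param max_timescale Upper bound (in time steps) of the log-spread
#'   retention-gate bias initialization; set to the typical tokenized
#'   sequence length so the recurrent state carries evidence across the
#'   whole sequence from the first epoch.
#' @return A config list of class `gmean_backbone_config`.
#' @export
backbone_config <- function(vocab_size,
                            embedding_dim = 32L,
                            gru_units = 200L,
                            dense_units = c(128L, 64L, 32L, 16L),
                            dropout_rate = 0.2,
                            latent_layer_index = 4L,
                            backbone_kind = c("gru", "bigru", "lstm", "bilstm"),
                            input_encoding = c("embedding", "onehot"),
                            max_timescale = 100L) {
  backbone_kind <- match.arg(backbone_kind)
  input_encoding <- match.arg(input_encoding)
  stopifnot(is_count(vocab_size), is_count(gru_units),
            all(vapply(dense_units, is_count, logical(1))))
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stopf("backbone_config: dropout_rate must lie in [0, 1)")
  }
  n_feature_layers <- 1L + length(dense_units)
  if (!is_count(latent_layer_index) || latent_layer_index > n_feature_layers) {
    stopf("backbone_config: latent_layer_index must lie in 1..%d",
          n_feature_layers)
  }
  if (input_encoding == "onehot") embedding_dim <- vocab_size + 1L
  structure(list(vocab_size = as.integer(vocab_size),
                 embedding_dim = as.integer(embedding_dim),
                 gru_units = as.integer(gru_units),
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate,
                 latent_layer_index = as.integer(latent_layer_index),
                 backbone_kind = backbone_kind,
                 input_encoding = input_encoding,
                 max_timescale = max(1L, as.integer(max_timescale))),
            class = "gmean_backbone_config")
}

backbone_is_bidirectional <- function(config) {
  config$backbone_kind %in% c("bigru", "bilstm")
}

backbone_cell_kind <- function(config) {
  if (config$backbone_kind %in% c("gru", "bigru")) "gru" else "lstm"
}

backbone_directions <- function(config) {
  if (backbone_is_bidirectional(config)) c("f", "b") else "f"
}

glorot_uniform <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# Random orthogonal H x H matrix (QR of a Gaussian with sign correction);
# recurrent kernels are initialized orthogonally, gate blocks side by side,
# which preserves state norms over long sequences.
random_orthogonal <- function(H) {
  qr_ <- qr(matrix(stats::rnorm(H * H), H, H))
  Q <- qr.Q(qr_)
  Q %*% diag(sign(diag(qr.R(qr_))), H)
}

orthogonal_blocks <- function(H, n_blocks) {
  do.call(cbind, replicate(n_blocks, random_orthogonal(H), simplify = FALSE))
}

init_backbone_params <- function(config, seed = 1L) {
  with_seed(seed, {
    E <- config$embedding_dim
    H <- config$gru_units
    cell <- backbone_cell_kind(config)
    params <- list()
    params$emb <- if (config$input_encoding == "onehot") {
      diag(1, config$vocab_size + 1L, E)
    } else {
      matrix(stats::runif((config$vocab_size + 1L) * E, -0.05, 0.05),
             config$vocab_size + 1L, E)
    }
    # Retention gates initialize to a log-spread spectrum of timescales
    # (1 .. max_timescale steps, chrono-style): with ~100-step sequences a
    # neutral gate forgets early-sequence evidence before the final state,
    # and training stalls at chance for many epochs before escaping.
    timescales <- function() log(stats::runif(H, 1, config$max_timescale))
    for (dir in backbone_directions(config)) {
      if (cell == "gru") {
        params[[paste0("W_", dir)]] <- glorot_uniform(E, 3L * H)
        params[[paste0("Uzr_", dir)]] <- orthogonal_blocks(H, 2L)
        params[[paste0("Uc_", dir)]] <- random_orthogonal(H)
        b <- numeric(3L * H)
        b[1L:H] <- timescales()  # update gate: state retention
        params[[paste0("b_", dir)]] <- b
      } else {
        params[[paste0("W_", dir)]] <- glorot_uniform(E, 4L * H)
        params[[paste0("U_", dir)]] <- orthogonal_blocks(H, 4L)
        b <- numeric(4L * H)
        b[(H + 1L):(2L * H)] <- timescales()  # forget gate: cell retention
        b[1L:H] <- -b[(H + 1L):(2L * H)]      # input gate balances it
        params[[paste0("b_", dir)]] <- b
      }
    }
    d_in <- H * length(backbone_directions(config))
    for (j in seq_along(config$dense_units)) {
      d_out <- config$dense_units[j]
      params[[paste0("Wd_", j)]] <- glorot_uniform(d_in, d_out)
      params[[paste0("bd_", j)]] <- numeric(d_out)
      d_in <- d_out
    }
    params$W_out <- glorot_uniform(d_in, 1L)
    params$b_out <- 0
    params
  })
}

#' Build a backbone model
#'
#' Constructs the architecture token embedding -> recurrent layer (final
#' hidden state) -> dense relu stack with dropout -> one-unit sigmoid head,
#' with freshly initialized weights (Glorot-uniform, deterministic under
#' `seed`).
#'
#' @param config A [backbone_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `gmean_backbone` holding `config`, the
#'   parameter list, and (after training) the attached vocabulary and
#'   history.
#' @export
build_backbone <- function(config, seed = 1L) {
  stopifnot(inherits(config, "gmean_backbone_config"))
  structure(list(config = config,
                 params = init_backbone_params(config, seed),
                 vocab = NULL, history = NULL, trained = FALSE),
            class = "gmean_backbone")
}

#' @export
print.gmean_backbone <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("%s backbone: embed %d -> %s(%d) -> dense [%s] -> sigmoid(1)\n",
              toupper(cfg$backbone_kind), cfg$embedding_dim,
              toupper(cfg$backbone_kind), cfg$gru_units,
              paste(cfg$dense_units, collapse = ", ")))
  cat(sprintf("  %s; %s trainable parameters; latent layer %d\n",
              if (x$trained) "trained" else "untrained",
              format(count_parameters(x), big.mark = ","),
              cfg$latent_layer_index))
  invisible(x)
}

#' Number of trainable parameters of a backbone
#'
#' @param model A `gmean_backbone`.
#' @return Integer count (the fixed one-hot table is excluded under
#'   `input_encoding = "onehot"`).
#' @export
count_parameters <- function(model) {
  ns <- names(model$params)
  if (model$config$input_encoding == "onehot") ns <- setdiff(ns, "emb")
  sum(vapply(model$params[ns], length, numeric(1)))
}

# Reverse each row's first `lengths[i]` tokens in place (padding stays at
# the end); used to feed the backward direction of bidirectional kinds.
reverse_tokens <- function(tokens, lengths) {
  out <- tokens
  for (i in seq_len(nrow(tokens))) {
    L <- lengths[i]
    if (L > 1L) out[i, seq_len(L)] <- tokens[i, L:1L]
  }
  out
}

# Run one direction of the recurrent layer over a token batch.
# Returns the final hidden state and, when keep_cache, everything the
# backward pass needs.
rnn_direction_forward <- function(params, config, dir, tokens, lengths,
                                  keep_cache = FALSE) {
  tokvec <- as.vector(tokens) + 1L  # time-major: row (t-1)*B + b
  Xemb <- params$emb[tokvec, , drop = FALSE]
  W <- params[[paste0("W_", dir)]]
  b <- matrix(params[[paste0("b_", dir)]], nrow = 1L)
  Ain <- Xemb %*% W
  n_steps <- ncol(tokens)
  out <- if (backbone_cell_kind(config) == "gru") {
    gru_forward_cpp(Ain, b, params[[paste0("Uzr_", dir)]],
                    params[[paste0("Uc_", dir)]],
                    as.integer(lengths), n_steps, keep_cache)
  } else {
    lstm_forward_cpp(Ain, b, params[[paste0("U_", dir)]],
                     as.integer(lengths), n_steps, keep_cache)
  }
  if (keep_cache) {
    out$Xemb <- Xemb
    out$tokvec <- tokvec
  }
  out
}

# Full forward pass. Returns the predicted probability, per-layer feature
# activations, and (training mode) dropout masks plus recurrent caches.
forward_backbone <- function(model, tokens, lengths, training = FALSE) {
  config <- model$config
  params <- model$params
  dirs <- backbone_directions(config)
  tok_by_dir <- list(f = tokens)
  if (length(dirs) == 2L) tok_by_dir$b <- reverse_tokens(tokens, lengths)
  rnn <- lapply(dirs, function(dir) {
    rnn_direction_forward(params, config, dir, tok_by_dir[[dir]], lengths,
                          keep_cache = training)
  })
  names(rnn) <- dirs
  h <- do.call(cbind, lapply(rnn, `[[`, "h"))
  features <- list(h)
  pre <- list()
  masks <- list()
  a <- h
  for (j in seq_along(config$dense_units)) {
    zpre <- add_bias(a %*% params[[paste0("Wd_", j)]],
                     params[[paste0("bd_", j)]])
    act <- pmax(zpre, 0)
    features[[j + 1L]] <- act
    if (training && config$dropout_rate > 0) {
      m <- (matrix(stats::runif(length(act)), nrow(act)) >=
              config$dropout_rate) / (1 - config$dropout_rate)
      masks[[j]] <- m
      act <- act * m
    }
    pre[[j]] <- zpre
    a <- act
  }
  logit <- drop(a %*% params$W_out) + params$b_out
  prob <- sigmoid(logit)
  list(prob = prob, features = features,
       cache = if (training) list(rnn = rnn, tok_by_dir = tok_by_dir,
                                  pre = pre, masks = masks,
                                  dense_in = features, last_act = a,
                                  lengths = lengths) else NULL)
}

# Gradients of mean binary cross-entropy w.r.t. every trainable parameter.
backward_backbone <- function(model, fwd, y) {
  config <- model$config
  params <- model$params
  cache <- fwd$cache
  B <- length(y)
  grads <- list()
  dlogit <- (fwd$prob - y) / B
  # output layer
  a_last <- if (length(config$dense_units)) {
    act <- cache$dense_in[[length(config$dense_units) + 1L]]
    if (config$dropout_rate > 0) act * cache$masks[[length(config$dense_units)]]
    else act
  } else {
    cache$dense_in[[1L]]
  }
  grads$W_out <- crossprod(a_last, dlogit)
  grads$b_out <- sum(dlogit)
  da <- matrix(dlogit, ncol = 1L) %*% t(params$W_out)
  for (j in rev(seq_along(config$dense_units))) {
    if (config$dropout_rate > 0) da <- da * cache$masks[[j]]
    dz <- da * (cache$pre[[j]] > 0)
    a_in <- cache$dense_in[[j]]
    if (j > 1L && config$dropout_rate > 0) a_in <- a_in * cache$masks[[j - 1L]]
    grads[[paste0("Wd_", j)]] <- crossprod(a_in, dz)
    grads[[paste0("bd_", j)]] <- colSums(dz)
    da <- dz %*% t(params[[paste0("Wd_", j)]])
  }
  # recurrent layer(s)
  H <- config$gru_units
  dirs <- backbone_directions(config)
  grads$emb <- matrix(0, nrow(params$emb), ncol(params$emb))
  for (k in seq_along(dirs)) {
    dir <- dirs[k]
    dh <- da[, ((k - 1L) * H + 1L):(k * H), drop = FALSE]
    rnn <- cache$rnn[[dir]]
    n_steps <- ncol(cache$tok_by_dir[[dir]])
    if (backbone_cell_kind(config) == "gru") {
      bk <- gru_backward_cpp(dh, rnn, params[[paste0("Uzr_", dir)]],
                             params[[paste0("Uc_", dir)]],
                             as.integer(cache$lengths), n_steps)
      grads[[paste0("Uzr_", dir)]] <- bk$du_zr
      grads[[paste0("Uc_", dir)]] <- bk$du_c
    } else {
      bk <- lstm_backward_cpp(dh, rnn, params[[paste0("U_", dir)]],
                              as.integer(cache$lengths), n_steps)
      grads[[paste0("U_", dir)]] <- bk$du
    }
    W <- params[[paste0("W_", dir)]]
    grads[[paste0("W_", dir)]] <- crossprod(rnn$Xemb, bk$dain)
    grads[[paste0("b_", dir)]] <- colSums(bk$dain)
    if (config$input_encoding == "embedding") {
      dXemb <- bk$dain %*% t(W)
      rs <- rowsum(dXemb, group = rnn$tokvec)
      idx <- as.integer(rownames(rs))
      grads$emb[idx, ] <- grads$emb[idx, , drop = FALSE] + rs
    }
  }
  if (config$input_encoding == "onehot") grads$emb <- NULL
  grads
}

bce_loss <- function(prob, y, eps = 1e-7) {
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

#' Training configuration
#'
#' @param epochs Maximum number of epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param early_stopping_patience Stop after this many epochs without
#'   improvement of the monitored quantity; the best weights are restored.
#' @param monitor `"val_loss"` (minimized, default) or `"val_accuracy"`
#'   (maximized).
#' @param seed Seed for shuffling and dropout.
#' @param min_delta Smallest change counting as an improvement.
#' @return A config list of class `gmean_train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 32L,
                         learning_rate = 1e-3,
                         early_stopping_patience = 5L,
                         monitor = c("val_loss", "val_accuracy"),
                         seed = 1L, min_delta = 0) {
  monitor <- match.arg(monitor)
  stopifnot(is_count(epochs), is_count(batch_size), learning_rate > 0,
            is_count(early_stopping_patience, min = 0L))
  if (early_stopping_patience >= epochs) {
    stopf("train_config: early_stopping_patience (%d) must be smaller than epochs (%d)",
          early_stopping_patience, epochs)
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 early_stopping_patience = as.integer(early_stopping_patience),
                 monitor = monitor, seed = as.integer(seed),
                 min_delta = min_delta),
            class = "gmean_train_config")
}

# Early stopping as a pure function over a monitored series: returns the
# best epoch and the epoch training halts (best + patience, capped at the
# series length). Used by the train loop and directly testable.
early_stopping_plan <- function(values, patience,
                                mode = c("min", "max"), min_delta = 0) {
  mode <- match.arg(mode)
  best <- 1L
  wait <- 0L
  for (e in seq_along(values)[-1L]) {
    improved <- if (mode == "min") {
      values[e] < values[best] - min_delta
    } else {
      values[e] > values[best] + min_delta
    }
    if (improved) {
      best <- e
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) return(list(best_epoch = best, stop_epoch = e))
    }
  }
  list(best_epoch = best, stop_epoch = length(values))
}

eval_backbone <- function(model, tokens, lengths, labels, batch_size = 512L) {
  n <- nrow(tokens)
  probs <- numeric(n)
  for (start in seq.int(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    probs[idx] <- forward_backbone(model, tokens[idx, , drop = FALSE],
                                   lengths[idx], training = FALSE)$prob
  }
  list(prob = probs, loss = bce_loss(probs, labels),
       accuracy = mean(as.integer(probs >= 0.5) == labels))
}

#' Train a backbone on labelled token matrices
#'
#' Minimizes binary cross-entropy with Adam; after each epoch the
#' validation set is scored and training halts once the monitored quantity
#' has failed to improve for `early_stopping_patience` epochs, restoring
#' the weights of the best epoch.
#'
#' @param model A `gmean_backbone` (see [build_backbone()]).
#' @param train,val Labelled [encode_dataset()] objects sharing one
#'   vocabulary.
#' @param config A [train_config()].
#' @param verbose Print one line per epoch?
#' @return The trained model with `$history` (data frame: epoch, loss,
#'   accuracy, val_loss, val_accuracy) and the vocabulary attached.
#' @export
train_supervised <- function(model, train, val, config = train_config(),
                             verbose = FALSE) {
  stopifnot(inherits(model, "gmean_backbone"),
            inherits(train, "gmean_tokens"), inherits(val, "gmean_tokens"),
            inherits(config, "gmean_train_config"))
  if (any(is.na(train$labels)) || any(is.na(val$labels))) {
    stopf("train_supervised: training and validation data must be labelled")
  }
  if (!identical(train$vocab$kmers, val$vocab$kmers)) {
    stopf("train_supervised: train and validation use different vocabularies")
  }
  if (max(train$tokens) > model$config$vocab_size) {
    stopf("train_supervised: token ids exceed the model's vocab_size")
  }
  params <- model$params
  opt <- adam_init(params)
  n <- nrow(train$tokens)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0), val_loss = numeric(0),
                        val_accuracy = numeric(0))
  best_params <- params
  best_value <- NULL
  wait <- 0L
  mode <- if (config$monitor == "val_loss") "min" else "max"
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(n)
      epoch_loss <- 0
      epoch_correct <- 0L
      for (start in seq.int(1L, n, by = config$batch_size)) {
        rows <- idx[start:min(start + config$batch_size - 1L, n)]
        toks <- train$tokens[rows, , drop = FALSE]
        lens <- train$lengths[rows]
        y <- train$labels[rows]
        model$params <- params
        fwd <- forward_backbone(model, toks, lens, training = TRUE)
        loss <- bce_loss(fwd$prob, y)
        if (!is.finite(loss)) {
          stopf("train_supervised: non-finite loss at epoch %d (divergence)",
                epoch)
        }
        epoch_loss <- epoch_loss + loss * length(rows)
        epoch_correct <- epoch_correct +
          sum(as.integer(fwd$prob >= 0.5) == y)
        grads <- backward_backbone(model, fwd, y)
        upd <- adam_step(params, grads, opt, config$learning_rate)
        params <- upd$params
        opt <- upd$state
      }
      model$params <- params
      vm <- eval_backbone(model, val$tokens, val$lengths, val$labels)
      history[epoch, ] <- list(epoch, epoch_loss / n, epoch_correct / n,
                               vm$loss, vm$accuracy)
      if (verbose) {
        message(sprintf(
          "epoch %2d  loss %.4f  acc %.4f  val_loss %.4f  val_acc %.4f",
          epoch, epoch_loss / n, epoch_correct / n, vm$loss, vm$accuracy))
      }
      value <- if (config$monitor == "val_loss") vm$loss else vm$accuracy
      improved <- is.null(best_value) ||
        (mode == "min" && value < best_value - config$min_delta) ||
        (mode == "max" && value > best_value + config$min_delta)
      if (improved) {
        best_value <- value
        best_params <- params
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$early_stopping_patience &&
            config$early_stopping_patience > 0L) break
      }
    }
  })
  model$params <- best_params
  model$history <- history
  model$vocab <- train$vocab
  model$trained <- TRUE
  model
}

#' Predicted class-1 probabilities for a tokenized dataset
#'
#' @param model A trained `gmean_backbone`.
#' @param data An [encode_dataset()] object.
#' @param batch_size Evaluation batch size.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(model, data, batch_size = 512L) {
  check_model_vocab(model, data)
  n <- nrow(data$tokens)
  probs <- numeric(n)
  for (start in seq.int(1L, max(n, 1L), by = batch_size)) {
    if (start > n) break
    idx <- start:min(start + batch_size - 1L, n)
    probs[idx] <- forward_backbone(model, data$tokens[idx, , drop = FALSE],
                                   data$lengths[idx], training = FALSE)$prob
  }
  probs
}

check_model_vocab <- function(model, data) {
  if (!is.null(model$vocab) &&
      !identical(model$vocab$kmers, data$vocab$kmers)) {
    stopf("vocabulary mismatch between model and data")
  }
  if (max(data$tokens) > model$config$vocab_size) {
    stopf("token ids exceed the model's vocab_size")
  }
  invisible(TRUE)
}

#' Extract the latent representation of a dataset
#'
#' Runs the network in evaluation mode (dropout disabled) and returns the
#' activation of the configured latent layer: index 1 is the recurrent
#' final state, index `1 + j` the j-th dense relu activation. The default
#' configuration yields a 32-wide latent space.
#'
#' @param model A trained `gmean_backbone`.
#' @param data An [encode_dataset()] object.
#' @param layer_index Overrides `config$latent_layer_index` when given.
#' @param batch_size Evaluation batch size.
#' @return An `n x d` numeric matrix; identical rows of input map to
#'   identical rows of output.
#' @export
extract_latent <- function(model, data, layer_index = NULL,
                           batch_size = 512L) {
  stopifnot(inherits(model, "gmean_backbone"))
  check_model_vocab(model, data)
  li <- as.integer(layer_index %||% model$config$latent_layer_index)
  n_layers <- 1L + length(model$config$dense_units)
  if (li < 1L || li > n_layers) {
    stopf("extract_latent: layer_index must lie in 1..%d", n_layers)
  }
  n <- nrow(data$tokens)
  widths <- c(model$config$gru_units *
                length(backbone_directions(model$config)),
              model$config$dense_units)
  out <- matrix(0, n, widths[li])
  for (start in seq.int(1L, max(n, 1L), by = batch_size)) {
    if (start > n) break
    idx <- start:min(start + batch_size - 1L, n)
    fwd <- forward_backbone(model, data$tokens[idx, , drop = FALSE],
                            data$lengths[idx], training = FALSE)
    out[idx, ] <- fwd$features[[li]]
  }
  out
}

#' Save / load a backbone checkpoint
#'
#' The checkpoint embeds the architecture config, weights, vocabulary and
#' training history, so a prediction run is self-contained.
#'
#' @param model A `gmean_backbone`.
#' @param path File path.
#' @return `path` (save) or the reinstated model (load).
#' @export
save_backbone <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_backbone
#' @export
load_backbone <- function(path) {
  obj <- readRDS(path)
  class(obj$config) <- "gmean_backbone_config"
  structure(obj, class = "gmean_backbone")
}
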