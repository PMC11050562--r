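# CNN classification head over token embeddings.
#
# Architecture: conv1 (d_in -> 3*d_in, kernel 3, padding 1) + batch norm +
# ReLU, conv2 (3*d_in -> d_in, same kernel/padding) + batch norm + ReLU,
# masked mean-pool over non-pad token positions, FC1 (+ ReLU + dropout),
# FC2, softmax; trained with AdamW on cross-entropy. Forward, backward and
# the optimizer are implemented directly in matrix code; batch-norm
# statistics are computed over valid (non-pad) positions only and frozen
# at evaluation, so inference is batch-size invariant.

#' CNN head configuration
#'
#' @param d_in Input embedding width.
#' @param expansion_factor Channel expansion of the first convolution
#'   (default 3: d_in -> 3*d_in, then back to d_in).
#' @param kernel_size,padding Convolution geometry; padding must equal
#'   `(kernel_size - 1) / 2` so sequence length is preserved.
#' @param fc_hidden Width of the first fully connected layer
#'   (default `d_in`).
#' @param dropout_rate Dropout fraction in `[0, 1)` before the output layer.
#' @param n_classes Number of classes (binary: 2).
#' @return A `head_config` list with the derived `channel_trace`.
#' @export
head_config <- function(d_in = 64L, expansion_factor = 3L,
                        kernel_size = 3L, padding = 1L,
                        fc_hidden = d_in, dropout_rate = 0.2,
                        n_classes = 2L) {
  if (padding != (kernel_size - 1L) / 2L) {
    stop("config error: padding must be (kernel_size - 1)/2 to preserve sequence length",
         call. = FALSE)
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("config error: dropout_rate must be in [0, 1)", call. = FALSE)
  }
  d_in <- as.integer(d_in)
  structure(
    list(d_in = d_in, expansion_factor = as.integer(expansion_factor),
         kernel_size = as.integer(kernel_size), padding = as.integer(padding),
         fc_hidden = as.integer(fc_hidden), dropout_rate = dropout_rate,
         n_classes = as.integer(n_classes),
         channel_trace = c(d_in, as.integer(expansion_factor) * d_in, d_in)),
    class = "head_config"
  )
}

#' Training configuration for the CNN head
#'
#' @param learning_rate,batch_size,max_epochs,early_stop_patience,weight_decay
#'   AdamW / loop hyperparameters.
#' @param val_fraction Fraction of the training data carved off as the
#'   internal early-stopping validation split.
#' @param class_weights Optional numeric `c(negative, positive)` loss
#'   weights (e.g. inverse class frequencies); `NULL` for unweighted.
#' @param seed Integer seed; training is deterministic given the seed.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 32L,
                         max_epochs = 100L, early_stop_patience = 10L,
                         weight_decay = 1e-2, val_fraction = 0.15,
                         class_weights = NULL, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            early_stop_patience >= 1, weight_decay >= 0,
            val_fraction > 0, val_fraction < 0.5)
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         early_stop_patience = as.integer(early_stop_patience),
         weight_decay = weight_decay, val_fraction = val_fraction,
         class_weights = class_weights, seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Build an untrained CNN head
#'
#' @param config A [head_config()].
#' @param seed Seed for weight initialization.
#' @return An `adr_head` with He-initialized weights and unit batch-norm.
#' @export
build_head <- function(config = head_config(), seed = 1L) {
  stopifnot(inherits(config, "head_config"))
  rng <- .local_rng(.derive_seed(seed, 271L))
  d <- config$d_in
  ce <- config$expansion_factor * d
  ks <- config$kernel_size
  he <- function(nr, nc, fan_in) {
    matrix(rng$rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  }
  params <- list(
    conv1_W = he(ce, ks * d, ks * d), conv1_b = rep(0, ce),
    bn1_g = rep(1, ce), bn1_b = rep(0, ce),
    conv2_W = he(d, ks * ce, ks * ce), conv2_b = rep(0, d),
    bn2_g = rep(1, d), bn2_b = rep(0, d),
    fc1_W = he(d, config$fc_hidden, d), fc1_b = rep(0, config$fc_hidden),
    fc2_W = he(config$fc_hidden, config$n_classes, config$fc_hidden),
    fc2_b = rep(0, config$n_classes)
  )
  state <- list(
    bn1_mean = rep(0, ce), bn1_var = rep(1, ce),
    bn2_mean = rep(0, d), bn2_var = rep(1, d)
  )
  structure(list(config = config, params = params, state = state),
            class = "adr_head")
}

# ---- low-level layers ----------------------------------------------------

# Batches are flat (B*L) x C matrices in token-fastest order (row
# t + (b-1)*L). Kernel-3/padding-1 convolutions become three matmuls on
# row-shifted views; the shift indices (with a virtual zero row N+1) are
# precomputed at packing time.

# rows of M shifted per the index vector; `zero_rows` are boundary rows
# (virtual index N+1) that read zero
.shift_rows <- function(M, idx, zero_rows) {
  out <- M[pmin.int(idx, nrow(M)), , drop = FALSE]
  if (length(zero_rows) > 0L) out[zero_rows, ] <- 0
  out
}

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1

# ---- forward / backward --------------------------------------------------

# Forward pass. pk: packed batch from .pack_batch (flat Xm, shift indices).
# Returns probabilities and, if `train`, a cache for backprop; batch-norm
# uses batch statistics in training mode and running statistics in
# evaluation mode, computed over valid (non-pad) rows only.
.head_forward <- function(head, pk, train = FALSE, dropout_mask = NULL) {
  cfg <- head$config
  p <- head$params
  B <- pk$B; L <- pk$L; N <- B * L
  valid <- pk$valid
  inval <- pk$invalid_rows
  im1 <- pk$idx_m1; ip1 <- pk$idx_p1
  cache <- list(B = B, L = L, valid = valid, inval = inval,
                im1 = im1, ip1 = ip1,
                zm1 = pk$zero_m1, zp1 = pk$zero_p1)

  conv_bn_relu <- function(Xm, W, b, g, beta, rmean, rvar, tag) {
    C_in <- ncol(Xm)
    C_out <- nrow(W)
    Xl <- .shift_rows(Xm, im1, pk$zero_m1)
    Xr <- .shift_rows(Xm, ip1, pk$zero_p1)
    W1 <- W[, 1:C_in, drop = FALSE]
    W2 <- W[, (C_in + 1L):(2L * C_in), drop = FALSE]
    W3 <- W[, (2L * C_in + 1L):(3L * C_in), drop = FALSE]
    Y <- Xl %*% t(W1) + Xm %*% t(W2) + Xr %*% t(W3) + rep(b, each = N)
    if (train) {
      Yv <- Y[valid, , drop = FALSE]
      mu <- colMeans(Yv)
      va <- colMeans(Yv * Yv) - mu^2
    } else {
      mu <- rmean; va <- rvar
    }
    inv_sd <- 1 / sqrt(va + .BN_EPS)
    xhat <- (Y - rep(mu, each = N)) * rep(inv_sd, each = N)
    Z <- xhat * rep(g, each = N) + rep(beta, each = N)
    A <- Z * (Z > 0)
    if (length(inval) > 0L) A[inval, ] <- 0
    cache[[tag]] <<- list(Xm = Xm, Xl = Xl, Xr = Xr, mu = mu, va = va,
                          xhat = xhat, Z = Z, C_in = C_in)
    list(A = A, mu = mu, va = va)
  }

  s1 <- conv_bn_relu(pk$Xm, p$conv1_W, p$conv1_b, p$bn1_g, p$bn1_b,
                     head$state$bn1_mean, head$state$bn1_var, "c1")
  s2 <- conv_bn_relu(s1$A, p$conv2_W, p$conv2_b, p$bn2_g, p$bn2_b,
                     head$state$bn2_mean, head$state$bn2_var, "c2")

  # masked mean-pool over token positions (rows grouped by molecule)
  pool <- rowsum(s2$A, pk$row_group, reorder = TRUE) / pk$lens

  H1 <- pool %*% p$fc1_W + rep(p$fc1_b, each = B)
  R1 <- pmax(H1, 0)
  if (train && cfg$dropout_rate > 0) {
    if (is.null(dropout_mask)) dropout_mask <- matrix(1, B, cfg$fc_hidden)
    D1 <- R1 * dropout_mask
  } else {
    dropout_mask <- NULL
    D1 <- R1
  }
  logits <- D1 %*% p$fc2_W + rep(p$fc2_b, each = B)
  m <- apply(logits, 1L, max)
  ex <- exp(logits - m)
  probs <- ex / rowSums(ex)
  cache$pool <- pool; cache$H1 <- H1
  cache$D1 <- D1; cache$dropout_mask <- dropout_mask
  cache$probs <- probs
  cache$batch_stats <- list(bn1 = s1[c("mu", "va")], bn2 = s2[c("mu", "va")])
  list(probs = probs, cache = cache)
}

# Backward pass from cross-entropy on `y` (integer 1/2 class index).
# Returns gradients named like params.
.head_backward <- function(head, pk, y, cache, class_weights = NULL) {
  p <- head$params
  B <- cache$B; L <- cache$L; N <- B * L
  valid <- cache$valid
  probs <- cache$probs
  onehot <- matrix(0, B, ncol(probs))
  onehot[cbind(seq_len(B), y)] <- 1
  wts <- if (is.null(class_weights)) rep(1, B) else class_weights[y]
  wsum <- sum(wts)
  dlogits <- (probs - onehot) * (wts / wsum)

  g <- list()
  g$fc2_W <- crossprod(cache$D1, dlogits)
  g$fc2_b <- colSums(dlogits)
  dD1 <- dlogits %*% t(p$fc2_W)
  if (!is.null(cache$dropout_mask)) dD1 <- dD1 * cache$dropout_mask
  dH1 <- dD1 * (cache$H1 > 0)
  g$fc1_W <- crossprod(cache$pool, dH1)
  g$fc1_b <- colSums(dH1)
  dpool <- dH1 %*% t(p$fc1_W)                      # (B, d_in)

  # broadcast pooled gradient back to token rows
  dA2 <- (dpool / pk$lens)[pk$row_group, , drop = FALSE]
  if (length(pk$invalid_rows) > 0L) dA2[pk$invalid_rows, ] <- 0

  bn_conv_backward <- function(dA, cc, W, gam) {
    dZ <- dA * (cc$Z > 0)
    if (length(cache$inval) > 0L) dZ[cache$inval, ] <- 0
    xhat <- cc$xhat
    inv_sd <- 1 / sqrt(cc$va + .BN_EPS)
    dZv <- dZ[valid, , drop = FALSE]
    xhv <- xhat[valid, , drop = FALSE]
    dgamma <- colSums(dZv * xhv)
    dbeta <- colSums(dZv)
    dxhat <- dZ * rep(gam, each = N)
    nv <- sum(valid)
    mean_dxhat <- colSums(dxhat[valid, , drop = FALSE]) / nv
    mean_dxhat_x <- colSums((dxhat * xhat)[valid, , drop = FALSE]) / nv
    dY <- (dxhat - rep(mean_dxhat, each = N) -
             xhat * rep(mean_dxhat_x, each = N)) * rep(inv_sd, each = N)
    if (length(cache$inval) > 0L) dY[cache$inval, ] <- 0
    C_in <- cc$C_in
    dW <- cbind(crossprod(dY, cc$Xl), crossprod(dY, cc$Xm),
                crossprod(dY, cc$Xr))
    db <- colSums(dY)
    W1 <- W[, 1:C_in, drop = FALSE]
    W2 <- W[, (C_in + 1L):(2L * C_in), drop = FALSE]
    W3 <- W[, (2L * C_in + 1L):(3L * C_in), drop = FALSE]
    # Y_t sees X_{t-1} (W1) and X_{t+1} (W3): scatter gradients back by the
    # opposite shifts
    dXin <- .shift_rows(dY %*% W1, cache$ip1, cache$zp1) + dY %*% W2 +
      .shift_rows(dY %*% W3, cache$im1, cache$zm1)
    list(dW = dW, db = db, dgamma = dgamma, dbeta = dbeta, dXin = dXin)
  }

  b2 <- bn_conv_backward(dA2, cache$c2, p$conv2_W, p$bn2_g)
  g$conv2_W <- b2$dW; g$conv2_b <- b2$db
  g$bn2_g <- b2$dgamma; g$bn2_b <- b2$dbeta
  dA1 <- b2$dXin
  if (length(cache$inval) > 0L) dA1[cache$inval, ] <- 0
  b1 <- bn_conv_backward(dA1, cache$c1, p$conv1_W, p$bn1_g)
  g$conv1_W <- b1$dW; g$conv1_b <- b1$db
  g$bn1_g <- b1$dgamma; g$bn1_b <- b1$dbeta
  g
}

.ce_loss <- function(probs, y, class_weights = NULL) {
  wts <- if (is.null(class_weights)) rep(1, length(y)) else class_weights[y]
  eps <- 1e-12
  sum(wts * -log(probs[cbind(seq_along(y), y)] + eps)) / sum(wts)
}

# Pack a list of (L_i x d) embedding matrices into a flat padded batch:
# Xm is (B*L x d) in token-fastest order with zeroed pad rows; idx_m1 and
# idx_p1 are the kernel-3 shift index vectors (row B*L+1 = virtual zero).
.pack_batch <- function(emb_list) {
  B <- length(emb_list)
  lens <- vapply(emb_list, nrow, integer(1))
  L <- max(lens)
  d <- ncol(emb_list[[1]])
  N <- B * L
  Xm <- matrix(0, N, d)
  valid <- logical(N)
  for (i in seq_len(B)) {
    rows <- (i - 1L) * L + seq_len(lens[i])
    Xm[rows, ] <- emb_list[[i]]
    valid[rows] <- TRUE
  }
  t_of <- rep(seq_len(L), times = B)
  idx_m1 <- ifelse(t_of == 1L, N + 1L, seq_len(N) - 1L)
  idx_p1 <- ifelse(t_of == L, N + 1L, seq_len(N) + 1L)
  list(Xm = Xm, valid = valid, invalid_rows = which(!valid),
       lens = lens, B = B, L = L,
       row_group = rep(seq_len(B), each = L),
       idx_m1 = idx_m1, idx_p1 = idx_p1,
       zero_m1 = which(t_of == 1L), zero_p1 = which(t_of == L))
}

# ---- training ------------------------------------------------------------

#' Train the CNN head on encoded molecules
#'
#' Carves an internal stratified validation split from the training data,
#' optimizes with AdamW on cross-entropy, stops early when validation loss
#' has not improved for `early_stop_patience` epochs, and returns the
#' best-validation-epoch weights. Deterministic given
#' `train_cfg$seed`.
#'
#' @param head An `adr_head` from [build_head()].
#' @param embeddings List of (length x d_in) token-embedding matrices.
#' @param labels Character vector (`"positive"`/`"negative"`) or 1/2
#'   integer class indices (1 = negative, 2 = positive).
#' @param train_cfg A [train_config()].
#' @param encoder_fingerprint Fingerprint string of the encoder that
#'   produced `embeddings`, stored for provenance.
#' @return An `adr_model`: fitted head plus training history, config
#'   snapshots and encoder fingerprint.
#' @export
train_head <- function(head, embeddings, labels,
                       train_cfg = train_config(),
                       encoder_fingerprint = NA_character_) {
  stopifnot(inherits(head, "adr_head"), inherits(train_cfg, "train_config"))
  y <- .as_class_index(labels)
  if (length(unique(y)) < 2L) {
    stop("training error: training data contains a single class",
         call. = FALSE)
  }
  stopifnot(length(embeddings) == length(y))
  n <- length(y)
  rng <- .local_rng(.derive_seed(train_cfg$seed, 577L))

  # stratified internal validation split
  val_idx <- integer(0)
  for (cls in 1:2) {
    members <- which(y == cls)
    n_val <- max(1L, round(train_cfg$val_fraction * length(members)))
    pick <- rng$sample_int(length(members), min(n_val, length(members) - 1L))
    val_idx <- c(val_idx, members[pick])
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(unique(y[tr_idx])) < 2L) {
    stop("training error: internal split left a single class", call. = FALSE)
  }

  val_pack <- .pack_batch(embeddings[val_idx])
  cw <- train_cfg$class_weights

  opt <- .adamw_init(head$params)
  best <- list(loss = Inf, params = head$params, state = head$state,
               epoch = 0L)
  history <- list()
  stale <- 0L
  for (epoch in seq_len(train_cfg$max_epochs)) {
    ord <- tr_idx[rng$sample_perm(length(tr_idx))]
    batches <- split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      pk <- .pack_batch(embeddings[bt])
      dm <- if (head$config$dropout_rate > 0) {
        keep <- 1 - head$config$dropout_rate
        matrix(
          (rng$runif(length(bt) * head$config$fc_hidden) < keep) / keep,
          length(bt), head$config$fc_hidden)
      } else {
        NULL
      }
      fw <- .head_forward(head, pk, train = TRUE,
                          dropout_mask = dm)
      loss <- .ce_loss(fw$cache$probs, y[bt], cw)
      if (!is.finite(loss)) {
        stop(sprintf(
          "divergence error: non-finite loss at epoch %d (last stable epoch %d)",
          epoch, epoch - 1L), call. = FALSE)
      }
      ep_loss <- ep_loss + loss * length(bt)
      grads <- .head_backward(head, pk, y[bt], fw$cache, cw)
      upd <- .adamw_step(head$params, grads, opt, train_cfg)
      head$params <- upd$params
      opt <- upd$opt
      # running batch-norm statistics (unbiased variance, torch convention)
      nv <- sum(pk$valid)
      bs <- fw$cache$batch_stats
      corr <- if (nv > 1L) nv / (nv - 1L) else 1
      head$state$bn1_mean <- (1 - .BN_MOMENTUM) * head$state$bn1_mean +
        .BN_MOMENTUM * bs$bn1$mu
      head$state$bn1_var <- (1 - .BN_MOMENTUM) * head$state$bn1_var +
        .BN_MOMENTUM * bs$bn1$va * corr
      head$state$bn2_mean <- (1 - .BN_MOMENTUM) * head$state$bn2_mean +
        .BN_MOMENTUM * bs$bn2$mu
      head$state$bn2_var <- (1 - .BN_MOMENTUM) * head$state$bn2_var +
        .BN_MOMENTUM * bs$bn2$va * corr
    }
    ep_loss <- ep_loss / length(tr_idx)
    vfw <- .head_forward(head, val_pack, train = FALSE)
    val_loss <- .ce_loss(vfw$probs, y[val_idx], cw)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = ep_loss, val_loss = val_loss)
    if (val_loss < best$loss - 1e-7) {
      best <- list(loss = val_loss, params = head$params,
                   state = head$state, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= train_cfg$early_stop_patience) break
    }
  }
  head$params <- best$params
  head$state <- best$state
  structure(
    list(head = head, history = dplyr::bind_rows(history),
         best_epoch = best$epoch, best_val_loss = best$loss,
         train_config = train_cfg,
         encoder_fingerprint = encoder_fingerprint),
    class = "adr_model"
  )
}

.as_class_index <- function(labels) {
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(1, 2)))
    return(as.integer(labels))
  }
  stopifnot(all(labels %in% c("positive", "negative")))
  ifelse(labels == "positive", 2L, 1L)
}

.adamw_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

.adamw_step <- function(params, grads, opt, cfg,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  b1c <- 1 - beta1^opt$t
  b2c <- 1 - beta2^opt$t
  decayed <- c("conv1_W", "conv2_W", "fc1_W", "fc2_W")
  for (nm in names(params)) {
    gr <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * gr
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * gr^2
    step <- (opt$m[[nm]] / b1c) / (sqrt(opt$v[[nm]] / b2c) + eps)
    wd <- if (nm %in% decayed) cfg$weight_decay * params[[nm]] else 0
    params[[nm]] <- params[[nm]] - cfg$learning_rate * (step + wd)
  }
  list(params = params, opt = opt)
}

#' Predict ADR risk probabilities for encoded molecules
#'
#' Runs the fitted head in evaluation mode (dropout off, batch-norm frozen
#' at running statistics); outputs are independent of batch composition.
#'
#' @param object An `adr_model`.
#' @param embeddings List of token-embedding matrices (width must match
#'   the model's `d_in`).
#' @param batch_size Scoring batch size (does not affect results).
#' @param ... Unused.
#' @return A tibble with `p_positive`, `p_negative`, `label`
#'   (hard label at threshold 0.5).
#' @export
predict.adr_model <- function(object, embeddings, batch_size = 32L, ...) {
  d_in <- object$head$config$d_in
  widths <- vapply(embeddings, ncol, integer(1))
  if (any(widths != d_in)) {
    stop(sprintf("shape error: embedding width %d does not match model d_in %d",
                 widths[widths != d_in][1], d_in), call. = FALSE)
  }
  n <- length(embeddings)
  probs <- matrix(NA_real_, n, 2L)
  for (bt in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    pk <- .pack_batch(embeddings[bt])
    fw <- .head_forward(object$head, pk, train = FALSE)
    probs[bt, ] <- fw$probs
  }
  tibble::tibble(
    p_negative = probs[, 1], p_positive = probs[, 2],
    label = ifelse(probs[, 2] >= 0.5, "positive", "negative")
  )
}

#' @export
print.adr_model <- function(x, ...) {
  tr <- x$head$config$channel_trace
  cat(sprintf(
    "<adr_model> conv %d->%d->%d, fc %d->%d, best epoch %d (val loss %.4f)\n",
    tr[1], tr[2], tr[3], x$head$config$fc_hidden, x$head$config$n_classes,
    x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' Save / load a fitted model with its encoder fingerprint
#'
#' The model file refuses to load against a different encoder.
#'
#' @param model An `adr_model`.
#' @param path File path.
#' @return `path` invisibly (`save_model`); an `adr_model` (`load_model`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "adr_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @param encoder_handle Encoder the model will be used with; fingerprints
#'   must match.
#' @export
load_model <- function(path, encoder_handle = NULL) {
  model <- readRDS(path)
  if (!inherits(model, "adr_model")) {
    stop(sprintf("'%s' is not a saved adr_model", path), call. = FALSE)
  }
  if (!is.null(encoder_handle) &&
      !identical(model$encoder_fingerprint, encoder_handle$fingerprint)) {
    stop(sprintf(
      "fingerprint mismatch: model was trained with encoder %s but %s was supplied",
      model$encoder_fingerprint, encoder_handle$fingerprint), call. = FALSE)
  }
  model
}
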