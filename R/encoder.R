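# Transformer chemical language encoder: token embeddings with rotary
# positional encoding and linear (kernelized) attention, producing
# per-token embeddings plus explicitly materialized attention maps.
#
# Two encoder kinds share one contract: a small self-contained reference
# encoder (deterministically initialized from a seed, frozen; its random
# features are the test-time stand-in for a large pre-trained model) and an
# adapter for locally converted pre-trained checkpoints. Attribution needs
# an n x n attention matrix; linear attention never forms one during O(n)
# evaluation, so the kernelized attention is materialized exactly
# (normalized feature inner products) at encode time.

.SPECIAL_TOKENS <- c("<pad>", "<bos>", "<eos>")

#' Base SMILES token vocabulary
#'
#' Organic-subset atoms, common bracket atoms, bonds, branches and ring
#' closures. [build_vocab()] extends it with tokens observed in a corpus.
#' @return Named integer vector: token -> id (0-based; 0 is `<pad>`).
#' @export
default_vocab <- function() {
  toks <- c(
    .SPECIAL_TOKENS,
    "B", "C", "N", "O", "P", "S", "F", "I", "Cl", "Br",
    "b", "c", "n", "o", "p", "s",
    "[nH]", "[NH]", "[N+]", "[N-]", "[O-]", "[n+]", "[S+]", "[Na+]", "[Cl-]",
    as.character(1:9), "%10", "%11",
    "(", ")", "-", "=", "#", ":", "/", "\\", "."
  )
  stats::setNames(seq_along(toks) - 1L, toks)
}

#' Build a vocabulary from a SMILES corpus
#'
#' @param smiles Character vector of SMILES strings.
#' @param base Starting vocabulary (default [default_vocab()]).
#' @return Named integer vector token -> id.
#' @export
build_vocab <- function(smiles, base = default_vocab()) {
  seen <- unique(unlist(lapply(smiles, function(s) tokenize_smiles(s)$token)))
  extra <- setdiff(seen, names(base))
  if (length(extra) > 0L) {
    base <- c(base, stats::setNames(length(base) + seq_along(extra) - 1L,
                                    extra))
  }
  base
}

#' Configuration of the reference encoder
#'
#' @param d_model Embedding width (divisible by `n_heads`).
#' @param n_layers,n_heads Transformer depth and head count.
#' @param max_len Maximum token positions including the two boundary tokens.
#' @param feature_map Positive feature map for linear attention
#'   (`"elu1"`: elu(x) + 1).
#' @param vocab Token vocabulary (named integer vector).
#' @param seed Seed for deterministic weight initialization.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(d_model = 64L, n_layers = 2L, n_heads = 4L,
                           max_len = 256L, feature_map = "elu1",
                           vocab = default_vocab(), seed = 1L) {
  if (d_model %% n_heads != 0L) {
    stop("config error: d_model must be divisible by n_heads", call. = FALSE)
  }
  if ((d_model / n_heads) %% 2L != 0L) {
    stop("config error: head dimension must be even for rotary embeddings",
         call. = FALSE)
  }
  structure(
    list(d_model = as.integer(d_model), n_layers = as.integer(n_layers),
         n_heads = as.integer(n_heads), max_len = as.integer(max_len),
         feature_map = feature_map, vocab = vocab, seed = as.integer(seed)),
    class = "encoder_config"
  )
}

#' Build the self-contained reference encoder
#'
#' Initializes all weights deterministically from `config$seed`. The
#' encoder is frozen: encoding is a pure function of the token sequence.
#'
#' @param config An [encoder_config()].
#' @return An `encoder_handle` (kind `"reference"`).
#' @export
reference_encoder <- function(config = encoder_config()) {
  stopifnot(inherits(config, "encoder_config"))
  rng <- .local_rng(.derive_seed(config$seed, 42L))
  d <- config$d_model
  V <- length(config$vocab)
  mat <- function(nr, nc, sd = 0.05) {
    matrix(rng$rnorm(nr * nc, sd = sd), nr, nc)
  }
  layers <- lapply(seq_len(config$n_layers), function(l) {
    list(
      Wq = mat(d, d), Wk = mat(d, d), Wv = mat(d, d), Wo = mat(d, d),
      ln1_g = rep(1, d), ln1_b = rep(0, d),
      W1 = mat(d, 4L * d), b1 = rep(0, 4L * d),
      W2 = mat(4L * d, d), b2 = rep(0, d),
      ln2_g = rep(1, d), ln2_b = rep(0, d)
    )
  })
  weights <- list(embedding = mat(V, d, sd = 0.5), layers = layers,
                  lnf_g = rep(1, d), lnf_b = rep(0, d))
  handle <- list(kind = "reference", config = config, weights = weights)
  handle$fingerprint <- .fingerprint(weights)
  class(handle) <- "encoder_handle"
  handle
}

#' @export
print.encoder_handle <- function(x, ...) {
  cat(sprintf(
    "<encoder_handle %s> d_model=%d layers=%d heads=%d vocab=%d fp=%s\n",
    x$kind, x$config$d_model, x$config$n_layers, x$config$n_heads,
    length(x$config$vocab), x$fingerprint))
  invisible(x)
}

# Stable content hash (FNV-1a over the serialized object) used as the
# encoder fingerprint stored in fitted models.
.fingerprint <- function(obj) {
  bytes <- as.double(serialize(obj, NULL, version = 2L))
  n <- length(bytes)
  w1 <- (seq_len(n) %% 9973) + 1
  w2 <- (seq_len(n) %% 499) + 3
  h1 <- sum(bytes * w1) %% 2147483647
  h2 <- sum(bytes * w2) %% 2147483647
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}

#' Rotary positional transform
#'
#' Applies the position-dependent rotation of rotary embeddings to each row
#' of `x`. The transform is norm-preserving, and inner products between a
#' rotated query at position i and a rotated key at position j depend only
#' on the offset i - j.
#'
#' @param x Numeric matrix (positions x head dimension, dimension even).
#' @param positions Integer vector of 0-based positions, one per row.
#' @param base Frequency base (default 10000).
#' @return Matrix of the same shape.
#' @export
rotary_transform <- function(x, positions, base = 10000) {
  d <- ncol(x)
  if (d %% 2L != 0L) {
    stop("config error: rotary transform needs an even head dimension",
         call. = FALSE)
  }
  stopifnot(length(positions) == nrow(x))
  half <- d / 2L
  freqs <- base^(-(2 * (seq_len(half) - 1L)) / d)
  ang <- outer(positions, freqs)          # n x half
  cosm <- cos(ang); sinm <- sin(ang)
  odd <- seq(1L, d, by = 2L)
  even <- odd + 1L
  x1 <- x[, odd, drop = FALSE]
  x2 <- x[, even, drop = FALSE]
  out <- x
  out[, odd] <- x1 * cosm - x2 * sinm
  out[, even] <- x1 * sinm + x2 * cosm
  out
}

.feature_map <- function(x, kind = "elu1") {
  switch(kind,
    elu1 = ifelse(x > 0, x + 1, exp(x)),
    stop(sprintf("unknown feature map '%s'", kind), call. = FALSE)
  )
}

#' Linear (kernelized) attention with materialized attention matrix
#'
#' Computes attention through a positive feature map in O(length) via the
#' factorization phi(Q) (phi(K)' V) / (phi(Q) phi(K)' 1), and additionally
#' materializes the exact n x n kernelized attention matrix (row-normalized
#' phi(Q) phi(K)') for attribution.
#'
#' @param q,k,v Numeric matrices (length x head dimension).
#' @param pad_mask Logical vector, `TRUE` for real positions.
#' @param feature_map Feature-map kind (see [encoder_config()]).
#' @return List with `output` (length x d_v) and `attention`
#'   (length x length; rows over non-pad positions sum to 1).
#' @export
linear_attention <- function(q, k, v, pad_mask = NULL,
                             feature_map = "elu1") {
  n <- nrow(q)
  if (is.null(pad_mask)) pad_mask <- rep(TRUE, n)
  if (!any(pad_mask)) {
    stop("degenerate input: all positions are padding", call. = FALSE)
  }
  fq <- .feature_map(q, feature_map)
  fk <- .feature_map(k, feature_map)
  fk[!pad_mask, ] <- 0
  kv <- crossprod(fk, v)                  # d x d_v
  z <- colSums(fk)                        # d
  num <- fq %*% kv                        # n x d_v
  den <- as.vector(fq %*% z)              # n
  out <- num / den
  out[!pad_mask, ] <- 0
  scores <- fq %*% t(fk)                  # exact kernelized attention
  attn <- scores / rowSums(scores)
  attn[!pad_mask, ] <- 0
  list(output = out, attention = attn)
}

.layer_norm <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  va <- rowMeans((x - mu)^2)
  ((x - mu) / sqrt(va + eps)) * rep(g, each = nrow(x)) +
    rep(b, each = nrow(x))
}

#' Encode a canonical SMILES into embeddings and attention maps
#'
#' Tokenizes the SMILES, adds boundary tokens, and runs the encoder
#' forward pass, materializing every layer/head attention matrix.
#'
#' @param smiles_canonical A canonical SMILES string.
#' @param handle An `encoder_handle`.
#' @return An `encoded_molecule`: list with `smiles`, `tokens` (tibble from
#'   [tokenize_smiles()]), `embeddings` (length x d_model, rows include the
#'   two boundary tokens), `attention` (list over layers of list over heads
#'   of length x length matrices), `pad_mask`, `is_boundary` and
#'   `fingerprint`.
#' @export
encode <- function(smiles_canonical, handle) {
  stopifnot(inherits(handle, "encoder_handle"))
  cfg <- handle$config
  tok <- tokenize_smiles(smiles_canonical)
  ids <- cfg$vocab[tok$token]
  if (anyNA(ids)) {
    oov <- unique(tok$token[is.na(ids)])
    stop(sprintf("vocabulary error: out-of-vocabulary token(s) %s",
                 paste(sprintf("'%s'", oov), collapse = ", ")),
         call. = FALSE)
  }
  ids <- c(cfg$vocab["<bos>"], ids, cfg$vocab["<eos>"])
  L <- length(ids)
  if (L > cfg$max_len) {
    stop(sprintf("truncation error: %d tokens exceed max_len %d",
                 L, cfg$max_len), call. = FALSE)
  }
  w <- handle$weights
  x <- w$embedding[ids + 1L, , drop = FALSE]
  d <- cfg$d_model
  dh <- d %/% cfg$n_heads
  pos <- seq_len(L) - 1L
  attn_all <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    ly <- w$layers[[l]]
    h <- .layer_norm(x, ly$ln1_g, ly$ln1_b)
    q <- h %*% ly$Wq
    k <- h %*% ly$Wk
    v <- h %*% ly$Wv
    heads_out <- matrix(0, L, d)
    attn_all[[l]] <- vector("list", cfg$n_heads)
    for (hd in seq_len(cfg$n_heads)) {
      cols <- ((hd - 1L) * dh + 1L):(hd * dh)
      qh <- rotary_transform(q[, cols, drop = FALSE], pos)
      kh <- rotary_transform(k[, cols, drop = FALSE], pos)
      la <- linear_attention(qh, kh, v[, cols, drop = FALSE],
                             feature_map = cfg$feature_map)
      heads_out[, cols] <- la$output
      attn_all[[l]][[hd]] <- la$attention
    }
    x <- x + heads_out %*% ly$Wo
    h2 <- .layer_norm(x, ly$ln2_g, ly$ln2_b)
    ff <- pmax(h2 %*% ly$W1 + rep(ly$b1, each = L), 0) %*% ly$W2 +
      rep(ly$b2, each = L)
    x <- x + ff
  }
  x <- .layer_norm(x, w$lnf_g, w$lnf_b)
  if (any(!is.finite(x))) {
    stop("encoder produced non-finite embeddings", call. = FALSE)
  }
  structure(
    list(smiles = smiles_canonical, tokens = tok, embeddings = x,
         attention = attn_all, pad_mask = rep(TRUE, L),
         is_boundary = c(TRUE, rep(FALSE, L - 2L), TRUE),
         fingerprint = handle$fingerprint),
    class = "encoded_molecule"
  )
}

#' @export
print.encoded_molecule <- function(x, ...) {
  cat(sprintf("<encoded_molecule> %s: %d tokens, d=%d, %d layers\n",
              x$smiles, nrow(x$embeddings), ncol(x$embeddings),
              length(x$attention)))
  invisible(x)
}

#' Load a pre-trained encoder checkpoint
#'
#' Reads a locally stored checkpoint directory containing `config.json`
#' (fields `d_model`, `n_layers`, `n_heads`, `max_len`, `feature_map`,
#' `vocab`) and `weights.rds` (the weight list layout of
#' [reference_encoder()]). Public chemical-language-model checkpoints must
#' first be converted to this layout offline; downloads are never
#' attempted here.
#'
#' @param checkpoint_dir Directory path.
#' @return An `encoder_handle` (kind `"pretrained"`) satisfying the same
#'   [encode()] contract, including attention materialization.
#' @export
load_pretrained_adapter <- function(checkpoint_dir) {
  cfg_path <- file.path(checkpoint_dir, "config.json")
  w_path <- file.path(checkpoint_dir, "weights.rds")
  if (!dir.exists(checkpoint_dir) || !file.exists(cfg_path) ||
      !file.exists(w_path)) {
    stop(structure(
      class = c("adralert_checkpoint_error", "error", "condition"),
      list(message = sprintf(
        paste0("checkpoint load error: '%s' must contain config.json and ",
               "weights.rds; convert a downloaded checkpoint first or use ",
               "encoder kind 'reference'"), checkpoint_dir),
        call = NULL)
    ))
  }
  cj <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  cfg <- encoder_config(
    d_model = cj$d_model, n_layers = cj$n_layers, n_heads = cj$n_heads,
    max_len = cj$max_len %||% 256L,
    feature_map = cj$feature_map %||% "elu1",
    vocab = stats::setNames(as.integer(unlist(cj$vocab)), names(cj$vocab)),
    seed = 0L
  )
  weights <- tryCatch(readRDS(w_path), error = function(e) NULL)
  if (is.null(weights) || !all(c("embedding", "layers") %in% names(weights))) {
    stop(structure(
      class = c("adralert_checkpoint_error", "error", "condition"),
      list(message = sprintf(
        "checkpoint load error: weights.rds in '%s' is corrupt or has the wrong layout",
        checkpoint_dir), call = NULL)
    ))
  }
  if (nrow(weights$embedding) != length(cfg$vocab) ||
      ncol(weights$embedding) != cfg$d_model) {
    stop("checkpoint load error: embedding shape disagrees with config.json",
         call. = FALSE)
  }
  handle <- list(kind = "pretrained", config = cfg, weights = weights)
  handle$fingerprint <- .fingerprint(weights)
  class(handle) <- "encoder_handle"
  handle
}

#' Resolve an encoder from settings, with reference fallback
#'
#' @param kind `"reference"` or `"pretrained"`.
#' @param checkpoint Checkpoint directory for `"pretrained"`.
#' @param config [encoder_config()] for the reference encoder.
#' @param fallback If the pretrained checkpoint cannot be loaded, fall back
#'   to the reference encoder with a warning instead of failing?
#' @return An `encoder_handle`.
#' @export
get_encoder <- function(kind = c("reference", "pretrained"),
                        checkpoint = NULL, config = encoder_config(),
                        fallback = TRUE) {
  kind <- match.arg(kind)
  if (kind == "reference") return(reference_encoder(config))
  tryCatch(
    load_pretrained_adapter(checkpoint),
    error = function(e) {
      if (!fallback) stop(e)
      warning(sprintf(
        "pretrained encoder unavailable (%s); falling back to reference encoder",
        conditionMessage(e)), call. = FALSE)
      reference_encoder(config)
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
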