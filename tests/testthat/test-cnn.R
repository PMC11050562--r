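test_that("head architecture conforms structurally: channel trace and shapes", {
  cfg <- head_config(d_in = 64L)
  expect_identical(cfg$channel_trace, c(64L, 192L, 64L))
  head <- build_head(cfg, seed = 1L)
  expect_identical(dim(head$params$conv1_W), c(192L, 192L))  # 3*64 x k*64
  expect_identical(dim(head$params$conv2_W), c(64L, 576L))   # 64 x k*192
  expect_identical(dim(head$params$fc2_W), c(64L, 2L))
  expect_error(head_config(kernel_size = 3L, padding = 2L), "padding")
  expect_error(head_config(dropout_rate = 1), "dropout")
})

test_that("convolutions preserve sequence length (kernel 3, padding 1)", {
  head <- build_head(head_config(d_in = 8L), seed = 2L)
  emb <- list(matrix(rnorm(33 * 8), 33, 8))
  pk <- .pack_batch(emb)
  fw <- .head_forward(head, pk)
  # conv activations exist for all 33 positions of the single molecule
  expect_identical(pk$L, 33L)
  expect_identical(nrow(fw$probs), 1L)
})

test_that("outputs live on the probability simplex", {
  head <- build_head(head_config(d_in = 8L), seed = 3L)
  set.seed(4)
  emb <- lapply(1:100, function(i) {
    matrix(rnorm(sample(3:20, 1) * 8, sd = 3), ncol = 8)
  })
  pr <- predict(structure(list(head = head), class = "adr_model"), emb)
  expect_true(all(pr$p_positive >= 0 & pr$p_positive <= 1))
  expect_true(all(abs(pr$p_positive + pr$p_negative - 1) < 1e-6))
})

test_that("training reduces loss on a separable planted-token task", {
  enc <- tiny_encoder()
  ds <- synthetic_corpus()
  embs <- lapply(ds$smiles_canonical, function(s) encode(s, enc)$embeddings)
  model <- train_head(
    build_head(head_config(d_in = 32L), seed = 5L),
    embs, ds$label,
    train_config(max_epochs = 8L, seed = 6L))
  h <- model$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_identical(h$epoch, seq_len(nrow(h)))
})

test_that("training is bit-reproducible under a fixed seed", {
  enc <- tiny_encoder()
  ds <- synthetic_corpus()[c(1:15, 41:55), ]
  embs <- lapply(ds$smiles_canonical, function(s) encode(s, enc)$embeddings)
  run <- function() {
    train_head(build_head(head_config(d_in = 32L), seed = 5L),
               embs, ds$label,
               train_config(max_epochs = 5L, seed = 11L))
  }
  m1 <- run()
  m2 <- run()
  expect_identical(m1$head$params, m2$head$params)
  expect_identical(m1$history, m2$history)
})

test_that("single-class training data is refused", {
  enc <- tiny_encoder()
  embs <- lapply(synthetic_corpus()$smiles_canonical[1:10],
                 function(s) encode(s, enc)$embeddings)
  expect_error(
    train_head(build_head(head_config(d_in = 32L)), embs,
               rep("positive", 10), train_config()),
    "single class")
})

test_that("scoring is batch-size invariant and width-checked", {
  enc <- tiny_encoder()
  ds <- synthetic_corpus()[c(1:10, 41:50), ]
  embs <- lapply(ds$smiles_canonical, function(s) encode(s, enc)$embeddings)
  model <- train_head(build_head(head_config(d_in = 32L), seed = 1L),
                      embs, ds$label,
                      train_config(max_epochs = 3L, seed = 2L))
  one_by_one <- do.call(rbind, lapply(embs, function(e) {
    as.matrix(predict(model, list(e))[, c("p_negative", "p_positive")])
  }))
  batched <- as.matrix(predict(model, embs,
                               batch_size = 32L)[, c("p_negative",
                                                     "p_positive")])
  expect_lt(max(abs(one_by_one - batched)), 1e-6)
  wrong <- list(matrix(0, 5, 16))
  expect_error(predict(model, wrong), "shape error")
})

test_that("model files refuse a mismatched encoder fingerprint", {
  enc <- tiny_encoder()
  ds <- synthetic_corpus()[c(1:10, 41:50), ]
  embs <- lapply(ds$smiles_canonical, function(s) encode(s, enc)$embeddings)
  model <- train_head(build_head(head_config(d_in = 32L), seed = 1L),
                      embs, ds$label,
                      train_config(max_epochs = 2L, seed = 2L),
                      encoder_fingerprint = enc$fingerprint)
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  expect_s3_class(load_model(path, enc), "adr_model")
  other <- reference_encoder(encoder_config(d_model = 16L, n_heads = 2L,
                                            seed = 99L))
  expect_error(load_model(path, other), "fingerprint mismatch")
})
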