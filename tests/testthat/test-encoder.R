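test_that("encoding has the contracted shapes and normalized attention", {
  enc <- tiny_encoder()
  e <- encode("CCO", enc)
  expect_identical(dim(e$embeddings), c(5L, 32L))     # 3 tokens + 2 boundary
  expect_identical(sum(e$is_boundary), 2L)
  for (layer in e$attention) {
    for (A in layer) {
      expect_true(all(A >= 0))
      expect_true(all(abs(rowSums(A) - 1) < 1e-5))
    }
  }
  expect_true(all(is.finite(e$embeddings)))
})

test_that("attention is normalized on every layer/head across a corpus", {
  enc <- tiny_encoder()
  pool <- utils::head(smiles_pool(), 100)
  worst <- 0
  for (smi in pool) {
    e <- encode(smi, enc)
    for (layer in e$attention) {
      for (A in layer) {
        worst <- max(worst, max(abs(rowSums(A) - 1)))
        if (min(A) < 0) worst <- Inf
      }
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("encoding is deterministic and seed-sensitive", {
  cfg <- encoder_config(d_model = 16L, n_heads = 2L, seed = 3L)
  e1 <- encode("CCO", reference_encoder(cfg))
  e2 <- encode("CCO", reference_encoder(cfg))
  expect_identical(e1$embeddings, e2$embeddings)
  cfg2 <- encoder_config(d_model = 16L, n_heads = 2L, seed = 4L)
  e3 <- encode("CCO", reference_encoder(cfg2))
  expect_false(identical(e1$embeddings, e3$embeddings))
})

test_that("out-of-vocabulary tokens and over-length inputs error loudly", {
  enc <- reference_encoder(encoder_config(
    d_model = 16L, n_heads = 2L,
    vocab = stats::setNames(0:4, c("<pad>", "<bos>", "<eos>", "C", "O"))))
  expect_error(encode("CCN", enc), "out-of-vocabulary.*'N'")
  enc2 <- reference_encoder(encoder_config(d_model = 16L, n_heads = 2L,
                                           max_len = 4L))
  expect_error(encode("CCCCCC", enc2), "truncation")
})

test_that("rotary transform is an isometry depending only on offsets", {
  set.seed(5)
  for (i in 1:100) {
    d <- sample(c(4L, 8L, 16L), 1L)
    q <- matrix(rnorm(d), 1)
    k <- matrix(rnorm(d), 1)
    pi_ <- sample(0:40, 1)
    pj <- sample(0:40, 1)
    off <- sample(0:10, 1)
    d1 <- sum(rotary_transform(q, pi_) * rotary_transform(k, pj))
    d2 <- sum(rotary_transform(q, pi_ + off) * rotary_transform(k, pj + off))
    expect_lt(abs(d1 - d2), 1e-8)
    expect_lt(abs(sqrt(sum(rotary_transform(q, pj)^2)) - sqrt(sum(q^2))),
              1e-10)
  }
  expect_identical(rotary_transform(matrix(1:8, 2), c(0, 0)),
                   matrix(1:8, 2) * 1)
  expect_error(rotary_transform(matrix(rnorm(3), 1), 0), "even")
})

test_that("factorized linear attention equals the naive quadratic oracle", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(2:24, 1)
    d <- sample(c(4L, 8L, 16L), 1L)
    dv <- sample(c(4L, 8L), 1L)
    q <- matrix(rnorm(n * d), n)
    k <- matrix(rnorm(n * d), n)
    v <- matrix(rnorm(n * dv), n)
    fast <- linear_attention(q, k, v)
    slow <- naive_kernel_attention(q, k, v)
    expect_lt(max(abs(fast$output - slow$output)), 1e-6)
    expect_lt(max(abs(fast$attention - slow$attention)), 1e-9)
  }
})

test_that("linear attention handles degenerate shapes per contract", {
  q <- matrix(rnorm(4), 1)
  out <- linear_attention(q, q, matrix(1, 1, 2))
  expect_equal(out$attention, matrix(1, 1, 1))
  # identical keys: uniform attention
  k <- matrix(rep(rnorm(4), 6), 6, byrow = TRUE)
  out2 <- linear_attention(matrix(rnorm(24), 6), k, matrix(rnorm(6), 6))
  expect_true(all(abs(out2$attention - 1 / 6) < 1e-12))
  expect_error(
    linear_attention(q, q, matrix(1, 1, 2), pad_mask = FALSE),
    "all positions"
  )
})

test_that("the pretrained adapter enforces the checkpoint contract", {
  expect_error(load_pretrained_adapter(tempfile()),
               class = "adralert_checkpoint_error")
  # a converted checkpoint (reference layout) loads and encodes identically
  enc <- tiny_encoder()
  dir <- tempfile()
  dir.create(dir)
  jsonlite::write_json(
    list(d_model = enc$config$d_model, n_layers = enc$config$n_layers,
         n_heads = enc$config$n_heads, max_len = enc$config$max_len,
         feature_map = enc$config$feature_map,
         vocab = as.list(enc$config$vocab)),
    file.path(dir, "config.json"), auto_unbox = TRUE)
  saveRDS(enc$weights, file.path(dir, "weights.rds"))
  pre <- load_pretrained_adapter(dir)
  expect_identical(pre$kind, "pretrained")
  expect_identical(encode("CCO", pre)$embeddings,
                   encode("CCO", enc)$embeddings)
  # corrupt weights are refused
  saveRDS(list(nonsense = 1), file.path(dir, "weights.rds"))
  expect_error(load_pretrained_adapter(dir),
               class = "adralert_checkpoint_error")
})

test_that("get_encoder falls back to the reference encoder with a warning", {
  expect_warning(
    h <- get_encoder("pretrained", checkpoint = tempfile(),
                     config = encoder_config(d_model = 16L, n_heads = 2L)),
    "falling back"
  )
  expect_identical(h$kind, "reference")
  expect_error(get_encoder("pretrained", checkpoint = tempfile(),
                           fallback = FALSE))
})

test_that("a drug-scale molecule encodes with the independent token count", {
  enc <- tiny_encoder()
  ros <- canonicalize_smiles(
    drug_smiles()$smiles[drug_smiles()$name == "rosuvastatin"])
  e <- encode(ros, enc)
  expect_identical(nrow(e$embeddings), nrow(tokenize_smiles(ros)) + 2L)
})
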