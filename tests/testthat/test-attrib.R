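test_that("pooled scores equal a naive loop over layers, heads and rows", {
  enc <- tiny_encoder()
  for (smi in c("CCO", "c1ccc(Cl)cc1", "CC(N)C(=O)O")) {
    e <- encode(smi, enc)
    scores <- pool_attention(e, policy = "received")
    keep <- which(!e$is_boundary)
    L <- length(e$pad_mask)
    nl <- length(e$attention); nh <- length(e$attention[[1]])
    # naive accumulation, one cell at a time
    acc <- matrix(0, L, L)
    for (l in seq_len(nl)) for (h in seq_len(nh)) {
      acc <- acc + e$attention[[l]][[h]]
    }
    acc <- acc / (nl * nh)
    naive <- vapply(keep, function(j) mean(acc[keep, j]), numeric(1))
    expect_lt(max(abs(scores - naive)), 1e-12)
    expect_true(all(scores >= 0))
  }
})

test_that("pooling is linear in the attention tensors", {
  enc <- tiny_encoder()
  e1 <- encode("CCOC", enc)
  e2 <- encode("CCOC", reference_encoder(
    encoder_config(d_model = 32L, n_layers = 2L, n_heads = 2L,
                   vocab = enc$config$vocab, seed = 123L)))
  lam <- 0.3
  mix <- e1
  for (l in seq_along(mix$attention)) {
    for (h in seq_along(mix$attention[[l]])) {
      mix$attention[[l]][[h]] <- lam * e1$attention[[l]][[h]] +
        (1 - lam) * e2$attention[[l]][[h]]
    }
  }
  got <- pool_attention(mix)
  want <- lam * pool_attention(e1) + (1 - lam) * pool_attention(e2)
  expect_lt(max(abs(got - want)), 1e-9)
})

test_that("uniform and delta attention pool to uniform and delta scores", {
  enc <- tiny_encoder()
  e <- encode("CCCCCC", enc)
  L <- length(e$pad_mask)
  uni <- matrix(1 / L, L, L)
  e$attention <- list(list(uni), list(uni))
  s <- pool_attention(e)
  expect_lt(diff(range(s)), 1e-12)
  delta <- matrix(0, L, L); delta[, 3] <- 1
  e$attention <- list(list(delta))
  s2 <- pool_attention(e)
  expect_equal(unname(s2[2]), 1)          # token 3 = first non-boundary + 1
  expect_true(all(s2[-2] == 0))
})

test_that("token scores map onto atoms through the tokenizer", {
  tok <- tokenize_smiles("C(Cl)=O")
  scores <- stats::setNames(seq_len(nrow(tok)) / 10, tok$token)
  atom_scores <- tokens_to_atoms(scores, tok)
  expect_length(atom_scores, 3L)
  expect_identical(names(atom_scores), c("C", "Cl", "O"))
  tok2 <- tokenize_smiles("c1cc[nH]c1")
  s2 <- tokens_to_atoms(stats::setNames(rep(1, nrow(tok2)), tok2$token),
                        tok2)
  expect_length(s2, 5L)
  expect_true("[nH]" %in% names(s2))
  expect_error(tokens_to_atoms(1:3, tok), "mapping error")
})

test_that("substructure selection honors quantile, ties and expansion", {
  scores <- seq(1, 0.1, length.out = 10)
  expect_identical(select_substructure(scores, top_fraction = 1),
                   1:10)
  expect_identical(select_substructure(scores, top_fraction = 0.3), 1:3)
  tied <- c(1, 0.5, 0.5, 0.5, 0.1)
  expect_identical(select_substructure(tied, top_fraction = 0.4), 1:2)
  # catalog expansion completes an overlapping matched group
  cat <- alert_catalog()
  g <- parse_smiles("CCCCC(=O)O")          # carboxyl at atoms 5,6,7
  sc <- c(0, 0, 0, 0, 1, 0, 0)
  sel <- select_substructure(sc, g, top_fraction = 0.15, catalog = cat)
  expect_true(all(c(5L, 6L, 7L) %in% sel))
})

test_that("alert matching reports named drugs' known alerts", {
  cat <- alert_catalog()
  d <- drug_smiles()
  get_alerts <- function(name) {
    smi <- canonicalize_smiles(d$smiles[d$name == name])
    unique(match_alerts(smi, integer(0), cat)$alert_name)
  }
  expect_true("carboxylic_acid" %in% get_alerts("valproate"))
  expect_true("imide_NH" %in% get_alerts("phenytoin"))
  for (statin in c("fluvastatin", "atorvastatin", "rosuvastatin",
                   "pitavastatin")) {
    expect_true("aromatic_halide" %in% get_alerts(statin))
  }
  expect_true("sulfonamide" %in% get_alerts("ibutilide"))
  expect_true("ether" %in% get_alerts("quinidine"))
  expect_true("tertiary_amine" %in% get_alerts("disopyramide"))
})

test_that("matched alert names are invariant under SMILES enumeration", {
  cat <- alert_catalog()
  can <- canonicalize_smiles(
    drug_smiles()$smiles[drug_smiles()$name == "valproate"])
  base_alerts <- sort(unique(match_alerts(can, integer(0), cat)$alert_name))
  for (var in enumerate_smiles(can, 5L, seed = 21L)) {
    got <- sort(unique(match_alerts(var, integer(0), cat)$alert_name))
    expect_identical(got, base_alerts)
  }
})

test_that("attribution reports serialize and render deterministically", {
  enc <- tiny_encoder()
  rep <- attribute_molecule("CCCC(CCC)C(=O)O", enc)
  expect_s3_class(rep, "alert_report")
  expect_length(rep$atom_scores, 10L)
  jp <- tempfile(fileext = ".json")
  write_alert_report(rep, jp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_identical(back$smiles, rep$smiles)
  sp1 <- tempfile(fileext = ".svg")
  sp2 <- tempfile(fileext = ".svg")
  expect_identical(render_annotation(rep, sp1), sp1)
  render_annotation(rep, sp2)
  expect_gt(file.info(sp1)$size, 0)
  expect_identical(readLines(sp1), readLines(sp2))
  # empty selection still renders
  rep$selected_atoms <- integer(0)
  expect_identical(render_annotation(rep, sp1), sp1)
})

test_that("write_smiles exposes the atom correspondence of a rendering", {
  g <- parse_smiles("CC(N)C(=O)O")
  set.seed(17)
  for (i in 1:10) {
    pr <- sample(nrow(g$atoms))
    v <- write_smiles(g, priority = pr)
    ord <- attr(v, "atom_order")
    expect_identical(sort(ord), seq_len(nrow(g$atoms)))
    # the element written at each output position is the element of the
    # original atom the correspondence names
    gv <- parse_smiles(as.character(v))
    expect_identical(gv$atoms$element, g$atoms$element[ord])
  }
})

test_that("variant-averaged attribution keeps atom order and determinism", {
  enc <- tiny_encoder()
  r1 <- attribute_molecule("CCCC(CCC)C(=O)O", enc, n_average = 4L,
                           seed = 3L)
  r2 <- attribute_molecule("CCCC(CCC)C(=O)O", enc, n_average = 4L,
                           seed = 3L)
  expect_identical(r1$atom_scores, r2$atom_scores)
  expect_length(r1$atom_scores, 10L)
  r0 <- attribute_molecule("CCCC(CCC)C(=O)O", enc)
  expect_false(identical(r0$atom_scores, r1$atom_scores))
})
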