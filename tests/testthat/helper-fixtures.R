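# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  got <- get0(name, envir = .fixture_env)
  if (is.null(got)) {
    got <- builder()
    assign(name, got, envir = .fixture_env)
  }
  got
}

# Published drug SMILES used throughout: the high-risk QT drugs, the two
# teratogenic antiepileptics and the seven statins.
drug_smiles <- function() {
  tibble::tribble(
    ~name, ~smiles,
    "quinidine", "C=CC1CN2CCC1CC2C(O)c1ccnc2ccc(OC)cc12",
    "vandetanib", "COc1cc2c(Nc3ccc(Br)cc3F)ncnc2cc1OCC1CCN(C)CC1",
    "ibutilide", "CCCCCCCN(CC)CCCC(O)c1ccc(NS(C)(=O)=O)cc1",
    "dofetilide", "CN(CCOc1ccc(NS(C)(=O)=O)cc1)CCc1ccc(NS(C)(=O)=O)cc1",
    "disopyramide", "CC(C)N(CCC(C(N)=O)(c1ccccc1)c1ccccn1)C(C)C",
    "phenytoin", "C1=CC=C(C=C1)C2(C(=O)NC(=O)N2)C3=CC=CC=C3",
    "valproate", "CCCC(CCC)C(=O)O",
    "fluvastatin", "CC(C)n1c(C=CC(O)CC(O)CC(=O)O)c(-c2ccc(F)cc2)c2ccccc21",
    "lovastatin", "CCC(C)C(=O)OC1CC(C)C=C2C=CC(C)C(CCC3CC(O)CC(=O)O3)C21",
    "pravastatin", "CCC(C)C(=O)OC1CC(O)C=C2C=CC(C)C(CCC(O)CC(O)CC(=O)O)C21",
    "atorvastatin", "CC(C)c1c(C(=O)Nc2ccccc2)c(-c2ccccc2)c(-c2ccc(F)cc2)n1CCC(O)CC(O)CC(=O)O",
    "rosuvastatin", "CC(C)c1nc(N(C)S(C)(=O)=O)nc(-c2ccc(F)cc2)c1C=CC(O)CC(O)CC(=O)O",
    "pitavastatin", "O=C(O)CC(O)CC(O)C=Cc1c(C2CC2)nc2ccccc2c1-c1ccc(F)cc1",
    "simvastatin", "CCC(C)(C)C(=O)OC1CC(C)C=C2C=CC(C)C(CCC3CC(O)CC(=O)O3)C21"
  )
}

# A reusable synthetic corpus: 60 molecules (40 with a planted aryl
# fluoride, 20 without), noiseless.
synthetic_corpus <- function() {
  memo("synthetic_corpus", function() {
    generate_dataset(sim_spec(n_pos = 40L, n_neg = 20L,
                              label_noise_rate = 0,
                              scaffold_size = c(6L, 14L), seed = 421L))
  })
}

# ~1,000 SMILES strings: the corpus canonical forms plus enumerated
# variants of each.
smiles_pool <- function() {
  memo("smiles_pool", function() {
    ds <- synthetic_corpus()
    vars <- unlist(lapply(seq_len(nrow(ds)), function(i) {
      enumerate_smiles(ds$smiles_canonical[i], n = 16L, seed = 1000L + i)
    }))
    unique(c(ds$smiles_canonical, vars))
  })
}

# Small shared reference encoder covering the corpus + drug vocabulary.
tiny_encoder <- function() {
  memo("tiny_encoder", function() {
    vocab <- build_vocab(c(synthetic_corpus()$smiles_canonical,
                           canonicalize_smiles(drug_smiles()$smiles)))
    reference_encoder(encoder_config(d_model = 32L, n_layers = 2L,
                                     n_heads = 2L, vocab = vocab,
                                     seed = 7L))
  })
}

# Independent naive (quadratic) kernelized attention oracle.
naive_kernel_attention <- function(q, k, v, feature = function(x) {
  ifelse(x > 0, x + 1, exp(x))
}) {
  fq <- feature(q)
  fk <- feature(k)
  scores <- fq %*% t(fk)
  A <- scores / rowSums(scores)
  list(output = A %*% v, attention = A)
}

# Write a tiny labeled CSV for chem_io tests.
write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}
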