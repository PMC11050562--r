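test_that("scaffolds respect the heavy-atom range and re-parse as valid", {
  for (i in 1:25) {
    s <- generate_scaffold(c(5L, 5L), seed = i)
    expect_identical(heavy_atom_count(s), 5L)
    expect_no_error(canonicalize_smiles(s))
  }
  for (i in 1:50) {
    s <- generate_scaffold(c(8L, 20L), seed = 1000L + i)
    n <- heavy_atom_count(s)
    expect_gte(n, 8L)
    expect_lte(n, 20L)
  }
})

test_that("scaffold generation is deterministic under a fixed seed", {
  a <- vapply(1:10, function(i) generate_scaffold(c(6L, 12L), seed = 77L),
              character(1))
  expect_identical(length(unique(a)), 1L)
})

test_that("planting a fragment guarantees the paired SMARTS match", {
  for (i in 1:15) {
    scaf <- generate_scaffold(c(8L, 14L), seed = 300L + i)
    planted <- plant_alert(scaf, "c1ccc(F)cc1", seed = i)
    expect_gte(length(match_smarts(planted, "[c][F,Cl,Br,I]")), 1L)
    planted2 <- plant_alert(scaf, "C(=O)O", seed = i)
    expect_gte(length(match_smarts(planted2, "[CX3](=[OX1])[OX2H1]")), 1L)
  }
})

test_that("datasets separate classes by construction and record truth", {
  ds <- synthetic_corpus()
  pat <- parse_smarts("[c][F,Cl,Br,I]")
  truth <- attr(ds, "truth")
  for (i in seq_len(nrow(ds))) {
    hits <- match_smarts(parse_smiles(ds$smiles_canonical[i]), pat)
    expect_identical(length(hits) > 0L, ds$label[i] == "positive")
  }
  # planted atom indices are valid atom indices of their molecule
  for (smi in names(truth$planted_atoms)) {
    n <- heavy_atom_count(smi)
    expect_true(all(unlist(truth$planted_atoms[[smi]]) <= n))
  }
  expect_identical(length(truth$flipped_ids), 0L)
})

test_that("label noise flips exactly round(rate * n) labels and lists them", {
  spec <- sim_spec(n_pos = 25L, n_neg = 15L, label_noise_rate = 0.1,
                   scaffold_size = c(6L, 12L), seed = 88L)
  ds <- generate_dataset(spec)
  truth <- attr(ds, "truth")
  expect_identical(length(truth$flipped_ids), 4L)   # round(0.1 * 40)
  clean <- generate_dataset(sim_spec(n_pos = 25L, n_neg = 15L,
                                     label_noise_rate = 0,
                                     scaffold_size = c(6L, 12L),
                                     seed = 88L))
  flipped <- ds$record_id %in% truth$flipped_ids
  expect_identical(ds$label[!flipped], clean$label[!flipped])
  expect_true(all(ds$label[flipped] != clean$label[flipped]))
})

test_that("generation is deterministic and seeds vary the data", {
  s1 <- generate_dataset(sim_spec(n_pos = 5L, n_neg = 5L,
                                  scaffold_size = c(6L, 10L), seed = 3L))
  s2 <- generate_dataset(sim_spec(n_pos = 5L, n_neg = 5L,
                                  scaffold_size = c(6L, 10L), seed = 3L))
  s3 <- generate_dataset(sim_spec(n_pos = 5L, n_neg = 5L,
                                  scaffold_size = c(6L, 10L), seed = 4L))
  expect_identical(s1$smiles_canonical, s2$smiles_canonical)
  expect_false(identical(s1$smiles_canonical, s3$smiles_canonical))
})

test_that("hard negatives carry the decoy but never the alert", {
  ds <- generate_dataset(sim_spec(n_pos = 5L, n_neg = 10L,
                                  decoy_fragment = "CCF",
                                  scaffold_size = c(6L, 12L), seed = 55L))
  negs <- ds[ds$label == "negative", ]
  arom <- parse_smarts("[c][F,Cl,Br,I]")
  alip <- parse_smarts("[CX4][F,Cl,Br,I]")
  for (smi in negs$smiles_canonical) {
    g <- parse_smiles(smi)
    expect_length(match_smarts(g, arom), 0L)
    expect_gte(length(match_smarts(g, alip)), 1L)
  }
})

test_that("spec validation refuses impossible settings", {
  expect_error(sim_spec(n_pos = 0L), "n_pos")
  expect_error(sim_spec(label_noise_rate = 0.6))
  expect_error(sim_spec(scaffold_size = c(10L, 5L)))
})
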