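test_that("canonicalization maps to a stable canonical form", {
  expect_identical(canonicalize_smiles("OCC"), "CCO")
  expect_identical(canonicalize_smiles("CCO"), "CCO")
})

test_that("canonicalization preserves heavy-atom composition and is idempotent", {
  for (smi in drug_smiles()$smiles) {
    can <- canonicalize_smiles(smi)
    expect_identical(canonicalize_smiles(can), can)
    expect_identical(heavy_atom_count(can), heavy_atom_count(smi))
  }
  # phenytoin: 19 heavy atoms in the printed SMILES
  phen <- drug_smiles()$smiles[drug_smiles()$name == "phenytoin"]
  expect_identical(heavy_atom_count(phen), 19L)
  expect_identical(heavy_atom_count(canonicalize_smiles(phen)), 19L)
})

test_that("canonicalize . canonicalize = canonicalize over a large corpus", {
  pool <- smiles_pool()
  can1 <- canonicalize_smiles(pool)
  can2 <- canonicalize_smiles(can1)
  expect_identical(can1, can2)
})

test_that("stereo descriptors are stripped by default but kept on request", {
  chiral <- "C[C@H](N)C(=O)O"
  plain <- canonicalize_smiles(chiral)
  expect_false(grepl("@", plain, fixed = TRUE))
  kept <- canonicalize_smiles(chiral, keep_stereo = TRUE)
  expect_true(grepl("@", kept, fixed = TRUE))
})

test_that("unparseable SMILES raise a structured parse error", {
  err <- tryCatch(canonicalize_smiles("C1CC"), error = identity)
  expect_s3_class(err, "adralert_parse_error")
  expect_match(conditionMessage(err), "C1CC", fixed = TRUE)
  expect_error(canonicalize_smiles("xx$$yy"), class = "adralert_parse_error")
})

test_that("concern-level mapping is total, deterministic and task-specific", {
  expect_identical(map_concern_to_label("moderate", "DIQT"), "positive")
  expect_identical(map_concern_to_label("most", "DIQT"), "positive")
  expect_identical(map_concern_to_label("ambiguous", "DIQT"), "excluded")
  expect_identical(map_concern_to_label("none", "DIQT"), "negative")
  expect_identical(map_concern_to_label("high", "DIT"), "positive")
  expect_identical(map_concern_to_label("low", "DIT"), "negative")
  expect_identical(map_concern_to_label(c("most", "moderate", "less"), "DIR"),
                   rep("positive", 3))
  expect_identical(map_concern_to_label("none", "DIR"), "negative")
  expect_error(map_concern_to_label("weird", "DIQT"), "accepted")
})

test_that("load_dataset drops invalid rows with counts, never silently", {
  df <- data.frame(
    id = sprintf("D%d", 1:5),
    name = sprintf("drug%d", 1:5),
    smiles = c("CCO", "c1ccccc1", "C1CC", "CCN", "CC(=O)O"),
    label = c("positive", "negative", "positive", "negative", "positive")
  )
  path <- write_fixture_csv(df)
  expect_message(ds <- load_dataset(path), "1 unparseable")
  expect_identical(nrow(ds), 4L)
  ing <- attr(ds, "ingestion")
  expect_identical(ing$n_unparseable, 1L)
  expect_identical(ing$dropped_record_ids, "D3")
})

test_that("load_dataset enforces record_id uniqueness and schema", {
  df <- data.frame(id = c("A", "A"), smiles = c("CCO", "CCN"),
                   label = c("positive", "negative"))
  expect_error(load_dataset(write_fixture_csv(df)), "duplicated record_id")
  df2 <- data.frame(foo = "A", bar = "CCO")
  expect_error(load_dataset(write_fixture_csv(df2)), "schema error")
  expect_error(load_dataset(tempfile()), "not found")
})

test_that("conflicting labels for one structure abort; duplicates merge", {
  # OCC and CCO are the same molecule
  df <- data.frame(id = c("A", "B"), smiles = c("CCO", "OCC"),
                   label = c("positive", "negative"))
  expect_error(load_dataset(write_fixture_csv(df)), "data-quality")
  df2 <- data.frame(id = c("A", "B", "C"), smiles = c("CCO", "OCC", "CCN"),
                    label = c("positive", "positive", "negative"))
  expect_message(ds <- load_dataset(write_fixture_csv(df2)), "1 duplicates")
  expect_identical(nrow(ds), 2L)
})

test_that("salts lose their counter-ion before canonicalization", {
  df <- data.frame(id = "A", smiles = "CC(=O)O.[Na+]", label = "positive")
  ds <- load_dataset(write_fixture_csv(df))
  expect_identical(ds$smiles_canonical, canonicalize_smiles("CC(=O)O"))
  expect_identical(attr(ds, "ingestion")$n_fragment_stripped, 1L)
})

test_that("an imbalanced dataset reports its class counts", {
  ds <- synthetic_corpus()
  expect_identical(attr(ds, "n_pos") + attr(ds, "n_neg"), nrow(ds))
  tmp <- tempfile(fileext = ".csv")
  rep_path <- tempfile(fileext = ".json")
  write_synthetic(ds, tmp)
  ds2 <- load_dataset(tmp, schema = list(id = "record_id", name = "name",
                                         smiles = "smiles_canonical",
                                         label = "label"))
  expect_identical(attr(ds2, "n_pos"), attr(ds, "n_pos"))
  expect_identical(attr(ds2, "n_neg"), attr(ds, "n_neg"))
  write_dataset(ds2, tmp, rep_path)
  rep <- jsonlite::read_json(rep_path)
  expect_identical(rep$n_pos, as.integer(attr(ds, "n_pos")))
})
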