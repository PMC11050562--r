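# The synthetic planted-alert study at full scale (100 positives, 100
# negatives, 5% label noise), shared by the end-to-end acceptance checks.
# Built once per test run; all seeds fixed.

study_conditions <- function() {
  list(
    spec = sim_spec(n_pos = 100L, n_neg = 100L,
                    alert_smarts = "[c][F,Cl,Br,I]",
                    fragment_smiles = "c1ccc(F)cc1",
                    label_noise_rate = 0.05,
                    scaffold_size = c(8L, 20L), seed = 7L),
    encoder_seed = 11L,
    train = train_config(max_epochs = 40L, early_stop_patience = 6L,
                         seed = 1L),
    multiplicity = 3L,
    cv_seed = 13L
  )
}

study_dataset <- function() {
  memo("study_dataset", function() generate_dataset(study_conditions()$spec))
}

study_encoder <- function() {
  memo("study_encoder", function() {
    reference_encoder(encoder_config(
      vocab = build_vocab(study_dataset()$smiles_canonical),
      seed = study_conditions()$encoder_seed))
  })
}

study_cv <- function() {
  memo("study_cv", function() {
    cond <- study_conditions()
    run_cv(study_dataset(), study_encoder(),
           train_cfg = cond$train, multiplicity = cond$multiplicity,
           seed = cond$cv_seed)
  })
}
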