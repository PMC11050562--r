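# Leakage-safe stratified group fivefold cross-validation of the full
# encode -> augment -> train -> score pipeline, with Table-style
# mean +/- sd reporting.
#
# Folds partition drugs (group_id), never SMILES variants: augmentation is
# applied after splitting and only to the training side, and each held-out
# drug is scored once on its canonical SMILES.

#' Stratified group k-fold assignment
#'
#' Assigns each group to exactly one fold with per-class fold counts
#' within one of perfect stratification.
#'
#' @param dataset An `adr_dataset` (or tibble with `group_id`, `label`).
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return A tibble `group_id`, `label`, `fold`.
#' @export
stratified_group_kfold <- function(dataset, k = 5L, seed = 1L) {
  groups <- dataset |>
    dplyr::distinct(.data$group_id, .data$label)
  if (anyDuplicated(groups$group_id)) {
    stop("a group_id appears with both labels; groups must be label-pure",
         call. = FALSE)
  }
  counts <- table(groups$label)
  if (any(counts < k)) {
    stop(sprintf(
      "stratification error: class '%s' has %d groups, fewer than k = %d",
      names(counts)[which.min(counts)], min(counts), k), call. = FALSE)
  }
  rng <- .local_rng(.derive_seed(seed, 733L))
  out <- groups |>
    dplyr::group_by(.data$label) |>
    dplyr::group_modify(function(df, key) {
      perm <- rng$sample_perm(nrow(df))
      df$fold <- (seq_len(nrow(df))[order(perm)] - 1L) %% k + 1L
      df
    }) |>
    dplyr::ungroup()
  out[, c("group_id", "label", "fold")]
}

#' Run fivefold cross-validation of the ADR pipeline
#'
#' For each fold: augment the training groups by SMILES enumeration,
#' encode, train the CNN head, score the held-out drugs on their canonical
#' SMILES, and compute the nine-metric report. Aggregates per-fold metrics
#' as mean and sample (n-1) standard deviation.
#'
#' @param dataset An `adr_dataset`.
#' @param encoder An `encoder_handle`; must cover the dataset vocabulary.
#' @param head_cfg A [head_config()] (d_in must equal the encoder width).
#' @param train_cfg A [train_config()].
#' @param k Number of folds.
#' @param multiplicity Augmentation multiplicity for training folds
#'   (1 = no augmentation).
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return An `adr_cv` object: list with `per_fold` (tibble of fold x
#'   metrics), `summary` (metric, mean, sd), `fold_table`, `predictions`
#'   (per-drug out-of-fold scores) and a `provenance` list.
#' @export
run_cv <- function(dataset, encoder, head_cfg = NULL,
                   train_cfg = train_config(), k = 5L,
                   multiplicity = 5L, seed = 1L) {
  stopifnot(inherits(encoder, "encoder_handle"))
  if (is.null(head_cfg)) {
    head_cfg <- head_config(d_in = encoder$config$d_model)
  }
  if (head_cfg$d_in != encoder$config$d_model) {
    stop("shape error: head d_in must equal encoder d_model", call. = FALSE)
  }
  folds <- stratified_group_kfold(dataset, k = k,
                                  seed = .derive_seed(seed, 1L))
  ds <- dplyr::left_join(tibble::as_tibble(dataset),
                         folds[, c("group_id", "fold")], by = "group_id")

  # encode cache: every canonical SMILES and variant encoded exactly once
  cache <- new.env(parent = emptyenv())
  embed_of <- function(smiles) {
    key <- smiles
    got <- get0(key, envir = cache)
    if (is.null(got)) {
      got <- encode(smiles, encoder)$embeddings
      assign(key, got, envir = cache)
    }
    got
  }

  per_fold <- list()
  preds <- list()
  for (f in seq_len(k)) {
    train_df <- ds[ds$fold != f, , drop = FALSE]
    test_df <- ds[ds$fold == f, , drop = FALSE]
    aug <- augment_training_split(train_df, multiplicity = multiplicity,
                                  seed = .derive_seed(seed, 100L + f))
    tr_emb <- lapply(aug$smiles, embed_of)
    te_emb <- lapply(test_df$smiles_canonical, embed_of)
    tc <- train_cfg
    tc$seed <- .derive_seed(seed, 200L + f)
    model <- tryCatch(
      train_head(build_head(head_cfg, seed = .derive_seed(seed, 300L + f)),
                 tr_emb, aug$label, tc,
                 encoder_fingerprint = encoder$fingerprint),
      error = function(e) {
        stop(sprintf("CV aborted at fold %d: %s", f, conditionMessage(e)),
             call. = FALSE)
      }
    )
    pr <- predict(model, te_emb)
    cc <- confusion(test_df$label, pr$label)
    mr <- compute_metrics(cc, scores = pr$p_positive, y_true = test_df$label)
    per_fold[[f]] <- dplyr::bind_cols(tibble::tibble(fold = f), mr)
    preds[[f]] <- tibble::tibble(
      group_id = test_df$group_id, fold = f, label = test_df$label,
      p_positive = pr$p_positive, predicted = pr$label
    )
  }
  per_fold <- dplyr::bind_rows(per_fold)
  summary <- per_fold |>
    tidyr::pivot_longer(-"fold", names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = stats::sd(.data$value), .groups = "drop")
  structure(
    list(per_fold = per_fold, summary = summary, fold_table = folds,
         predictions = dplyr::bind_rows(preds),
         provenance = list(
           task_name = attr(dataset, "task_name"),
           n_groups = nrow(folds), k = k, multiplicity = multiplicity,
           seed = seed, encoder_fingerprint = encoder$fingerprint,
           encoder_kind = encoder$kind,
           head_config = unclass(head_cfg),
           train_config = unclass(train_cfg))),
    class = "adr_cv"
  )
}

#' @export
print.adr_cv <- function(x, ...) {
  cat(sprintf("<adr_cv '%s'> %d folds over %d groups\n",
              x$provenance$task_name, x$provenance$k, x$provenance$n_groups))
  print(metric_table(x))
  invisible(x)
}

#' Metric table in report form
#'
#' Formats the cross-validation summary in the conventional row order
#' (Accuracy, Recall rate, Precision, MCC, BACC, F1 score, AUROC, AUPRC,
#' Specificity) as "mean +/- sd" to three decimals.
#'
#' @param cv An `adr_cv`.
#' @return A tibble with `metric` and `value` columns.
#' @export
metric_table <- function(cv) {
  stopifnot(inherits(cv, "adr_cv"))
  order_names <- c(accuracy = "Accuracy", recall_rate = "Recall rate",
                   precision = "Precision", mcc = "MCC", bacc = "BACC",
                   f1 = "F1 score", auroc = "AUROC", auprc = "AUPRC",
                   specificity = "Specificity")
  s <- cv$summary
  rows <- lapply(names(order_names), function(m) {
    r <- s[s$metric == m, ]
    tibble::tibble(
      metric = order_names[[m]],
      value = sprintf("%.3f ± %.3f", r$mean, r$sd)
    )
  })
  dplyr::bind_rows(rows)
}

#' Tidy per-fold cross-validation metrics
#'
#' @param x An `adr_cv`.
#' @param ... Unused.
#' @return A long tibble: `fold`, `metric`, `value`.
#' @method tidy adr_cv
#' @export
tidy.adr_cv <- function(x, ...) {
  x$per_fold |>
    tidyr::pivot_longer(-"fold", names_to = "metric", values_to = "value")
}

#' One-row cross-validation summary
#'
#' @param x An `adr_cv`.
#' @param ... Unused.
#' @return A one-row tibble of metric means (suffix `_sd` for spreads).
#' @method glance adr_cv
#' @export
glance.adr_cv <- function(x, ...) {
  means <- stats::setNames(as.list(x$summary$mean), x$summary$metric)
  sds <- stats::setNames(as.list(x$summary$sd),
                         paste0(x$summary$metric, "_sd"))
  tibble::as_tibble(c(means, sds))
}

#' Plot per-fold metric spread
#'
#' @param object An `adr_cv`.
#' @param ... Unused.
#' @return A ggplot object: per-fold points with mean bars per metric.
#' @method autoplot adr_cv
#' @export
autoplot.adr_cv <- function(object, ...) {
  long <- tidy.adr_cv(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.5,
                          linewidth = 0.3, color = "steelblue") +
    ggplot2::labs(x = NULL, y = "metric value",
                  title = sprintf("Cross-validation metrics (%s)",
                                  object$provenance$task_name)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Serialize a cross-validation result
#'
#' Writes the per-fold metrics, summary, fold table and provenance as JSON
#' and the formatted metric table as CSV.
#'
#' @param cv An `adr_cv`.
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @return `cv`, invisibly.
#' @export
write_cv_result <- function(cv, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(per_fold = cv$per_fold, summary = cv$summary,
           fold_table = cv$fold_table, provenance = cv$provenance),
      json_path, auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  if (!is.null(csv_path)) {
    utils::write.csv(metric_table(cv), csv_path, row.names = FALSE)
  }
  invisible(cv)
}
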