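# Reading, validating and normalizing labeled molecule tables.
#
# Canonicalization is delegated to Open Babel (via ChemmineOB), the same
# class of toolkit used to prepare the curated ADR datasets. All canonical
# SMILES in the package are Open Babel canonical SMILES.

#' Canonicalize SMILES strings
#'
#' Converts SMILES to canonical form. With `keep_stereo = FALSE` (default)
#' stereo descriptors (`@`, `/`, `\\`) are removed first, matching the
#' convention of drug-label datasets whose printed SMILES carry no stereo
#' marks even for chiral drugs.
#'
#' @param smiles Character vector of SMILES strings.
#' @param keep_stereo Keep stereochemistry descriptors?
#' @return Character vector of canonical SMILES, same length as input.
#'   Canonicalization is idempotent: applying it to its own output returns
#'   the output unchanged.
#' @examples
#' \donttest{
#' canonicalize_smiles("OCC")   # "CCO"
#' }
#' @export
canonicalize_smiles <- function(smiles, keep_stereo = FALSE) {
  out <- .canonicalize_quiet(smiles, keep_stereo)
  if (anyNA(out)) {
    bad <- smiles[is.na(out)]
    stop(structure(
      class = c("adralert_parse_error", "error", "condition"),
      list(
        message = sprintf(
          "unparseable SMILES: %s",
          paste(sprintf("'%s'", utils::head(bad, 5)), collapse = ", ")
        ),
        call = NULL, offending = bad
      )
    ))
  }
  out
}

# Vectorized canonicalization returning NA for unparseable inputs.
# Inputs are tagged with an index title so dropped molecules re-align.
.canonicalize_quiet <- function(smiles, keep_stereo = FALSE) {
  if (length(smiles) == 0L) return(character(0))
  s <- as.character(smiles)
  if (!keep_stereo) s <- .strip_stereo(s)
  ok <- !is.na(s) & nzchar(s) & !grepl("[ \t\n]", s)
  out <- rep(NA_character_, length(s))
  if (!any(ok)) return(out)
  convert <- function(idx) {
    payload <- paste(sprintf("%s idx%d", s[idx], idx), collapse = "\n")
    res <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", payload),
      error = function(e) ""
    )
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(trimws(lines))]
    for (ln in lines) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) >= 2L && grepl("^idx[0-9]+$", trimws(parts[2]))) {
        i <- as.integer(sub("idx", "", trimws(parts[2])))
        can <- trimws(parts[1])
        if (nzchar(can)) out[i] <<- can
      }
    }
  }
  convert(which(ok))
  # an unparseable entry can abort the remainder of a batch: retry every
  # still-missing input on its own so one bad row cannot shadow good ones
  missing <- which(ok & is.na(out))
  for (i in missing) convert(i)
  out
}

.strip_stereo <- function(s) {
  s <- gsub("[/\\\\]", "", s)
  s <- gsub("@{1,2}", "", s)
  # [CH] etc. left bracketed: still valid SMILES with explicit H
  s
}

#' Keep the largest covalent fragment of a SMILES
#'
#' Drops counter-ions and minor components of salts/mixtures (dot-separated
#' fragments), keeping the fragment with the most heavy atoms.
#'
#' @param smiles Character vector of SMILES.
#' @return A list with `smiles` (largest fragment per input) and
#'   `stripped` (logical: was anything removed?).
#' @export
largest_fragment <- function(smiles) {
  res <- vapply(smiles, function(s) {
    if (is.na(s) || !grepl(".", s, fixed = TRUE)) return(s)
    g <- tryCatch(parse_smiles(s), error = function(e) NULL)
    if (is.null(g)) return(s)
    comp <- .mol_components(g)
    sizes <- table(comp)
    keep <- as.integer(names(sizes)[which.max(sizes)])
    sub <- .subgraph(g, which(comp == keep))
    write_smiles(sub)
  }, character(1), USE.NAMES = FALSE)
  list(smiles = res, stripped = grepl(".", smiles, fixed = TRUE))
}

.subgraph <- function(g, atom_idx) {
  remap <- integer(nrow(g$atoms))
  remap[atom_idx] <- seq_along(atom_idx)
  atoms <- g$atoms[atom_idx, , drop = FALSE]
  atoms$idx <- seq_len(nrow(atoms))
  keep_b <- g$bonds$from %in% atom_idx & g$bonds$to %in% atom_idx
  bonds <- g$bonds[keep_b, , drop = FALSE]
  bonds$from <- remap[bonds$from]
  bonds$to <- remap[bonds$to]
  out <- list(atoms = atoms, bonds = bonds, smiles = NA_character_)
  class(out) <- "mol_graph"
  out
}

#' Map drug-label concern levels to binary labels
#'
#' Implements the task-specific mapping used by the curated drug-induced
#' QT-prolongation (DIQT), teratogenicity (DIT) and rhabdomyolysis (DIR)
#' datasets: DIQT takes most/moderate concern as positive, no concern as
#' negative and ambiguous as excluded; DIT maps high/low teratogenic risk
#' to positive/negative; DIR takes most/moderate/less concern as positive
#' and no concern as negative.
#'
#' @param concern_level Character vector of concern levels.
#' @param task One of `"DIQT"`, `"DIT"`, `"DIR"`.
#' @return Character vector over `{"positive", "negative", "excluded"}`.
#' @export
map_concern_to_label <- function(concern_level,
                                 task = c("DIQT", "DIT", "DIR")) {
  task <- match.arg(task)
  maps <- list(
    DIQT = c(most = "positive", moderate = "positive",
             ambiguous = "excluded", less = "excluded", none = "negative"),
    DIT = c(high = "positive", low = "negative"),
    DIR = c(most = "positive", moderate = "positive", less = "positive",
            none = "negative")
  )
  map <- maps[[task]]
  lv <- tolower(trimws(as.character(concern_level)))
  unknown <- setdiff(unique(lv), names(map))
  if (length(unknown) > 0L) {
    stop(sprintf(
      "unknown concern level(s) %s for task %s; accepted: %s",
      paste(sprintf("'%s'", unknown), collapse = ", "), task,
      paste(names(map), collapse = ", ")
    ), call. = FALSE)
  }
  unname(map[lv])
}

#' Load and normalize a labeled molecule table
#'
#' Reads a CSV/TSV of drugs with SMILES and either binary labels or concern
#' levels, keeps each molecule's largest covalent fragment, canonicalizes,
#' drops (and counts) unparseable rows, merges duplicate canonical SMILES
#' with agreeing labels, and rejects label conflicts. Nothing is dropped
#' silently: the attrition report is attached to the result.
#'
#' @param path Path to a delimited text file with a header.
#' @param task `"DIQT"`, `"DIT"` or `"DIR"`; required when labels come from
#'   a concern-level column.
#' @param schema Named list mapping the roles `id`, `name`, `smiles`,
#'   `label`, `concern` to column names in the file. `label` and `concern`
#'   are alternatives; `name` is optional.
#' @param sep Field separator (default `","`; use `"\t"` for TSV).
#' @param keep_stereo Passed to [canonicalize_smiles()].
#' @return An `adr_dataset`: a tibble with columns `record_id`, `name`,
#'   `smiles_raw`, `smiles_canonical`, `label`, `group_id`, with attributes
#'   `task_name`, `n_pos`, `n_neg` and `ingestion` (drop/merge counts).
#' @export
load_dataset <- function(path, task = NULL,
                         schema = list(id = "id", name = "name",
                                       smiles = "smiles", label = "label",
                                       concern = "concern_level"),
                         sep = ",", keep_stereo = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("dataset file not found: '%s'", path), call. = FALSE)
  }
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c(schema$id, schema$smiles)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("schema error: missing column(s) %s in '%s'",
                 paste(sprintf("'%s'", missing_cols), collapse = ", "), path),
         call. = FALSE)
  }
  has_label <- !is.null(schema$label) && schema$label %in% names(df)
  has_concern <- !is.null(schema$concern) && schema$concern %in% names(df)
  if (!has_label && !has_concern) {
    stop("schema error: need either a binary label column or a concern-level column",
         call. = FALSE)
  }
  ids <- as.character(df[[schema$id]])
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicated record_id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  nm <- if (!is.null(schema$name) && schema$name %in% names(df)) {
    as.character(df[[schema$name]])
  } else {
    ids
  }
  normalize_dataset(
    tibble::tibble(
      record_id = ids, name = nm,
      smiles_raw = as.character(df[[schema$smiles]]),
      label_in = if (has_label) tolower(as.character(df[[schema$label]]))
                 else NA_character_,
      concern = if (has_concern) as.character(df[[schema$concern]])
                else NA_character_
    ),
    task = task, use_concern = !has_label, keep_stereo = keep_stereo,
    source = path
  )
}

# Shared normalization core for load_dataset and in-memory tables.
normalize_dataset <- function(raw, task, use_concern, keep_stereo, source) {
  n_in <- nrow(raw)
  if (use_concern) {
    if (is.null(task)) {
      stop("task is required to map concern levels to labels", call. = FALSE)
    }
    raw$label <- map_concern_to_label(raw$concern, task)
  } else {
    bad <- setdiff(unique(raw$label_in), c("positive", "negative", "1", "0"))
    if (length(bad) > 0L) {
      stop(sprintf("unrecognized label value(s): %s (accepted: positive, negative, 1, 0)",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    raw$label <- ifelse(raw$label_in %in% c("positive", "1"),
                        "positive", "negative")
  }
  n_excluded <- sum(raw$label == "excluded")
  raw <- raw[raw$label != "excluded", , drop = FALSE]

  frag <- largest_fragment(raw$smiles_raw)
  n_fragment_stripped <- sum(frag$stripped, na.rm = TRUE)
  can <- .canonicalize_quiet(frag$smiles, keep_stereo = keep_stereo)
  n_unparseable <- sum(is.na(can))
  dropped_ids <- raw$record_id[is.na(can)]
  keep <- !is.na(can)
  out <- tibble::tibble(
    record_id = raw$record_id[keep], name = raw$name[keep],
    smiles_raw = raw$smiles_raw[keep], smiles_canonical = can[keep],
    label = raw$label[keep], group_id = raw$record_id[keep]
  )

  # duplicate canonical structures: merge if labels agree, abort otherwise
  conflicts <- out |>
    dplyr::distinct(.data$smiles_canonical, .data$label) |>
    dplyr::count(.data$smiles_canonical) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(conflicts) > 0L) {
    stop(sprintf(
      "data-quality error: %d canonical SMILES appear with both labels (first: '%s')",
      nrow(conflicts), conflicts$smiles_canonical[1]
    ), call. = FALSE)
  }
  n_before_merge <- nrow(out)
  out <- out |> dplyr::distinct(.data$smiles_canonical, .keep_all = TRUE)
  n_merged <- n_before_merge - nrow(out)

  if (nrow(out) == 0L) {
    stop("empty dataset: no rows survived validation", call. = FALSE)
  }
  ingestion <- list(
    source = source, n_input = n_in, n_excluded = n_excluded,
    n_fragment_stripped = n_fragment_stripped,
    n_unparseable = n_unparseable, dropped_record_ids = dropped_ids,
    n_duplicates_merged = n_merged, n_retained = nrow(out)
  )
  if (n_unparseable + n_excluded + n_merged > 0L) {
    message(sprintf(
      "load_dataset: %d input rows -> %d retained (%d excluded by label map, %d unparseable, %d duplicates merged)",
      n_in, nrow(out), n_excluded, n_unparseable, n_merged
    ))
  }
  new_adr_dataset(out, task_name = if (is.null(task)) "custom" else task,
                  ingestion = ingestion)
}

new_adr_dataset <- function(tbl, task_name, ingestion = NULL) {
  stopifnot(all(c("record_id", "smiles_canonical", "label", "group_id")
                %in% names(tbl)))
  attr(tbl, "task_name") <- task_name
  attr(tbl, "n_pos") <- sum(tbl$label == "positive")
  attr(tbl, "n_neg") <- sum(tbl$label == "negative")
  attr(tbl, "ingestion") <- ingestion
  class(tbl) <- c("adr_dataset", class(tibble::tibble()))
  tbl
}

#' @export
print.adr_dataset <- function(x, ...) {
  cat(sprintf("<adr_dataset '%s'> %d molecules (%d positive, %d negative)\n",
              attr(x, "task_name"), nrow(x),
              attr(x, "n_pos"), attr(x, "n_neg")))
  NextMethod()
}

#' Write a normalized dataset and its ingestion report
#'
#' @param dataset An `adr_dataset`.
#' @param csv_path Output CSV path (`record_id`, `name`, `smiles_canonical`,
#'   `label`, `group_id`).
#' @param report_path Optional JSON path for the ingestion report.
#' @return `csv_path`, invisibly.
#' @export
write_dataset <- function(dataset, csv_path, report_path = NULL) {
  utils::write.csv(
    dataset[, c("record_id", "name", "smiles_canonical", "label", "group_id")],
    csv_path, row.names = FALSE
  )
  if (!is.null(report_path)) {
    rep <- attr(dataset, "ingestion")
    if (is.null(rep)) rep <- list()
    rep$task_name <- attr(dataset, "task_name")
    rep$n_pos <- attr(dataset, "n_pos")
    rep$n_neg <- attr(dataset, "n_neg")
    jsonlite::write_json(rep, report_path, auto_unbox = TRUE, null = "null")
  }
  invisible(csv_path)
}
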