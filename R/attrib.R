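# Attention-based structural attribution: average-pool the encoder's
# attention tensors into per-atom importance scores, select the attended
# substructure, and match it against a SMARTS structural-alert catalog.

#' Average-pool attention tensors into per-token scores
#'
#' Pools the materialized attention maps over layers and heads, then over
#' one axis: with the default `"received"` policy a token's score is the
#' mean attention it receives (column mean over non-pad, non-boundary
#' rows); `"emitted"` uses row means; `"symmetric"` averages both.
#' Boundary and pad tokens are excluded from both axes.
#'
#' @param encoded An `encoded_molecule` from [encode()].
#' @param policy `"received"` (default), `"emitted"` or `"symmetric"`.
#' @return Numeric vector of nonnegative scores, one per non-boundary
#'   token, named by token.
#' @export
pool_attention <- function(encoded,
                           policy = c("received", "emitted", "symmetric")) {
  policy <- match.arg(policy)
  stopifnot(inherits(encoded, "encoded_molecule"))
  if (length(encoded$attention) == 0L) {
    stop("input error: encoded molecule carries no attention maps",
         call. = FALSE)
  }
  keep <- encoded$pad_mask & !encoded$is_boundary
  mats <- unlist(encoded$attention, recursive = FALSE)
  M <- Reduce(`+`, mats) / length(mats)          # mean over layers & heads
  M <- M[keep, keep, drop = FALSE]
  scores <- switch(policy,
    received = colMeans(M),
    emitted = rowMeans(M),
    symmetric = (colMeans(M) + rowMeans(M)) / 2
  )
  names(scores) <- encoded$tokens$token
  scores
}

#' Map token scores to per-atom scores
#'
#' Atom tokens pass their score to their atom; non-atom tokens (bonds,
#' ring digits, parentheses) carry no atom and are dropped.
#'
#' @param token_scores Numeric vector over non-boundary tokens (the output
#'   of [pool_attention()]).
#' @param tokens Token tibble from [tokenize_smiles()] (also found in
#'   `encoded$tokens`).
#' @return Numeric vector of length heavy-atom count, in atom order.
#' @export
tokens_to_atoms <- function(token_scores, tokens) {
  if (length(token_scores) != nrow(tokens)) {
    stop("mapping error: token scores and token table disagree in length",
         call. = FALSE)
  }
  sel <- tokens$is_atom
  out <- token_scores[sel]
  names(out) <- tokens$token[sel]
  if (anyNA(out)) {
    stop("mapping error: atom token without a score", call. = FALSE)
  }
  out
}

#' Select the attended substructure
#'
#' Picks the atoms whose scores fall in the top `top_fraction` of atoms
#' (ties broken by score descending, then atom index ascending), then
#' expands the selection to complete any catalog group that overlaps it.
#'
#' @param atom_scores Numeric per-atom scores.
#' @param mol A `mol_graph` (or SMILES string) for catalog completion.
#' @param top_fraction Fraction of atoms selected, in (0, 1].
#' @param catalog Optional [alert_catalog()] used to complete overlapping
#'   matched groups.
#' @return Sorted integer vector of selected atom indices.
#' @export
select_substructure <- function(atom_scores, mol = NULL, top_fraction = 0.3,
                                catalog = NULL) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  n <- length(atom_scores)
  k <- max(1L, floor(top_fraction * n + 1e-9))
  ord <- order(-atom_scores, seq_len(n))
  sel <- sort(ord[seq_len(k)])
  if (!is.null(catalog) && !is.null(mol)) {
    if (is.character(mol)) mol <- parse_smiles(mol)
    for (i in seq_len(nrow(catalog))) {
      hits <- match_smarts(mol, catalog$pattern[[i]])
      for (h in hits) {
        if (length(intersect(h, sel)) > 0L) sel <- union(sel, h)
      }
    }
    sel <- sort(sel)
  }
  sel
}

#' Load a structural-alert catalog
#'
#' Reads a TSV with columns `alert_name`, `smarts`, `source`; every SMARTS
#' is compiled at load and failures name the offending entry. With no
#' arguments, loads the catalog shipped with the package (amines, aniline,
#' alcohol, ether, aromatic halide, carboxylic acid, imide N-H,
#' sulfonamide and related groups).
#'
#' @param path TSV path; `NULL` for the built-in catalog.
#' @return A tibble `alert_name`, `smarts`, `source`, `pattern`
#'   (compiled), of class `alert_catalog`.
#' @export
alert_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "structural_alerts.tsv",
                        package = "adralert")
  }
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("alert_name", "smarts", "source")
  if (!all(need %in% names(df))) {
    stop(sprintf("catalog error: '%s' must have columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(df$alert_name)) {
    stop("catalog error: duplicate alert_name entries", call. = FALSE)
  }
  pats <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    pats[[i]] <- tryCatch(
      parse_smarts(df$smarts[i]),
      error = function(e) {
        stop(sprintf("catalog error in entry '%s': %s",
                     df$alert_name[i], conditionMessage(e)), call. = FALSE)
      }
    )
  }
  out <- tibble::as_tibble(df[, need])
  out$pattern <- pats
  class(out) <- c("alert_catalog", class(out))
  out
}

#' Match structural alerts against a molecule
#'
#' Every catalog SMARTS is matched against the whole molecule; each match
#' is reported with its overlap fraction against the selected atoms, so
#' near-misses of the attended substructure stay visible.
#'
#' @param mol A `mol_graph` or SMILES string.
#' @param selected_atoms Integer atom indices (e.g. from
#'   [select_substructure()]); may be empty.
#' @param catalog An [alert_catalog()].
#' @return A tibble `alert_name`, `atom_indices` (list column),
#'   `overlap`, sorted by overlap descending then alert name.
#' @export
match_alerts <- function(mol, selected_atoms = integer(0),
                         catalog = alert_catalog()) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  stopifnot(nrow(catalog) > 0L)
  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    hits <- match_smarts(mol, catalog$pattern[[i]])
    for (h in hits) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        alert_name = catalog$alert_name[i],
        atom_indices = list(sort(h)),
        overlap = if (length(h) > 0L) {
          length(intersect(h, selected_atoms)) / length(h)
        } else {
          0
        }
      )
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(alert_name = character(),
                          atom_indices = list(), overlap = numeric()))
  }
  dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$overlap), .data$alert_name)
}

#' Full attention-attribution report for one molecule
#'
#' Encodes the canonical SMILES, pools attention into atom scores, selects
#' the attended substructure and matches the alert catalog.
#'
#' @param smiles A SMILES string (canonicalized internally).
#' @param encoder An `encoder_handle`.
#' @param catalog An [alert_catalog()].
#' @param policy Pooling policy, see [pool_attention()].
#' @param top_fraction See [select_substructure()].
#' @param n_average Average per-atom scores over this many enumerated
#'   SMILES renderings for stability (0 = canonical rendering only, the
#'   default); the atom correspondence between renderings is exact.
#' @param seed Seed for the enumeration used when `n_average > 0`.
#' @return An `alert_report`: list with `smiles`, `atom_scores`,
#'   `selected_atoms`, `matches` (tibble), `policy`, `top_fraction`.
#' @export
attribute_molecule <- function(smiles, encoder,
                               catalog = alert_catalog(),
                               policy = "received", top_fraction = 0.3,
                               n_average = 0L, seed = 1L) {
  can <- canonicalize_smiles(smiles)
  enc <- encode(can, encoder)
  tok_scores <- pool_attention(enc, policy = policy)
  g <- parse_smiles(can)
  atom_scores <- tokens_to_atoms(tok_scores, enc$tokens)
  if (n_average > 0L) {
    acc <- unname(atom_scores)
    n_used <- 1L
    rng <- .local_rng(.derive_seed(seed, 909L))
    for (k in seq_len(n_average)) {
      v <- write_smiles(g, priority = rng$sample_perm(nrow(g$atoms)))
      ord <- attr(v, "atom_order")
      ev <- tryCatch(encode(as.character(v), encoder),
                     error = function(e) NULL)
      if (is.null(ev)) next
      vs <- tokens_to_atoms(pool_attention(ev, policy = policy),
                            ev$tokens)
      acc[ord] <- acc[ord] + unname(vs)
      n_used <- n_used + 1L
    }
    atom_scores <- stats::setNames(acc / n_used, names(atom_scores))
  }
  sel <- select_substructure(atom_scores, g, top_fraction = top_fraction,
                             catalog = catalog)
  matches <- match_alerts(g, sel, catalog)
  structure(
    list(smiles = can, atom_scores = unname(atom_scores),
         selected_atoms = sel, matches = matches, policy = policy,
         top_fraction = top_fraction),
    class = "alert_report"
  )
}

#' @export
print.alert_report <- function(x, ...) {
  cat(sprintf("<alert_report> %s\n  selected atoms: %s\n",
              x$smiles, paste(x$selected_atoms, collapse = ",")))
  if (nrow(x$matches) > 0L) {
    for (i in seq_len(nrow(x$matches))) {
      cat(sprintf("  %-24s overlap %.2f  atoms %s\n",
                  x$matches$alert_name[i], x$matches$overlap[i],
                  paste(x$matches$atom_indices[[i]], collapse = ",")))
    }
  } else {
    cat("  no catalog matches\n")
  }
  invisible(x)
}

#' Serialize an alert report to JSON
#'
#' @param report An `alert_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alert_report <- function(report, path) {
  jsonlite::write_json(
    list(smiles = report$smiles, atom_scores = report$atom_scores,
         selected_atoms = report$selected_atoms,
         matches = list(
           alert_name = report$matches$alert_name,
           atom_indices = report$matches$atom_indices,
           overlap = report$matches$overlap),
         policy = report$policy, top_fraction = report$top_fraction),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
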