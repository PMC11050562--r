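# Synthetic planted-alert benchmark data.
#
# Generates labeled SMILES datasets shaped like the curated ADR datasets
# (a few hundred molecules, imbalanced classes): positives carry a planted
# alert substructure, negatives are rejection-sampled against the alert
# SMARTS, and a configurable fraction of labels is flipped. The alert
# SMARTS is a perfect class oracle on noiseless data, so every pipeline
# stage can be validated offline against known ground truth.

#' Specification for a synthetic planted-alert dataset
#'
#' @param n_pos,n_neg Class sizes (>= 1). Defaults mirror the
#'   rhabdomyolysis atlas shape (155 positive / 39 negative).
#' @param alert_smarts SMARTS the planted fragment must (positives) or
#'   must not (negatives) match.
#' @param fragment_smiles Attachable fragment grafted onto positive
#'   scaffolds; its first atom is the attachment point.
#' @param label_noise_rate Fraction of labels flipped, in [0, 0.5).
#' @param scaffold_size Heavy-atom range `c(min, max)` for random scaffolds.
#' @param decoy_fragment Optional fragment grafted onto negatives (a
#'   "hard negative" that must still not match `alert_smarts`).
#' @param seed Integer seed.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_pos = 155L, n_neg = 39L,
                     alert_smarts = "[c][F,Cl,Br,I]",
                     fragment_smiles = "c1ccc(F)cc1",
                     label_noise_rate = 0,
                     scaffold_size = c(8L, 20L),
                     decoy_fragment = NULL,
                     seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L,
            label_noise_rate >= 0, label_noise_rate < 0.5,
            length(scaffold_size) == 2L,
            scaffold_size[1] <= scaffold_size[2])
  structure(
    list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
         alert_smarts = alert_smarts, fragment_smiles = fragment_smiles,
         label_noise_rate = label_noise_rate,
         scaffold_size = as.integer(scaffold_size),
         decoy_fragment = decoy_fragment, seed = as.integer(seed)),
    class = "sim_spec"
  )
}

#' Generate a random molecular scaffold
#'
#' Assembles a random valid molecule within a heavy-atom range from a
#' stochastic grammar: carbon-rich chains with branches over C/N/O/S,
#' occasional double bonds to O, and an optional 5/6-membered carbon ring,
#' all under valence limits. Validity is verified by re-canonicalization.
#'
#' @param size_range `c(min, max)` heavy atoms.
#' @param seed Integer seed.
#' @return A single SMILES string.
#' @export
generate_scaffold <- function(size_range = c(8L, 20L), seed = 1L) {
  rng <- .local_rng(seed)
  for (attempt in 1:25) {
    s <- .assemble_scaffold(size_range, rng)
    can <- .canonicalize_quiet(s)
    if (!is.na(can) && heavy_atom_count(s) >= size_range[1] &&
        heavy_atom_count(s) <= size_range[2]) {
      return(s)
    }
  }
  stop("scaffold generation failed after 25 attempts", call. = FALSE)
}

.assemble_scaffold <- function(size_range, rng) {
  n_target <- size_range[1] +
    rng$sample_int(size_range[2] - size_range[1] + 1L, 1L) - 1L
  # start from a ring or a chain
  use_ring <- rng$runif(1) < 0.5 && n_target >= 6L
  if (use_ring) {
    ring_n <- if (rng$runif(1) < 0.5) 5L else 6L
    aromatic <- ring_n == 6L && rng$runif(1) < 0.5
    core <- if (aromatic) "c1ccccc1" else
      if (ring_n == 6L) "C1CCCCC1" else "C1CCCC1"
    g <- parse_smiles(core)
  } else {
    g <- parse_smiles("CC")
  }
  elements <- c(rep("C", 8L), "N", "N", "O", "O", "S")
  spare <- function(g) {
    # atoms able to take one more single-bonded neighbor
    which(g$atoms$h_count >= 1L)
  }
  while (nrow(g$atoms) < n_target) {
    sp <- spare(g)
    if (length(sp) == 0L) break
    at <- sp[rng$sample_int(length(sp), 1L)]
    el <- elements[rng$sample_int(length(elements), 1L)]
    # grafted heteroatoms never join aromatic systems here; they hang off it
    g <- .graft_atom(g, at, el,
                     double = el == "O" && !g$atoms$aromatic[at] &&
                       g$atoms$h_count[at] >= 2L && rng$runif(1) < 0.15)
  }
  write_smiles(g)
}

# Attach one new atom to `at` by a single (or double) bond.
.graft_atom <- function(g, at, element, double = FALSE) {
  new_idx <- nrow(g$atoms) + 1L
  g$atoms <- dplyr::bind_rows(g$atoms, tibble::tibble(
    idx = new_idx, element = element, aromatic = FALSE, charge = 0L,
    h_explicit = NA_integer_, bracket = FALSE, token_position = NA_integer_,
    h_count = 0L
  ))
  g$bonds <- dplyr::bind_rows(g$bonds, tibble::tibble(
    from = at, to = new_idx, order = if (double) 2L else 1L,
    aromatic = FALSE
  ))
  g$atoms$h_count <- .implicit_h(g$atoms, g$bonds)
  g
}

#' Graft an alert fragment onto a scaffold
#'
#' Attaches the fragment's first atom to a randomly chosen scaffold atom
#' with an open valence via a single bond.
#'
#' @param scaffold_smiles Scaffold SMILES.
#' @param fragment_smiles Fragment SMILES; atom 1 is the attachment point.
#' @param seed Integer seed.
#' @return A SMILES string containing the fragment.
#' @export
plant_alert <- function(scaffold_smiles, fragment_smiles, seed = 1L) {
  rng <- .local_rng(seed)
  g <- parse_smiles(scaffold_smiles)
  frag <- parse_smiles(fragment_smiles)
  # attach at a carbon with an open valence (never an aromatic ring fusion)
  sp <- which(g$atoms$h_count >= 1L & g$atoms$element == "C")
  if (length(sp) == 0L) sp <- which(g$atoms$h_count >= 1L)
  if (length(sp) == 0L) {
    stop("no attachment point with open valence on scaffold", call. = FALSE)
  }
  at <- sp[rng$sample_int(length(sp), 1L)]
  off <- nrow(g$atoms)
  frag_atoms <- frag$atoms
  frag_atoms$idx <- frag_atoms$idx + off
  frag_bonds <- frag$bonds
  frag_bonds$from <- frag_bonds$from + off
  frag_bonds$to <- frag_bonds$to + off
  g$atoms <- dplyr::bind_rows(g$atoms, frag_atoms)
  g$bonds <- dplyr::bind_rows(
    g$bonds, frag_bonds,
    tibble::tibble(from = at, to = off + 1L, order = 1L, aromatic = FALSE)
  )
  g$atoms$h_count <- .implicit_h(g$atoms, g$bonds)
  write_smiles(g)
}

#' Generate a synthetic planted-alert dataset
#'
#' @param spec A [sim_spec()].
#' @return An `adr_dataset` with attribute `truth`: a list with
#'   `planted_atoms` (named list: canonical SMILES of each positive ->
#'   integer atom indices matched by the alert SMARTS), `flipped_ids`
#'   (record ids whose labels were inverted), and the spec echo.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  pat <- parse_smarts(spec$alert_smarts)
  seen <- character(0)
  recs <- list()
  make_one <- function(positive, i) {
    for (attempt in 1:60) {
      s_seed <- .derive_seed(spec$seed, i * 131L + attempt)
      scaf <- generate_scaffold(spec$scaffold_size, seed = s_seed)
      smi <- if (positive) {
        plant_alert(scaf, spec$fragment_smiles, seed = s_seed + 7L)
      } else if (!is.null(spec$decoy_fragment)) {
        plant_alert(scaf, spec$decoy_fragment, seed = s_seed + 7L)
      } else {
        scaf
      }
      can <- .canonicalize_quiet(smi)
      if (is.na(can) || can %in% seen) next
      hits <- match_smarts(parse_smiles(can), pat)
      if (positive != (length(hits) > 0L)) next
      seen <<- c(seen, can)
      return(list(canonical = can,
                  planted = if (positive) sort(unique(unlist(hits))) else NULL))
    }
    stop(paste("generation error: could not build a fresh",
               if (positive) "positive" else "negative",
               "molecule; widen scaffold_size"), call. = FALSE)
  }
  n_total <- spec$n_pos + spec$n_neg
  planted <- list()
  rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    positive <- i <= spec$n_pos
    one <- make_one(positive, i)
    if (positive) planted[[one$canonical]] <- one$planted
    rows[[i]] <- tibble::tibble(
      record_id = sprintf("SYN%04d", i),
      name = sprintf("synthetic_%04d", i),
      smiles_raw = one$canonical, smiles_canonical = one$canonical,
      label = if (positive) "positive" else "negative",
      group_id = sprintf("SYN%04d", i)
    )
  }
  out <- dplyr::bind_rows(rows)
  # label noise: flip round(rate * n) labels, chosen deterministically
  n_flip <- round(spec$label_noise_rate * n_total)
  flipped_ids <- character(0)
  if (n_flip > 0L) {
    rng <- .local_rng(.derive_seed(spec$seed, 999983L))
    flip <- rng$sample_int(n_total, n_flip)
    out$label[flip] <- ifelse(out$label[flip] == "positive",
                              "negative", "positive")
    flipped_ids <- out$record_id[flip]
  }
  ds <- new_adr_dataset(out, task_name = "synthetic_planted_alert")
  attr(ds, "truth") <- list(
    planted_atoms = planted, flipped_ids = flipped_ids,
    spec = unclass(spec)
  )
  ds
}

#' Write a synthetic dataset and its ground truth
#'
#' Emits the CSV schema [load_dataset()] reads plus a truth JSON (planted
#' atom indices, flipped labels, spec echo).
#'
#' @param dataset Result of [generate_dataset()].
#' @param csv_path,truth_path Output paths.
#' @return `csv_path`, invisibly.
#' @export
write_synthetic <- function(dataset, csv_path, truth_path = NULL) {
  utils::write.csv(
    dataset[, c("record_id", "name", "smiles_canonical", "label", "group_id")],
    csv_path, row.names = FALSE
  )
  if (!is.null(truth_path)) {
    jsonlite::write_json(attr(dataset, "truth"), truth_path,
                         auto_unbox = TRUE, null = "null")
  }
  invisible(csv_path)
}
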