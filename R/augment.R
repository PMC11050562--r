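# SMILES enumeration data augmentation: many valid renderings of one
# molecule, used to enrich small training sets. Augmentation is applied
# after fold splitting and only to training folds, so a drug never leaks
# across folds and test metrics are computed on one canonical SMILES per
# drug.

#' Enumerate alternative SMILES renderings of a molecule
#'
#' Generates up to `n` distinct valid SMILES for the molecule by writing
#' the parsed graph under random atom-priority orders. Every returned
#' string canonicalizes back to the input. Small or highly symmetric
#' molecules admit fewer distinct renderings than requested.
#'
#' @param smiles_canonical A canonical SMILES string.
#' @param n Maximum number of variants to return (>= 1).
#' @param seed Integer seed; output is deterministic given
#'   `(smiles_canonical, n, seed)`.
#' @param include_canonical Prepend the canonical form itself?
#' @return Character vector of distinct SMILES (length <= `n`).
#' @export
enumerate_smiles <- function(smiles_canonical, n, seed,
                             include_canonical = FALSE) {
  stopifnot(n >= 1L)
  g <- parse_smiles(smiles_canonical)
  n_atoms <- nrow(g$atoms)
  out <- character(0)
  if (include_canonical) out <- smiles_canonical
  rng <- .local_rng(seed)
  max_tries <- 10L * n
  tries <- 0L
  while (length(out) < n + include_canonical && tries < max_tries) {
    tries <- tries + 1L
    pr <- rng$sample_perm(n_atoms)
    s <- write_smiles(g, priority = pr)
    if (!(s %in% out)) out <- c(out, s)
  }
  # round-trip guard: drop anything that fails to canonicalize back
  if (length(out) > 0L) {
    ref <- .canonicalize_quiet(smiles_canonical)
    backs <- .canonicalize_quiet(out)
    ok <- !is.na(backs) & backs == ref
    if (include_canonical) ok[1] <- TRUE
    out <- out[ok]
  }
  utils::head(out, n + as.integer(include_canonical))
}

#' Augment a training split by SMILES enumeration
#'
#' Each record contributes its canonical SMILES plus up to
#' `multiplicity - 1` enumerated variants, all carrying the record's
#' `group_id` and label, so grouped cross-validation keeps all variants of
#' a drug in one fold. Group-level class proportions are unchanged.
#'
#' @param split An `adr_dataset` (or tibble with `smiles_canonical`,
#'   `label`, `group_id`).
#' @param multiplicity Total variants per record including the canonical
#'   form (>= 1; `1` returns the canonical forms only).
#' @param seed Integer seed.
#' @return A tibble with columns `group_id`, `smiles`, `label`,
#'   `is_canonical`.
#' @export
augment_training_split <- function(split, multiplicity = 10L, seed = 1L) {
  stopifnot(multiplicity >= 1L)
  rows <- purrr::pmap(
    list(split$smiles_canonical, split$label, split$group_id,
         seq_len(nrow(split))),
    function(smi, lab, gid, i) {
      vars <- if (multiplicity > 1L) {
        enumerate_smiles(smi, n = multiplicity - 1L,
                         seed = .derive_seed(seed, i))
      } else {
        character(0)
      }
      tibble::tibble(
        group_id = gid, smiles = c(smi, vars), label = lab,
        is_canonical = c(TRUE, rep(FALSE, length(vars)))
      )
    }
  )
  dplyr::bind_rows(rows)
}

# Deterministic derivation of per-record / per-stage seeds from one master
# seed, kept inside 32-bit integer range.
.derive_seed <- function(seed, salt) {
  if (is.character(salt)) {
    salt <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  }
  as.integer((as.double(seed) * 48271 + as.double(salt) * 16807) %% 2147483647)
}

# Small self-contained RNG wrapper that never touches the global
# .Random.seed: callers get reproducibility without clobbering user state.
.local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- NULL
  run <- function(f) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    if (is.null(env$state)) {
      set.seed(seed)
    } else {
      assign(".Random.seed", env$state, envir = globalenv())
    }
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    f()
  }
  list(
    sample_perm = function(n) run(function() sample.int(n)),
    sample_int = function(n, size, replace = FALSE) {
      run(function() sample.int(n, size, replace = replace))
    },
    runif = function(n) run(function() stats::runif(n)),
    rnorm = function(n, mean = 0, sd = 1) {
      run(function() stats::rnorm(n, mean, sd))
    }
  )
}
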