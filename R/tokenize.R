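#' Tokenize a SMILES string
#'
#' Splits a SMILES string into the token sequence a chemical language model
#' consumes, and records which tokens denote atoms. Bracket expressions
#' (`[nH]`, `[N+]`) are single tokens, as are the two-letter organic-subset
#' halogens `Cl` and `Br`; ring-closure digits, bond symbols and branch
#' parentheses are non-atom tokens.
#'
#' @param smiles A single SMILES string (canonical or not).
#' @return A tibble with one row per token and columns
#'   \describe{
#'     \item{token}{the token string}
#'     \item{position}{1-based token position}
#'     \item{is_atom}{whether the token denotes a heavy atom}
#'     \item{atom_index}{1-based index of the atom among atom tokens,
#'       `NA` for non-atom tokens}
#'   }
#'   Concatenating `token` reproduces the input exactly.
#' @examples
#' tokenize_smiles("c1ccc(Cl)cc1")
#' @export
tokenize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  if (nchar(smiles) == 0L) {
    return(tibble::tibble(
      token = character(), position = integer(),
      is_atom = logical(), atom_index = integer()
    ))
  }
  m <- gregexpr(.smiles_token_regex, smiles, perl = TRUE)[[1]]
  toks <- regmatches(smiles, list(m))[[1]]
  if (paste(toks, collapse = "") != smiles) {
    residue <- .token_residue(smiles, m)
    stop(sprintf(
      "tokenization error: unconsumed characters '%s' in SMILES '%s'",
      residue, smiles
    ), call. = FALSE)
  }
  is_atom <- .is_atom_token(toks)
  tibble::tibble(
    token = toks,
    position = seq_along(toks),
    is_atom = is_atom,
    atom_index = ifelse(is_atom, cumsum(is_atom), NA_integer_)
  )
}

# Bracket atoms first, then two-letter halogens, then one-char tokens.
.smiles_token_regex <- paste0(
  "\\[[^\\]]+\\]",           # bracket atom, one token
  "|Br|Cl",                  # two-letter organic-subset elements
  "|%[0-9]{2}",              # two-digit ring closure
  "|[BCNOPSFI]",             # organic subset, aliphatic
  "|[bcnops]",               # organic subset, aromatic
  "|[0-9]",                  # ring closure
  "|[-=#$:/\\\\.()@+*~]"     # bonds, branches, dot, stereo marks
)

.is_atom_token <- function(toks) {
  startsWith(toks, "[") |
    toks %in% c("B", "C", "N", "O", "P", "S", "F", "I", "Cl", "Br",
                "b", "c", "n", "o", "p", "s", "*")
}

.token_residue <- function(smiles, m) {
  covered <- rep(FALSE, nchar(smiles))
  if (m[1] != -1L) {
    for (i in seq_along(m)) {
      covered[seq(m[i], length.out = attr(m, "match.length")[i])] <- TRUE
    }
  }
  chars <- strsplit(smiles, "")[[1]]
  paste(chars[!covered], collapse = "")
}
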