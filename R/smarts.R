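# SMARTS substructure matching over mol_graph objects.
#
# Implements the SMARTS subset needed for structural-alert catalogs:
# element / aromatic primitives, #n, a/A/*, X (connectivity), D (degree),
# H (total hydrogens), R/R0 (ring membership), charges, the logical
# operators ! & , ; and recursive environments $(...). Match results carry
# atom indices, which the count-only Open Babel interface does not expose;
# Open Babel remains the independent cross-check for match presence.

#' Parse a SMARTS pattern
#'
#' @param smarts A SMARTS string (see package docs for the supported subset).
#' @return A `smarts_pattern` object usable with [match_smarts()].
#' @export
parse_smarts <- function(smarts) {
  toks <- .scan_smarts(smarts)
  atoms <- list()
  bonds <- list()
  prev <- NA_integer_
  stack <- integer()
  pending <- NULL
  ring <- list()
  for (t in toks) {
    if (t$kind == "atom") {
      atoms[[length(atoms) + 1L]] <- .parse_smarts_atom(t$text, smarts)
      i <- length(atoms)
      if (!is.na(prev)) {
        bonds[[length(bonds) + 1L]] <-
          list(from = prev, to = i, expr = pending)
      }
      prev <- i
      pending <- NULL
    } else if (t$kind == "ring") {
      key <- t$text
      if (is.null(ring[[key]])) {
        ring[[key]] <- list(atom = prev, expr = pending)
      } else {
        op <- ring[[key]]
        bonds[[length(bonds) + 1L]] <- list(
          from = op$atom, to = prev,
          expr = if (!is.null(pending)) pending else op$expr
        )
        ring[[key]] <- NULL
      }
      pending <- NULL
    } else if (t$kind == "open") {
      stack <- c(stack, prev)
    } else if (t$kind == "close") {
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (t$kind == "bond") {
      pending <- t$text
    }
  }
  if (length(atoms) == 0L) {
    stop(sprintf("SMARTS parse error: no atoms in '%s'", smarts),
         call. = FALSE)
  }
  structure(
    list(atoms = atoms, bonds = bonds, smarts = smarts),
    class = "smarts_pattern"
  )
}

.scan_smarts <- function(s) {
  chars <- strsplit(s, "")[[1]]
  toks <- list()
  i <- 1L
  n <- length(chars)
  push <- function(kind, text) toks[[length(toks) + 1L]] <<-
    list(kind = kind, text = text)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      depth_b <- 1L
      j <- i + 1L
      while (j <= n && depth_b > 0L) {
        if (chars[j] == "[") depth_b <- depth_b + 1L
        if (chars[j] == "]") depth_b <- depth_b - 1L
        j <- j + 1L
      }
      if (depth_b != 0L) {
        stop(sprintf("SMARTS parse error: unbalanced '[' in '%s'", s),
             call. = FALSE)
      }
      push("atom", paste(chars[i:(j - 1L)], collapse = ""))
      i <- j
    } else if (ch == "C" && i < n && chars[i + 1L] == "l") {
      push("atom", "Cl"); i <- i + 2L
    } else if (ch == "B" && i < n && chars[i + 1L] == "r") {
      push("atom", "Br"); i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I",
                         "b", "c", "n", "o", "p", "s", "a", "A", "*")) {
      push("atom", ch); i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      push("ring", ch); i <- i + 1L
    } else if (ch == "%") {
      push("ring", paste(chars[i:(i + 2L)], collapse = "")); i <- i + 3L
    } else if (ch == "(") {
      push("open", "("); i <- i + 1L
    } else if (ch == ")") {
      push("close", ")"); i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "~", "@")) {
      push("bond", ch); i <- i + 1L
    } else {
      stop(sprintf("SMARTS parse error: unsupported character '%s' in '%s'",
                   ch, s), call. = FALSE)
    }
  }
  toks
}

# Atom expression -> predicate AST. Grammar (decreasing precedence):
#   primary := '!' primary | '$(' smarts ')' | primitive
#   and_hi  := primary { '&'? primary }      (juxtaposition = high-AND)
#   or_e    := and_hi { ',' and_hi }
#   expr    := or_e { ';' or_e }
.parse_smarts_atom <- function(text, pattern) {
  bare <- !startsWith(text, "[")
  body <- if (bare) text else substr(text, 2L, nchar(text) - 1L)
  pos <- 1L
  n <- nchar(body)
  peek <- function() if (pos <= n) substr(body, pos, pos) else ""
  take <- function(k = 1L) {
    out <- substr(body, pos, pos + k - 1L)
    pos <<- pos + k
    out
  }
  take_num <- function() {
    start <- pos
    while (pos <= n && grepl("[0-9]", substr(body, pos, pos))) pos <<- pos + 1L
    if (pos == start) NA_integer_ else as.integer(substr(body, start, pos - 1L))
  }
  parse_primary <- function() {
    ch <- peek()
    if (ch == "!") {
      take()
      node <- parse_primary()
      return(list(op = "not", x = node))
    }
    if (ch == "$") {
      take()
      if (take() != "(") {
        stop(sprintf("SMARTS parse error in '%s': expected '(' after '$'",
                     pattern), call. = FALSE)
      }
      depth <- 1L
      start <- pos
      while (pos <= n && depth > 0L) {
        c2 <- substr(body, pos, pos)
        if (c2 == "(") depth <- depth + 1L
        if (c2 == ")") depth <- depth - 1L
        pos <<- pos + 1L
      }
      inner <- substr(body, start, pos - 2L)
      return(list(op = "recursive", pattern = parse_smarts(inner)))
    }
    # two-letter elements first
    two <- if (pos + 1L <= n) substr(body, pos, pos + 1L) else ""
    if (two %in% c("Cl", "Br", "Na", "Si", "Se", "Li", "Mg", "Ca", "Zn")) {
      take(2L)
      return(list(op = "elem", element = two, aromatic = FALSE))
    }
    if (two %in% c("se", "si")) {
      take(2L)
      return(list(op = "elem",
                  element = paste0(toupper(substr(two, 1, 1)),
                                   substr(two, 2, 2)),
                  aromatic = TRUE))
    }
    if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      take()
      return(list(op = "elem", element = ch, aromatic = FALSE))
    }
    if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      take()
      return(list(op = "elem", element = toupper(ch), aromatic = TRUE))
    }
    if (ch == "#") {
      take()
      z <- take_num()
      return(list(op = "anum", z = z))
    }
    if (ch == "a") { take(); return(list(op = "arom", value = TRUE)) }
    if (ch == "A") { take(); return(list(op = "arom", value = FALSE)) }
    if (ch == "*") { take(); return(list(op = "any")) }
    if (ch == "X") {
      take(); k <- take_num()
      return(list(op = "conn", k = if (is.na(k)) 1L else k))
    }
    if (ch == "D") {
      take(); k <- take_num()
      return(list(op = "deg", k = if (is.na(k)) 1L else k))
    }
    if (ch == "H") {
      take(); k <- take_num()
      return(list(op = "hcount", k = if (is.na(k)) 1L else k))
    }
    if (ch == "R") {
      take(); k <- take_num()
      return(list(op = "ring", k = k))   # NA => any ring; 0 => acyclic
    }
    if (ch == "+" || ch == "-") {
      sgn <- if (ch == "+") 1L else -1L
      take()
      reps <- 1L
      while (peek() == ch) { take(); reps <- reps + 1L }
      k <- take_num()
      chg <- if (!is.na(k)) sgn * k else sgn * reps
      return(list(op = "charge", k = chg))
    }
    stop(sprintf("SMARTS parse error: unsupported primitive at '%s' in '%s'",
                 substr(body, pos, n), pattern), call. = FALSE)
  }
  parse_and_hi <- function() {
    nodes <- list(parse_primary())
    repeat {
      ch <- peek()
      if (ch == "&") { take(); nodes[[length(nodes) + 1L]] <- parse_primary() }
      else if (ch != "" && !(ch %in% c(",", ";"))) {
        nodes[[length(nodes) + 1L]] <- parse_primary()
      } else break
    }
    if (length(nodes) == 1L) nodes[[1L]] else list(op = "and", xs = nodes)
  }
  parse_or <- function() {
    nodes <- list(parse_and_hi())
    while (peek() == ",") { take(); nodes[[length(nodes) + 1L]] <- parse_and_hi() }
    if (length(nodes) == 1L) nodes[[1L]] else list(op = "or", xs = nodes)
  }
  parse_expr <- function() {
    nodes <- list(parse_or())
    while (peek() == ";") { take(); nodes[[length(nodes) + 1L]] <- parse_or() }
    if (length(nodes) == 1L) nodes[[1L]] else list(op = "and", xs = nodes)
  }
  out <- parse_expr()
  if (pos <= n) {
    stop(sprintf("SMARTS parse error: trailing '%s' in atom expression '%s'",
                 substr(body, pos, n), text), call. = FALSE)
  }
  out
}

.atomic_numbers <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12, Si = 14,
  P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Zn = 30, Se = 34, Br = 35, I = 53
)

# Precomputed per-molecule context used by atom predicates.
.smarts_context <- function(g) {
  n <- nrow(g$atoms)
  deg <- integer(n)
  if (nrow(g$bonds) > 0L) {
    tab <- table(factor(c(g$bonds$from, g$bonds$to), levels = seq_len(n)))
    deg <- as.integer(tab)
  }
  ring_bond <- .ring_bonds(g)
  ring_atom <- rep(FALSE, n)
  if (any(ring_bond)) {
    rb <- which(ring_bond)
    ring_atom[unique(c(g$bonds$from[rb], g$bonds$to[rb]))] <- TRUE
  }
  list(degree = deg, conn = deg + g$atoms$h_count, ring_atom = ring_atom,
       ring_bond = ring_bond)
}

# A bond is in a ring iff its endpoints stay connected after removing it.
.ring_bonds <- function(g) {
  nb <- nrow(g$bonds)
  if (nb == 0L) return(logical(0))
  adj <- .adjacency(g)
  vapply(seq_len(nb), function(bi) {
    src <- g$bonds$from[bi]; dst <- g$bonds$to[bi]
    seen <- rep(FALSE, nrow(g$atoms))
    seen[src] <- TRUE
    queue <- src
    while (length(queue) > 0L) {
      a <- queue[1]; queue <- queue[-1]
      sel <- adj[[a]]$bond != bi
      for (b in adj[[a]]$nbr[sel]) {
        if (!seen[b]) {
          if (b == dst) return(TRUE)
          seen[b] <- TRUE
          queue <- c(queue, b)
        }
      }
    }
    FALSE
  }, logical(1))
}

.eval_atom_pred <- function(node, g, ctx, i) {
  a <- g$atoms
  switch(node$op,
    any = TRUE,
    elem = a$element[i] == node$element && a$aromatic[i] == node$aromatic,
    anum = {
      z <- .atomic_numbers[a$element[i]]
      !is.na(z) && z == node$z
    },
    arom = a$aromatic[i] == node$value,
    conn = ctx$conn[i] == node$k,
    deg = ctx$degree[i] == node$k,
    hcount = a$h_count[i] == node$k,
    ring = if (is.na(node$k)) ctx$ring_atom[i] else if (node$k == 0L)
      !ctx$ring_atom[i] else ctx$ring_atom[i],
    charge = a$charge[i] == node$k,
    not = !.eval_atom_pred(node$x, g, ctx, i),
    and = all(vapply(node$xs, .eval_atom_pred, logical(1),
                     g = g, ctx = ctx, i = i)),
    or = any(vapply(node$xs, .eval_atom_pred, logical(1),
                    g = g, ctx = ctx, i = i)),
    recursive = length(.match_engine(g, node$pattern, ctx,
                                     anchor = i, first_only = TRUE)) > 0L,
    stop(sprintf("unknown SMARTS predicate op '%s'", node$op))
  )
}

.eval_bond_pred <- function(expr, g, ctx, bi) {
  b_arom <- g$bonds$aromatic[bi]
  o <- g$bonds$order[bi]
  if (is.null(expr)) return(b_arom || o == 1L)   # single-or-aromatic default
  switch(expr,
    "-" = !b_arom && o == 1L,
    "=" = !b_arom && o == 2L,
    "#" = !b_arom && o == 3L,
    ":" = b_arom,
    "~" = TRUE,
    "@" = ctx$ring_bond[bi],
    stop(sprintf("unsupported SMARTS bond '%s'", expr))
  )
}

#' Match a SMARTS pattern against a molecule
#'
#' @param g A `mol_graph` (from [parse_smiles()]) or a SMILES string.
#' @param pattern A `smarts_pattern` (from [parse_smarts()]) or a SMARTS
#'   string.
#' @param unique_sets If `TRUE` (default) matches differing only in atom
#'   order/automorphism are collapsed to unique atom sets.
#' @return A list of integer vectors of matched molecule atom indices (in
#'   pattern-atom order for `unique_sets = FALSE`); empty list if no match.
#' @examples
#' match_smarts("CCCC(CCC)C(=O)O", "[CX3](=[OX1])[OX2H1]")
#' @export
match_smarts <- function(g, pattern, unique_sets = TRUE) {
  if (is.character(g)) g <- parse_smiles(g)
  if (is.character(pattern)) pattern <- parse_smarts(pattern)
  ctx <- .smarts_context(g)
  hits <- .match_engine(g, pattern, ctx)
  if (unique_sets && length(hits) > 0L) {
    keys <- vapply(hits, function(h) paste(sort(h), collapse = ","),
                   character(1))
    hits <- hits[!duplicated(keys)]
  }
  hits
}

# Backtracking subgraph matcher. Pattern atoms are matched in an order that
# keeps each new atom adjacent to an already-matched one (pattern assumed
# connected). `anchor` pins pattern atom 1 to a molecule atom (recursive
# SMARTS); `first_only` short-circuits at the first embedding.
.match_engine <- function(g, pattern, ctx, anchor = NULL,
                          first_only = FALSE) {
  np <- length(pattern$atoms)
  nm <- nrow(g$atoms)
  # pattern adjacency
  padj <- replicate(np, list(nbr = integer(), bond = integer()),
                    simplify = FALSE)
  for (bi in seq_along(pattern$bonds)) {
    b <- pattern$bonds[[bi]]
    padj[[b$from]]$nbr <- c(padj[[b$from]]$nbr, b$to)
    padj[[b$from]]$bond <- c(padj[[b$from]]$bond, bi)
    padj[[b$to]]$nbr <- c(padj[[b$to]]$nbr, b$from)
    padj[[b$to]]$bond <- c(padj[[b$to]]$bond, bi)
  }
  # order: BFS from atom 1
  ord <- integer(0)
  seen <- rep(FALSE, np)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0L) {
    a <- queue[1]; queue <- queue[-1]
    ord <- c(ord, a)
    for (b in padj[[a]]$nbr) {
      if (!seen[b]) { seen[b] <- TRUE; queue <- c(queue, b) }
    }
  }
  if (!all(seen)) {
    stop(sprintf("disconnected SMARTS pattern unsupported: '%s'",
                 pattern$smarts), call. = FALSE)
  }
  madj <- .adjacency(g)
  mol_bond_idx <- function(u, v) {
    k <- which(madj[[u]]$nbr == v)
    if (length(k) == 0L) NA_integer_ else madj[[u]]$bond[k[1]]
  }
  results <- list()
  assign_map <- rep(NA_integer_, np)
  used <- rep(FALSE, nm)
  ok_atom <- function(p, m) .eval_atom_pred(pattern$atoms[[p]], g, ctx, m)
  extend <- function(step) {
    if (step > np) {
      results[[length(results) + 1L]] <<- assign_map
      return(first_only)
    }
    p <- ord[step]
    # candidates: adjacent to some mapped pattern neighbor, or all atoms
    mapped_nbrs <- padj[[p]]$nbr[!is.na(assign_map[padj[[p]]$nbr])]
    cands <- if (length(mapped_nbrs) > 0L) {
      madj[[assign_map[mapped_nbrs[1]]]]$nbr
    } else if (!is.null(anchor) && step == 1L) {
      anchor
    } else {
      seq_len(nm)
    }
    if (!is.null(anchor) && p == 1L) cands <- intersect(cands, anchor)
    for (m in cands) {
      if (used[m] || !ok_atom(p, m)) next
      ok <- TRUE
      for (k in seq_along(padj[[p]]$nbr)) {
        q <- padj[[p]]$nbr[k]
        if (!is.na(assign_map[q])) {
          mb <- mol_bond_idx(m, assign_map[q])
          if (is.na(mb) ||
              !.eval_bond_pred(pattern$bonds[[padj[[p]]$bond[k]]]$expr,
                               g, ctx, mb)) {
            ok <- FALSE
            break
          }
        }
      }
      if (!ok) next
      assign_map[p] <<- m
      used[m] <<- TRUE
      done <- extend(step + 1L)
      assign_map[p] <<- NA_integer_
      used[m] <<- FALSE
      if (done) return(TRUE)
    }
    FALSE
  }
  extend(1L)
  results
}
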