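# Lightweight molecular graph built from a SMILES string.
#
# The pipeline canonicalizes every SMILES through Open Babel before graph
# work, so the parser only needs to be faithful on well-formed SMILES; it is
# still defensive about ring-closure and bracket syntax. Aromaticity is read
# from the string (lowercase atoms / ':' bonds), never re-perceived, and
# stereo marks are ignored at the graph level.

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles A single valid SMILES string.
#' @return An object of class `mol_graph`: a list with
#'   `atoms` (tibble: `idx`, `element`, `aromatic`, `charge`, `h_count`,
#'   `bracket`, `token_position`) and `bonds` (tibble: `from`, `to`,
#'   `order`, `aromatic`). `h_count` is the implicit/explicit hydrogen
#'   count; `order` is 1/2/3 with `aromatic = TRUE` marking aromatic bonds.
#' @export
parse_smiles <- function(smiles) {
  tok <- tokenize_smiles(smiles)
  atoms <- list()
  bonds <- list()
  prev <- NA_integer_          # atom open for the next bond
  stack <- integer()           # branch stack
  pending_bond <- NULL         # explicit bond symbol awaiting next atom
  ring <- list()               # closure digit -> list(atom, bond)
  n_atom <- 0L

  add_bond <- function(a, b, sym, both_aromatic) {
    if (is.null(sym)) {
      list(order = 1L, aromatic = both_aromatic)
    } else {
      switch(sym,
        "-" = , "/" = , "\\" = list(order = 1L, aromatic = FALSE),
        "=" = list(order = 2L, aromatic = FALSE),
        "#" = list(order = 3L, aromatic = FALSE),
        ":" = list(order = 1L, aromatic = TRUE),
        stop(sprintf("unsupported bond symbol '%s'", sym), call. = FALSE)
      )
    }
  }

  for (i in seq_len(nrow(tok))) {
    t <- tok$token[i]
    if (tok$is_atom[i]) {
      n_atom <- n_atom + 1L
      atoms[[n_atom]] <- c(.parse_atom_token(t), list(token_position = i))
      if (!is.na(prev)) {
        both_ar <- atoms[[prev]]$aromatic && atoms[[n_atom]]$aromatic
        b <- add_bond(prev, n_atom, pending_bond, both_ar)
        bonds[[length(bonds) + 1L]] <-
          list(from = prev, to = n_atom, order = b$order, aromatic = b$aromatic)
      }
      prev <- n_atom
      pending_bond <- NULL
    } else if (grepl("^%?[0-9]", t)) {
      key <- sub("^%", "", t)
      if (is.null(ring[[key]])) {
        ring[[key]] <- list(atom = prev, bond = pending_bond)
      } else {
        opener <- ring[[key]]
        sym <- if (!is.null(pending_bond)) pending_bond else opener$bond
        both_ar <- atoms[[opener$atom]]$aromatic && atoms[[prev]]$aromatic
        b <- add_bond(opener$atom, prev, sym, both_ar)
        bonds[[length(bonds) + 1L]] <-
          list(from = opener$atom, to = prev, order = b$order,
               aromatic = b$aromatic)
        ring[[key]] <- NULL
      }
      pending_bond <- NULL
    } else if (t == "(") {
      stack <- c(stack, prev)
    } else if (t == ")") {
      if (length(stack) == 0L) {
        stop("SMILES parse error: unbalanced ')'", call. = FALSE)
      }
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (t %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_bond <- t
    } else if (t == ".") {
      prev <- NA_integer_
      pending_bond <- NULL
    } else if (t %in% c("@", "+", "~", "*", "$")) {
      stop(sprintf("SMILES parse error: unexpected token '%s'", t),
           call. = FALSE)
    }
  }
  open_rings <- names(ring)[!vapply(ring, is.null, logical(1))]
  if (length(open_rings) > 0L) {
    stop(sprintf("SMILES parse error: %d unmatched ring bond(s) in '%s'",
                 length(open_rings), smiles), call. = FALSE)
  }
  if (n_atom == 0L) {
    stop("SMILES parse error: no atoms", call. = FALSE)
  }

  atoms_df <- tibble::tibble(
    idx = seq_len(n_atom),
    element = vapply(atoms, function(a) a$element, character(1)),
    aromatic = vapply(atoms, function(a) a$aromatic, logical(1)),
    charge = vapply(atoms, function(a) a$charge, integer(1)),
    h_explicit = vapply(atoms, function(a) a$h_explicit, integer(1)),
    bracket = vapply(atoms, function(a) a$bracket, logical(1)),
    token_position = vapply(atoms, function(a) a$token_position, integer(1))
  )
  bonds_df <- if (length(bonds) > 0L) {
    tibble::tibble(
      from = vapply(bonds, `[[`, integer(1), "from"),
      to = vapply(bonds, `[[`, integer(1), "to"),
      order = vapply(bonds, `[[`, integer(1), "order"),
      aromatic = vapply(bonds, `[[`, logical(1), "aromatic")
    )
  } else {
    tibble::tibble(from = integer(), to = integer(),
                   order = integer(), aromatic = logical())
  }
  atoms_df$h_count <- .implicit_h(atoms_df, bonds_df)
  g <- list(atoms = atoms_df, bonds = bonds_df, smiles = smiles)
  class(g) <- "mol_graph"
  g
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %d atoms, %d bonds: %s\n",
              nrow(x$atoms), nrow(x$bonds), x$smiles))
  invisible(x)
}

.parse_atom_token <- function(t) {
  if (!startsWith(t, "[")) {
    aromatic <- t %in% c("b", "c", "n", "o", "p", "s")
    list(element = if (aromatic) toupper(t) else t, aromatic = aromatic,
         charge = 0L, h_explicit = NA_integer_, bracket = FALSE)
  } else {
    m <- regmatches(t, regexec(
      "^\\[([0-9]*)(\\*|[A-Z][a-z]?|[a-z]{1,2})(@{0,2}H?)?(H([0-9]*))?((?:\\+{1,3}|-{1,3}|[+-][0-9]+))?\\]$",
      t
    ))[[1]]
    if (length(m) == 0L) {
      stop(sprintf("cannot parse bracket atom '%s'", t), call. = FALSE)
    }
    elem <- m[3]
    aromatic <- elem == tolower(elem) && elem != "*"
    stereo_h <- grepl("H$", m[4])            # e.g. [C@@H]
    h <- if (m[5] != "") {
      if (m[6] == "") 1L else as.integer(m[6])
    } else if (stereo_h) 1L else 0L
    chg <- if (is.na(m[7]) || m[7] == "") {
      0L
    } else if (grepl("^[+-][0-9]+$", m[7])) {
      as.integer(m[7])
    } else {
      sgn <- if (startsWith(m[7], "+")) 1L else -1L
      sgn * nchar(m[7])
    }
    list(
      element = if (elem == "*") "*" else
        paste0(toupper(substr(elem, 1, 1)), substring(elem, 2)),
      aromatic = aromatic, charge = chg, h_explicit = h, bracket = TRUE
    )
  }
}

# Implicit hydrogens for organic-subset atoms; bracket atoms carry explicit H.
# Aromatic carbon gets 3 - degree; other aromatic atoms written without
# brackets carry no hydrogen (pyrrole-type N must be written [nH]).
.implicit_h <- function(atoms, bonds) {
  deg <- integer(nrow(atoms))
  bsum <- numeric(nrow(atoms))
  if (nrow(bonds) > 0L) {
    for (i in seq_len(nrow(bonds))) {
      deg[bonds$from[i]] <- deg[bonds$from[i]] + 1L
      deg[bonds$to[i]] <- deg[bonds$to[i]] + 1L
      o <- bonds$order[i]
      bsum[bonds$from[i]] <- bsum[bonds$from[i]] + o
      bsum[bonds$to[i]] <- bsum[bonds$to[i]] + o
    }
  }
  valences <- list(
    B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
    S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L
  )
  h <- integer(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    if (atoms$bracket[i]) {
      h[i] <- atoms$h_explicit[i]
    } else if (atoms$aromatic[i]) {
      h[i] <- if (atoms$element[i] == "C") max(0L, 3L - deg[i]) else 0L
    } else {
      v <- valences[[atoms$element[i]]]
      if (is.null(v)) {
        h[i] <- 0L
      } else {
        fit <- v[v >= bsum[i]]
        h[i] <- if (length(fit) == 0L) 0L else as.integer(fit[1] - bsum[i])
      }
    }
  }
  h
}

#' Heavy-atom count of a SMILES
#'
#' @param smiles A single SMILES string.
#' @return Integer number of heavy (non-hydrogen) atoms.
#' @export
heavy_atom_count <- function(smiles) {
  sum(tokenize_smiles(smiles)$is_atom)
}

# Connected components of a mol_graph (1-based component ids).
.mol_components <- function(g) {
  n <- nrow(g$atoms)
  comp <- integer(n)
  cur <- 0L
  adj <- .adjacency(g)
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {
      cur <- cur + 1L
      queue <- s
      comp[s] <- cur
      while (length(queue) > 0L) {
        a <- queue[1]; queue <- queue[-1]
        for (b in adj[[a]]$nbr) {
          if (comp[b] == 0L) {
            comp[b] <- cur
            queue <- c(queue, b)
          }
        }
      }
    }
  }
  comp
}

# adjacency list: for each atom, tibble of (nbr, bond row index)
.adjacency <- function(g) {
  n <- nrow(g$atoms)
  adj <- replicate(n, list(nbr = integer(), bond = integer()),
                   simplify = FALSE)
  if (nrow(g$bonds) > 0L) {
    for (i in seq_len(nrow(g$bonds))) {
      f <- g$bonds$from[i]; t <- g$bonds$to[i]
      adj[[f]]$nbr <- c(adj[[f]]$nbr, t)
      adj[[f]]$bond <- c(adj[[f]]$bond, i)
      adj[[t]]$nbr <- c(adj[[t]]$nbr, f)
      adj[[t]]$bond <- c(adj[[t]]$bond, i)
    }
  }
  adj
}

#' Write a SMILES string from a molecular graph
#'
#' Produces a valid (generally non-canonical) SMILES by depth-first
#' traversal. The atom priority order controls which of the many valid
#' renderings is produced; permuting it is the basis of SMILES enumeration.
#'
#' @param g A `mol_graph`.
#' @param priority Optional integer vector: traversal priority per atom
#'   (lower value visited first). Defaults to input order.
#' @return A SMILES string that parses back to the same molecular graph,
#'   with attribute `atom_order`: the original atom index written at each
#'   output atom position (the correspondence needed to map per-atom
#'   scores between renderings).
#' @export
write_smiles <- function(g, priority = NULL) {
  n <- nrow(g$atoms)
  if (is.null(priority)) priority <- seq_len(n)
  stopifnot(length(priority) == n)
  adj <- .adjacency(g)

  bond_sym <- function(bi) {
    if (g$bonds$aromatic[bi]) return("")
    o <- g$bonds$order[bi]
    if (o == 2L) return("=")
    if (o == 3L) return("#")
    f <- g$bonds$from[bi]; t <- g$bonds$to[bi]
    # explicit single between two aromatic atoms, else default
    if (g$atoms$aromatic[f] && g$atoms$aromatic[t]) "-" else ""
  }

  atom_token <- function(i) {
    a <- g$atoms[i, ]
    sym <- if (a$aromatic) tolower(a$element) else a$element
    if (!a$bracket) return(sym)
    h <- a$h_explicit
    hs <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    cs <- if (a$charge == 0L) "" else if (a$charge == 1L) "+" else
      if (a$charge == -1L) "-" else sprintf("%+d", a$charge)
    paste0("[", sym, hs, cs, "]")
  }

  # Pass 1: DFS in priority order; classify edges as tree or ring-closure
  # (back) edges, and record children per atom in traversal order.
  visited <- rep(FALSE, n)
  bond_used <- rep(FALSE, nrow(g$bonds))
  children <- replicate(n, list(), simplify = FALSE)
  back_edges <- list()
  classify <- function(i) {
    visited[i] <<- TRUE
    nbrs <- adj[[i]]$nbr
    bnds <- adj[[i]]$bond
    ord <- order(priority[nbrs])
    nbrs <- nbrs[ord]; bnds <- bnds[ord]
    for (k in seq_along(nbrs)) {
      if (bond_used[bnds[k]]) next
      if (visited[nbrs[k]]) {
        bond_used[bnds[k]] <<- TRUE
        back_edges[[length(back_edges) + 1L]] <<-
          list(a = nbrs[k], b = i, bond = bnds[k])
      } else {
        bond_used[bnds[k]] <<- TRUE
        children[[i]] <<- c(children[[i]], list(list(child = nbrs[k],
                                                     bond = bnds[k])))
        classify(nbrs[k])
      }
    }
  }

  roots <- integer(0)
  comp <- .mol_components(g)
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    start <- members[which.min(priority[members])]
    roots <- c(roots, start)
    classify(start)
  }

  # Assign one digit per ring-closure edge, written (with its bond symbol)
  # immediately after the atom token at both endpoints.
  digit_pool <- c(as.character(1:9), paste0("%", 10:99))
  if (length(back_edges) > length(digit_pool)) {
    stop("too many ring closures for SMILES digit pool", call. = FALSE)
  }
  closure_at <- replicate(n, character(0), simplify = FALSE)
  for (e_i in seq_along(back_edges)) {
    e <- back_edges[[e_i]]
    chunk <- paste0(bond_sym(e$bond), digit_pool[e_i])
    closure_at[[e$a]] <- c(closure_at[[e$a]], chunk)
    closure_at[[e$b]] <- c(closure_at[[e$b]], chunk)
  }

  # Pass 2: emit following the recorded tree.
  atom_order <- integer(0)
  emit <- function(i, from_bond) {
    atom_order <<- c(atom_order, i)
    piece <- if (is.na(from_bond)) "" else bond_sym(from_bond)
    piece <- paste0(piece, atom_token(i),
                    paste(closure_at[[i]], collapse = ""))
    kids <- children[[i]]
    if (length(kids) > 0L) {
      for (k in seq_along(kids)) {
        sub <- emit(kids[[k]]$child, kids[[k]]$bond)
        piece <- if (k < length(kids)) {
          paste0(piece, "(", sub, ")")
        } else {
          paste0(piece, sub)
        }
      }
    }
    piece
  }

  out <- paste(vapply(roots, emit, character(1), from_bond = NA_integer_),
               collapse = ".")
  attr(out, "atom_order") <- atom_order
  out
}
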