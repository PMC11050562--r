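# 2D depiction of alert reports as SVG. Coordinates come from Open
# Babel's 2D layout (deterministic for a given molecule); drawing is plain
# SVG text: bonds as lines, heteroatoms as labels, selected atoms circled,
# matched alerts listed beneath.

# molecule -> 2D coordinates + bonds via an Open Babel MOL block
.mol_2d <- function(smiles) {
  mol <- ChemmineOB::convertFormat(
    "SMI", "MOL", smiles,
    options = data.frame(names = "gen2D", args = "")
  )
  lines <- strsplit(mol, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  atoms <- do.call(rbind, lapply(lines[5:(4 + n_atoms)], function(l) {
    data.frame(x = as.numeric(substr(l, 1, 10)),
               y = as.numeric(substr(l, 11, 20)),
               element = trimws(substr(l, 32, 34)))
  }))
  bonds <- if (n_bonds > 0L) {
    do.call(rbind, lapply(lines[(5 + n_atoms):(4 + n_atoms + n_bonds)],
                          function(l) {
      data.frame(from = as.integer(substr(l, 1, 3)),
                 to = as.integer(substr(l, 4, 6)),
                 order = as.integer(substr(l, 7, 9)))
    }))
  } else {
    data.frame(from = integer(), to = integer(), order = integer())
  }
  list(atoms = atoms, bonds = bonds)
}

#' Render an alert report as an annotated SVG depiction
#'
#' Draws the molecule in 2D with the selected (attended) atoms highlighted
#' and the matched catalog alerts listed. If depiction fails the error is
#' logged and `NA` is returned; the report itself is unaffected.
#'
#' @param report An `alert_report` from [attribute_molecule()].
#' @param path Output SVG path.
#' @param width,height Canvas size in pixels.
#' @return `path` invisibly, or `NA` if depiction failed.
#' @export
render_annotation <- function(report, path, width = 420, height = 420) {
  stopifnot(inherits(report, "alert_report"))
  ok <- tryCatch({
    geom <- .mol_2d(report$smiles)
    # Open Babel's MOL block preserves input atom order, so graph atom
    # indices address geometry rows directly
    a <- geom$atoms
    pad <- 40
    xr <- range(a$x); yr <- range(a$y)
    sc <- min((width - 2 * pad) / max(diff(xr), 1e-6),
              (height - 120 - 2 * pad) / max(diff(yr), 1e-6))
    px <- pad + (a$x - xr[1]) * sc
    py <- pad + (yr[2] - a$y) * sc
    esc <- function(s) gsub("&", "&amp;", gsub("<", "&lt;", s))
    svg <- c(sprintf(
      '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
      width, height),
      sprintf('<rect width="%d" height="%d" fill="white"/>', width, height))
    for (i in seq_len(nrow(geom$bonds))) {
      b <- geom$bonds[i, ]
      w <- if (b$order >= 2L) 3 else 1.5
      svg <- c(svg, sprintf(
        '<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="black" stroke-width="%.1f"/>',
        px[b$from], py[b$from], px[b$to], py[b$to], w))
    }
    for (i in report$selected_atoms) {
      if (i <= length(px)) {
        svg <- c(svg, sprintf(
          '<circle cx="%.1f" cy="%.1f" r="11" fill="none" stroke="crimson" stroke-width="2"/>',
          px[i], py[i]))
      }
    }
    for (i in seq_len(nrow(a))) {
      if (a$element[i] != "C") {
        svg <- c(svg, sprintf(
          '<circle cx="%.1f" cy="%.1f" r="8" fill="white"/>', px[i], py[i]),
          sprintf(
          '<text x="%.1f" y="%.1f" font-size="12" text-anchor="middle" dy="4">%s</text>',
          px[i], py[i], esc(a$element[i])))
      }
    }
    yline <- height - 100
    svg <- c(svg, sprintf(
      '<text x="%d" y="%d" font-size="11" font-family="monospace">%s</text>',
      10, yline, esc(substr(report$smiles, 1, 60))))
    shown <- utils::head(unique(report$matches$alert_name), 6)
    for (j in seq_along(shown)) {
      svg <- c(svg, sprintf(
        '<text x="%d" y="%d" font-size="11">%s</text>',
        10, yline + 14 * j, esc(shown[j])))
    }
    svg <- c(svg, "</svg>")
    writeLines(svg, path)
    TRUE
  }, error = function(e) {
    message(sprintf("depiction failed for %s: %s", report$smiles,
                    conditionMessage(e)))
    FALSE
  })
  if (ok) invisible(path) else NA
}
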