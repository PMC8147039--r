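#' @title Molecular graph model
#' @description Heavy-atom molecular graphs: construction, Molfile V2000 I/O,
#' reconstruction from parsed identifiers, Hill formulas, permutations, and
#' the seeded fixture generator used by the audit harness. Atom indices are
#' 1-based everywhere, matching both the Molfile and identifier conventions.
#' @name molgraph
NULL

#' Construct a molecular graph
#'
#' @param elements character vector of element symbols (periodic table plus
#'   `"Zz"`).
#' @param bonds two-column integer matrix (or data frame with columns `i`,
#'   `j`) of bonded atom pairs; bond direction is kept as given (the first
#'   atom is the wedge origin for wedged bonds).
#' @param charge integer formal charges (recycled scalar 0).
#' @param hcount integer attached-hydrogen counts; `NA` requests filling from
#'   the valence model.
#' @param order bond orders (1, 2, 3, or 4 for aromatic), default 1.
#' @param wedge per-bond wedge flag: `"none"`, `"up"` or `"down"`.
#' @param coords optional two-column matrix of 2D depiction coordinates.
#' @param parity optional per-atom tetrahedral parity (`"+"`, `"-"`, `"?"`,
#'   or `NA` for non-stereocentres), relative to the atom's neighbors in
#'   ascending index order with an implicit hydrogen in the last slot.
#' @return a `mol_graph` object.
#' @export
mol_graph <- function(elements, bonds = NULL, charge = 0L, hcount = NA_integer_,
                      order = 1L, wedge = "none", coords = NULL, parity = NA_character_) {
  n <- length(elements)
  if (n < 1L) argument_error("atoms", "a molecule needs at least one atom")
  bad <- !is_known_symbol(elements)
  if (any(bad)) argument_error("element", paste("unknown element:", elements[bad][1]))
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0),
                        wedge = character(0), stringsAsFactors = FALSE)
  } else {
    bonds <- as.data.frame(bonds)
    if (ncol(bonds) < 2L) argument_error("bonds", "bonds need two index columns")
    names(bonds)[1:2] <- c("i", "j")
    bonds$order <- if ("order" %in% names(bonds)) as.integer(bonds$order) else rep(as.integer(order), nrow(bonds))
    bonds$wedge <- if ("wedge" %in% names(bonds)) as.character(bonds$wedge) else rep(wedge, length.out = nrow(bonds))
    bonds <- bonds[, c("i", "j", "order", "wedge")]
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))
      argument_error("bonds", "bond index out of range")
    if (any(bonds$i == bonds$j)) argument_error("bonds", "self-loop bond")
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) argument_error("bonds", "duplicate bond")
    if (!all(bonds$order %in% c(1L, 2L, 3L, 4L)))
      argument_error("bonds", "bond order must be 1, 2, 3 or 4 (aromatic)")
    if (!all(bonds$wedge %in% c("none", "up", "down")))
      argument_error("bonds", "wedge must be 'none', 'up' or 'down'")
  }
  atoms <- data.frame(element = as.character(elements),
                      charge = rep_len(as.integer(charge), n),
                      hcount = rep_len(as.integer(hcount), n),
                      x = NA_real_, y = NA_real_,
                      parity = rep_len(as.character(parity), n),
                      stringsAsFactors = FALSE)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    atoms$x <- as.numeric(coords[, 1]); atoms$y <- as.numeric(coords[, 2])
  }
  g <- structure(list(atoms = atoms, bonds = bonds, mobile_groups = list(),
                      extra_charge = 0L),
                 class = "mol_graph")
  if (anyNA(atoms$hcount)) g <- implicit_h_fill(g)
  g
}

#' Number of atoms in a graph
#' @param g a `mol_graph`.
#' @return integer atom count.
#' @export
n_atoms <- function(g) nrow(g$atoms)

#' Net formal charge of a graph
#' @param g a `mol_graph`.
#' @return integer: the sum of formal charges (plus any delocalized charge
#'   carried over from an identifier's `/q` layer, which does not localize
#'   charge on atoms).
#' @export
net_charge <- function(g) sum(g$atoms$charge) + g$extra_charge

# neighbor lists, sorted ascending; bond orders ignored
adjacency_list <- function(g) {
  n <- n_atoms(g)
  adj <- vector("list", n)
  for (r in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[r]; j <- g$bonds$j[r]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, function(v) if (is.null(v)) integer(0) else sort(v))
}

graph_degrees <- function(g) {
  d <- integer(n_atoms(g))
  tab <- table(c(g$bonds$i, g$bonds$j))
  d[as.integer(names(tab))] <- as.integer(tab)
  d
}

is_connected <- function(g) {
  n <- n_atoms(g)
  if (n == 1L) return(TRUE)
  adj <- adjacency_list(g)
  seen <- logical(n); seen[1] <- TRUE
  queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[v]][!seen[adj[[v]]]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# Fill implicit hydrogens from the valence model: effective valence is the
# element default shifted by the formal charge; atoms already exceeding it
# keep their bonds, get 0 implicit H, and trigger a warning. Elements with no
# tabulated valence (metals etc.) silently get 0.
implicit_h_fill <- function(g) {
  deg <- numeric(n_atoms(g))
  for (r in seq_len(nrow(g$bonds))) {
    o <- g$bonds$order[r]
    if (o == 4L) o <- 1.5          # aromatic; kekulize for exact counts
    deg[g$bonds$i[r]] <- deg[g$bonds$i[r]] + o
    deg[g$bonds$j[r]] <- deg[g$bonds$j[r]] + o
  }
  eff <- default_valence(g$atoms$element, g$atoms$charge)
  fill <- which(is.na(g$atoms$hcount))
  for (a in fill) {
    if (is.na(eff[a])) { g$atoms$hcount[a] <- 0L; next }
    free <- eff[a] - deg[a]
    if (free < 0) {
      warning(sprintf("atom %d (%s) exceeds its valence model; 0 implicit H assigned",
                      a, g$atoms$element[a]), call. = FALSE)
      free <- 0
    }
    g$atoms$hcount[a] <- as.integer(floor(free))
  }
  g
}

## ---- Molfile V2000 ---------------------------------------------------------

#' Read a Molfile (V2000 connection table)
#'
#' A tolerant whitespace-splitting reader for the legacy connection-table
#' format: 3 header lines, counts line, atom block (coordinates, element,
#' legacy charge code, optional explicit valence), bond block (indices,
#' order, wedge stereo flag 1=up / 6=down), then property lines. `M  CHG`
#' lines override all legacy charge codes, per the format definition.
#' Explicit hydrogen atoms bonded to a single heavy atom are folded into that
#' atom's hydrogen count; remaining hydrogens are filled from the valence
#' model (or taken from an explicit valence column). Aromatic bonds (order 4)
#' are kekulized immediately by a deterministic matching.
#'
#' @param text the Molfile contents as a single string or character vector of
#'   lines.
#' @return a `mol_graph`.
#' @export
read_molfile <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  if (length(lines) < 4L) format_error("header", "truncated Molfile")
  counts <- strsplit(trimws(lines[4]), "[[:space:]]+")[[1]]
  na <- suppressWarnings(as.integer(counts[1]))
  nb <- suppressWarnings(as.integer(counts[2]))
  if (is.na(na) || is.na(nb)) format_error("counts", "unreadable counts line")
  if (na > 999L) format_error("v2000-limit", "V2000 cannot hold more than 999 atoms")
  if (na < 1L) format_error("empty", "empty atom block")
  if (length(lines) < 4L + na + nb) format_error("counts", "atom/bond block shorter than counts line")
  atom_lines <- lines[4L + seq_len(na)]
  bond_lines <- if (nb > 0L) lines[4L + na + seq_len(nb)] else character(0)

  el <- character(na); x <- numeric(na); y <- numeric(na)
  chg <- integer(na); val_override <- rep(NA_integer_, na)
  legacy_chg <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
  for (k in seq_len(na)) {
    f <- strsplit(trimws(atom_lines[k]), "[[:space:]]+")[[1]]
    if (length(f) < 4L) format_error("atom", sprintf("unreadable atom line %d", k))
    x[k] <- suppressWarnings(as.numeric(f[1]))
    y[k] <- suppressWarnings(as.numeric(f[2]))
    el[k] <- f[4]
    if (length(f) >= 6L) {
      code <- suppressWarnings(as.integer(f[6]))
      if (!is.na(code) && as.character(code) %in% names(legacy_chg))
        chg[k] <- legacy_chg[[as.character(code)]]
    }
    if (length(f) >= 10L) {
      vv <- suppressWarnings(as.integer(f[10]))
      if (!is.na(vv) && vv > 0L) val_override[k] <- if (vv == 15L) 0L else vv
    }
  }
  bad <- !is_known_symbol(el)
  if (any(bad)) format_error("element", paste("unknown element:", el[bad][1]))

  bi <- integer(nb); bj <- integer(nb); bo <- integer(nb); bw <- character(nb)
  for (k in seq_len(nb)) {
    f <- suppressWarnings(as.integer(strsplit(trimws(bond_lines[k]), "[[:space:]]+")[[1]]))
    if (length(f) < 3L || anyNA(f[1:3])) format_error("bond", sprintf("unreadable bond line %d", k))
    if (f[1] < 1L || f[1] > na || f[2] < 1L || f[2] > na)
      format_error("bond", sprintf("bond %d references a missing atom", k))
    bi[k] <- f[1]; bj[k] <- f[2]; bo[k] <- f[3]
    st <- if (length(f) >= 4L && !is.na(f[4])) f[4] else 0L
    bw[k] <- if (st == 1L) "up" else if (st == 6L) "down" else "none"
  }

  # property block: M  CHG overrides every legacy charge code
  props <- lines[-seq_len(4L + na + nb)]
  chg_lines <- grep("^M  CHG", props, value = TRUE)
  if (length(chg_lines)) {
    chg <- integer(na)
    for (ln in chg_lines) {
      f <- strsplit(trimws(sub("^M  CHG[[:space:]]*[0-9]+", "", ln)), "[[:space:]]+")[[1]]
      f <- suppressWarnings(as.integer(f))
      if (length(f) %% 2L != 0L || anyNA(f)) format_error("chg", "unreadable M CHG line")
      for (p in seq(1L, length(f), by = 2L)) {
        if (f[p] < 1L || f[p] > na) format_error("chg", "M CHG references a missing atom")
        chg[f[p]] <- f[p + 1L]
      }
    }
  }

  g <- structure(list(
    atoms = data.frame(element = el, charge = chg, hcount = NA_integer_,
                       x = x, y = y, parity = NA_character_, stringsAsFactors = FALSE),
    bonds = data.frame(i = bi, j = bj, order = bo, wedge = bw, stringsAsFactors = FALSE),
    mobile_groups = list(), extra_charge = 0L), class = "mol_graph")
  if (any(g$bonds$order == 4L)) g <- kekulize(g)
  g <- fold_explicit_hydrogens(g)
  val_override <- val_override[attr(g, "kept_atoms") %||% seq_len(na)]
  attr(g, "kept_atoms") <- NULL
  eff <- default_valence(g$atoms$element, g$atoms$charge)
  eff[!is.na(val_override)] <- val_override[!is.na(val_override)]
  g <- implicit_h_fill_with(g, eff)
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

implicit_h_fill_with <- function(g, eff) {
  deg <- numeric(n_atoms(g))
  for (r in seq_len(nrow(g$bonds))) {
    deg[g$bonds$i[r]] <- deg[g$bonds$i[r]] + g$bonds$order[r]
    deg[g$bonds$j[r]] <- deg[g$bonds$j[r]] + g$bonds$order[r]
  }
  folded <- g$atoms$hcount
  folded[is.na(folded)] <- 0L
  for (a in seq_len(n_atoms(g))) {
    if (is.na(eff[a])) { g$atoms$hcount[a] <- folded[a]; next }
    free <- eff[a] - deg[a] - folded[a]
    if (free < 0) {
      warning(sprintf("atom %d (%s) exceeds its valence model; no implicit H added",
                      a, g$atoms$element[a]), call. = FALSE)
      free <- 0
    }
    g$atoms$hcount[a] <- folded[a] + as.integer(floor(free))
  }
  g
}

# explicit H atoms bonded to exactly one heavy atom become part of that
# atom's hydrogen count; H2 and isolated H are kept as atoms
fold_explicit_hydrogens <- function(g) {
  n <- n_atoms(g)
  is_h <- g$atoms$element == "H"
  if (!any(is_h)) { attr(g, "kept_atoms") <- seq_len(n); return(g) }
  adj <- adjacency_list(g)
  fold <- vapply(seq_len(n), function(a) {
    is_h[a] && length(adj[[a]]) == 1L && !is_h[adj[[a]]]
  }, logical(1))
  if (!any(fold)) { attr(g, "kept_atoms") <- seq_len(n); return(g) }
  extra_h <- integer(n)
  for (a in which(fold)) extra_h[adj[[a]]] <- extra_h[adj[[a]]] + 1L
  drop_bond <- g$bonds$i %in% which(fold) | g$bonds$j %in% which(fold)
  if (any(g$bonds$wedge[drop_bond] != "none"))
    warning("wedge on an explicit hydrogen bond is dropped when folding", call. = FALSE)
  keep <- which(!fold)
  remap <- integer(n); remap[keep] <- seq_along(keep)
  bonds <- g$bonds[!drop_bond, , drop = FALSE]
  bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
  atoms <- g$atoms[keep, , drop = FALSE]
  # folded counts become the explicit part; NA still means "fill from valence"
  atoms$hcount <- ifelse(extra_h[keep] > 0L, extra_h[keep], NA_integer_)
  rownames(atoms) <- NULL; rownames(bonds) <- NULL
  g$atoms <- atoms; g$bonds <- bonds
  attr(g, "kept_atoms") <- keep
  g
}

# Deterministic kekulization of aromatic (order 4) bonds: every atom incident
# to an aromatic bond must receive exactly one double bond among them.
# Backtracking over atoms in index order, preferring the lowest-indexed
# partner, makes the assignment reproducible.
kekulize <- function(g) {
  arom <- which(g$bonds$order == 4L)
  if (!length(arom)) return(g)
  atoms_in <- sort(unique(c(g$bonds$i[arom], g$bonds$j[arom])))
  partners <- lapply(atoms_in, function(a) {
    rows <- arom[g$bonds$i[arom] == a | g$bonds$j[arom] == a]
    other <- ifelse(g$bonds$i[rows] == a, g$bonds$j[rows], g$bonds$i[rows])
    rows[order(other)]
  })
  names(partners) <- atoms_in
  matched <- integer(0)        # bond rows assigned order 2
  assigned <- logical(max(atoms_in))
  solve <- function(k, matched) {
    if (k > length(atoms_in)) return(matched)
    a <- atoms_in[k]
    if (assigned[a]) return(solve(k + 1L, matched))
    for (row in partners[[k]]) {
      b <- ifelse(g$bonds$i[row] == a, g$bonds$j[row], g$bonds$i[row])
      if (assigned[b]) next
      assigned[a] <<- TRUE; assigned[b] <<- TRUE
      res <- solve(k + 1L, c(matched, row))
      if (!is.null(res)) return(res)
      assigned[a] <<- FALSE; assigned[b] <<- FALSE
    }
    NULL
  }
  res <- solve(1L, integer(0))
  if (is.null(res)) format_error("kekulize", "no perfect matching for aromatic bonds")
  g$bonds$order[arom] <- 1L
  g$bonds$order[res] <- 2L
  g
}

#' Write a Molfile (V2000)
#'
#' Inverse of [read_molfile()]: `read_molfile(write_molfile(g))` reproduces
#' `g` with identical atom order. Hydrogen counts that disagree with the
#' valence model are preserved through the explicit valence column.
#'
#' @param g a `mol_graph` with at most 999 atoms.
#' @return the Molfile text as a single string.
#' @export
write_molfile <- function(g) {
  n <- n_atoms(g)
  if (n > 999L) format_error("v2000-limit", "V2000 cannot hold more than 999 atoms")
  nb <- nrow(g$bonds)
  eff <- default_valence(g$atoms$element, g$atoms$charge)
  deg <- numeric(n)
  for (r in seq_len(nb)) {
    deg[g$bonds$i[r]] <- deg[g$bonds$i[r]] + g$bonds$order[r]
    deg[g$bonds$j[r]] <- deg[g$bonds$j[r]] + g$bonds$order[r]
  }
  out <- c("", "  minichi 2D", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (a in seq_len(n)) {
    total <- deg[a] + g$atoms$hcount[a]
    vcol <- 0L
    if (is.na(eff[a]) || total != eff[a]) vcol <- if (total == 0) 15L else as.integer(total)
    out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0%3d  0  0  0  0  0  0",
                          ifelse(is.na(g$atoms$x[a]), 0, g$atoms$x[a]),
                          ifelse(is.na(g$atoms$y[a]), 0, g$atoms$y[a]),
                          0, g$atoms$element[a], vcol))
  }
  wcode <- c(none = 0L, up = 1L, down = 6L)
  for (r in seq_len(nb)) {
    out <- c(out, sprintf("%3d%3d%3d%3d", g$bonds$i[r], g$bonds$j[r],
                          g$bonds$order[r], wcode[[g$bonds$wedge[r]]]))
  }
  charged <- which(g$atoms$charge != 0L)
  while (length(charged)) {
    take <- charged[seq_len(min(8L, length(charged)))]
    charged <- charged[-seq_len(min(8L, length(charged)))]
    out <- c(out, paste0("M  CHG", sprintf("%3d", length(take)),
                         paste0(sprintf("%4d%4d", take, g$atoms$charge[take]), collapse = "")))
  }
  out <- c(out, "M  END")
  paste(out, collapse = "\n")
}

#' Read an SDF batch (records separated by `$$$$`)
#' @param text SDF contents (string or lines).
#' @return list of `mol_graph` objects.
#' @export
read_sdf <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  recs <- split(lines, cumsum(c(0L, head(lines == "$$$$", -1L))))
  recs <- lapply(recs, function(r) r[r != "$$$$"])
  recs <- Filter(function(r) any(nzchar(trimws(r))), recs)
  unname(lapply(recs, read_molfile))
}

## ---- identifier -> graph ---------------------------------------------------

#' Reconstruct a molecular graph from a parsed identifier
#'
#' Heavy atoms are instantiated in layer-index order using the canonical
#' element-numbering convention: each element occupies a contiguous index
#' block, carbon first, heteroatoms alphabetically, `Zz` last. Fixed
#' hydrogens are attached per `/h`; each mobile group's hydrogens are placed
#' on its lowest-indexed members and flagged as mobile (the identifier does
#' not localize them). Bond orders are unset (the identifier carries
#' connectivity only), so all bonds are recorded as single. A `/q` charge is
#' carried as a delocalized graph-level charge, again because the identifier
#' does not localize it.
#'
#' @param p a `parsed_inchi` (single-component).
#' @return a `mol_graph`.
#' @export
graph_from_inchi <- function(p) {
  if (!inherits(p, "parsed_inchi")) argument_error("type", "not a parsed_inchi")
  if (length(p$formula$components) != 1L || p$formula$components[[1]]$multiplier != 1L)
    reconstruct_error("multi-component", "only single-component identifiers are reconstructed")
  counts <- p$formula$components[[1]]$counts
  heavy <- counts[names(counts) != "H"]
  if (!length(heavy)) reconstruct_error("formula", "no heavy atoms in formula")
  elements <- rep(names(heavy), heavy)   # Hill order minus H == C, alpha, Zz
  n <- length(elements)
  bonds <- NULL
  if (!is.null(p$connections)) {
    if (length(p$connections$components) != 1L)
      reconstruct_error("multi-component", "multi-component connection layer")
    if (p$connections$max_index > n)
      reconstruct_error("index", sprintf("/c index %d exceeds %d heavy atoms",
                                         p$connections$max_index, n))
    bonds <- p$connections$bonds
  } else if (n > 1L) {
    reconstruct_error("connections", "multi-atom molecule lacks a /c layer")
  }
  hcount <- integer(n)
  mobile_groups <- list()
  if (!is.null(p$hydrogens)) {
    comp <- p$hydrogens$components[[1]]
    if (length(comp$fixed)) hcount[names2int(comp$fixed)] <- comp$fixed
    for (gr in comp$mobile_groups) {
      placed <- gr$atoms[seq_len(min(gr$h, length(gr$atoms)))]
      tab <- table(placed)
      hcount[as.integer(names(tab))] <- hcount[as.integer(names(tab))] + as.integer(tab)
      mobile_groups[[length(mobile_groups) + 1L]] <-
        list(h = gr$h, atoms = gr$atoms, placed = placed)
    }
  }
  parity <- rep(NA_character_, n)
  if (!is.null(p$stereo) && nrow(p$stereo$t_entries))
    parity[p$stereo$t_entries$idx] <- p$stereo$t_entries$parity
  g <- mol_graph(elements, bonds = bonds, hcount = hcount, parity = parity)
  g$mobile_groups <- mobile_groups
  g$extra_charge <- if (is.na(p$charge_q)) 0L else p$charge_q
  g$stereo_flags <- if (!is.null(p$stereo)) list(m = p$stereo$m_flag, s = p$stereo$s_flag) else NULL
  g
}

## ---- formulas, permutations ------------------------------------------------

#' Hill formula of a graph
#'
#' @param g a `mol_graph`.
#' @return a single-component `formula_layer`: carbon, hydrogen, then other
#'   elements alphabetically, `Zz` last. Hydrogens are the sum of per-atom
#'   hydrogen counts plus any explicit H atoms.
#' @examples
#' format(hill_formula(mol_graph("C", hcount = 4L)))
#' @export
hill_formula <- function(g) {
  el <- g$atoms$element
  h_total <- sum(g$atoms$hcount) + sum(el == "H")
  counts <- table(el[el != "H"])
  counts <- stats::setNames(as.integer(counts), names(counts))
  if (h_total > 0L) counts <- c(counts, H = as.integer(h_total))
  counts <- counts[hill_sort_symbols(names(counts))]
  new_formula_layer(list(list(counts = counts, multiplier = 1L)))
}

#' Relabel a graph's atoms by a permutation
#'
#' `perm[i]` is the new index of input atom `i`. Coordinates, wedges and
#' mobile-group metadata travel with the atoms; tetrahedral parities are
#' recomputed for the new ascending-neighbor convention (they flip when the
#' relabeling reorders a centre's sorted neighbor list by an odd
#' permutation).
#'
#' @param g a `mol_graph`.
#' @param perm integer vector, a bijection on `1..n_atoms(g)`.
#' @return the relabeled `mol_graph`.
#' @export
permute <- function(g, perm) {
  n <- n_atoms(g)
  if (length(perm) != n || !setequal(perm, seq_len(n)))
    argument_error("perm", "perm must be a bijection on 1..n")
  perm <- as.integer(perm)
  adj <- adjacency_list(g)
  atoms <- g$atoms[order(perm), , drop = FALSE]
  rownames(atoms) <- NULL
  # parity bookkeeping before relabeling bonds
  for (a in which(!is.na(g$atoms$parity))) {
    pa <- g$atoms$parity[a]
    if (pa %in% c("+", "-")) {
      s <- relabel_sort_sign(adj[[a]], perm)
      if (s < 0L) pa <- if (pa == "+") "-" else "+"
    }
    atoms$parity[perm[a]] <- pa
  }
  bonds <- g$bonds
  bonds$i <- perm[g$bonds$i]; bonds$j <- perm[g$bonds$j]
  g2 <- g
  g2$atoms <- atoms
  g2$bonds <- bonds
  g2$mobile_groups <- lapply(g$mobile_groups, function(gr) {
    list(h = gr$h, atoms = sort(perm[gr$atoms]), placed = sort(perm[gr$placed]))
  })
  g2
}

# sign of the rearrangement that re-sorts a sorted neighbor list after
# relabeling; the implicit-H slot (absent here) stays last and is unaffected
relabel_sort_sign <- function(sorted_neighbors, perm) {
  mapped <- perm[sorted_neighbors]
  permutation_sign(order(mapped))
}

permutation_sign <- function(p) {
  n <- length(p)
  seen <- logical(n)
  cycles <- 0L
  for (k in seq_len(n)) {
    if (seen[k]) next
    cycles <- cycles + 1L
    j <- k
    while (!seen[j]) { seen[j] <- TRUE; j <- p[j] }
  }
  if ((n - cycles) %% 2L == 0L) 1L else -1L
}

## ---- seeded fixture generator ----------------------------------------------

# run code under a known RNG seed without touching the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Seeded random molecule generator
#'
#' Grows a connected, valence-valid heavy-atom graph: a random tree built by
#' attaching each new atom to an existing atom with free valence, followed by
#' a few ring-closing bonds between non-adjacent atoms that still have free
#' valence (about one ring per six atoms). Elements are drawn from
#' `element_weights`; nitrogen/phosphorus atoms may take a +1 charge and
#' oxygen/sulfur a -1 charge with probability `charge_prob`, shifting their
#' valence accordingly. Remaining valence becomes implicit hydrogens. The
#' result is fully determined by `seed`.
#'
#' @param n_atoms number of heavy atoms (>= 1).
#' @param element_weights named numeric sampling weights over
#'   C/N/O/S/P/F/Cl/Br/I; the default reflects typical organic molecules.
#' @param charge_prob per-eligible-atom probability of a formal charge.
#' @param seed integer seed (required: fixtures must be reproducible).
#' @return a `mol_graph`.
#' @examples
#' g <- random_graph(12, seed = 7)
#' format(hill_formula(g))
#' @export
random_graph <- function(n_atoms,
                         element_weights = c(C = 10, N = 2, O = 2, S = 1,
                                             P = 0.5, F = 0.5, Cl = 0.5,
                                             Br = 0.2, I = 0.1),
                         charge_prob = 0.05, seed) {
  if (missing(seed)) argument_error("seed", "a seed is required for reproducibility")
  if (n_atoms < 1L) generate_error("n", "n_atoms must be >= 1")
  allowed <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")
  if (!all(names(element_weights) %in% allowed) || any(element_weights < 0) ||
      sum(element_weights) <= 0)
    generate_error("weights", "element_weights must be nonnegative over C/N/O/S/P/halogens")
  with_seed(seed, {
    pool <- names(element_weights)
    wts <- element_weights / sum(element_weights)
    draw_atom <- function() {
      el <- sample(pool, 1L, prob = wts)
      ch <- 0L
      if (el %in% c("N", "P") && stats::runif(1) < charge_prob) ch <- 1L
      if (el %in% c("O", "S") && stats::runif(1) < charge_prob) ch <- -1L
      c(el, ch)
    }
    el <- character(n_atoms); chg <- integer(n_atoms)
    free <- numeric(n_atoms)
    a1 <- draw_atom()
    el[1] <- a1[1]; chg[1] <- as.integer(a1[2])
    free[1] <- default_valence(el[1], chg[1])
    bi <- integer(0); bj <- integer(0)
    for (k in seq_len(n_atoms)[-1]) {
      cand <- which(free[seq_len(k - 1L)] > 0)
      if (!length(cand)) generate_error("valence", "no free valence left to attach an atom")
      target <- if (length(cand) == 1L) cand else sample(cand, 1L)
      ak <- draw_atom()
      # keep the growing tree extensible: if attaching this atom would
      # exhaust every valence while atoms remain, force a carbon
      v <- default_valence(ak[1], as.integer(ak[2]))
      if (k < n_atoms && sum(free[seq_len(k - 1L)]) - 1 + (v - 1) < 1) {
        ak <- c("C", "0"); v <- 4
      }
      el[k] <- ak[1]; chg[k] <- as.integer(ak[2])
      free[k] <- v - 1
      free[target] <- free[target] - 1
      bi <- c(bi, target); bj <- c(bj, k)
    }
    # ring closures
    n_rings <- n_atoms %/% 6L
    bonded <- paste(pmin(bi, bj), pmax(bi, bj))
    for (r in seq_len(n_rings)) {
      open <- which(free > 0)
      if (length(open) < 2L) break
      pairs <- utils::combn(open, 2L)
      keys <- paste(pairs[1, ], pairs[2, ])
      ok <- !(keys %in% bonded)
      if (!any(ok)) break
      pick <- if (sum(ok) == 1L) which(ok) else sample(which(ok), 1L)
      u <- pairs[1, pick]; v <- pairs[2, pick]
      bi <- c(bi, u); bj <- c(bj, v)
      bonded <- c(bonded, keys[pick])
      free[u] <- free[u] - 1; free[v] <- free[v] - 1
    }
    mol_graph(el, bonds = if (length(bi)) cbind(i = bi, j = bj) else NULL,
              charge = chg, hcount = as.integer(floor(free)))
  })
}

## ---- isomorphism (brute force) ---------------------------------------------

#' Brute-force graph isomorphism test
#'
#' Backtracking matcher over atom mappings compatible with (element, charge,
#' hydrogen count, degree); intended as an independent oracle for small
#' molecules, e.g. when verifying suspected identifier collisions.
#'
#' @param g1,g2 `mol_graph` objects.
#' @param max_atoms refuse larger inputs (worst case is factorial).
#' @return logical.
#' @export
graphs_isomorphic <- function(g1, g2, max_atoms = 12L) {
  n <- n_atoms(g1)
  if (n != n_atoms(g2)) return(FALSE)
  if (n > max_atoms) argument_error("size", sprintf("isomorphism oracle limited to %d atoms", max_atoms))
  key <- function(g) paste(g$atoms$element, g$atoms$charge, g$atoms$hcount, graph_degrees(g))
  k1 <- key(g1); k2 <- key(g2)
  if (!identical(sort(k1), sort(k2))) return(FALSE)
  adj1 <- adjacency_list(g1); adj2 <- adjacency_list(g2)
  map <- integer(n); used <- logical(n)
  match_from <- function(a) {
    if (a > n) return(TRUE)
    for (b in which(!used & k2 == k1[a])) {
      lower <- adj1[[a]][adj1[[a]] < a]
      if (all(map[lower] %in% adj2[[b]]) &&
          length(adj1[[a]]) == length(adj2[[b]])) {
        map[a] <<- b; used[b] <<- TRUE
        if (match_from(a + 1L)) return(TRUE)
        used[b] <<- FALSE
      }
    }
    FALSE
  }
  match_from(1L)
}

## ---- structural equality, printing -----------------------------------------

#' Order-sensitive structural equality of two graphs
#'
#' Same elements, charges, hydrogen counts and parities in the same atom
#' order, and the same bond set (bond direction and row order ignored).
#'
#' @param g1,g2 `mol_graph` objects.
#' @return logical.
#' @export
graph_identical <- function(g1, g2) {
  norm_bonds <- function(g) {
    b <- data.frame(i = pmin(g$bonds$i, g$bonds$j), j = pmax(g$bonds$i, g$bonds$j),
                    order = g$bonds$order)
    b[order(b$i, b$j), ]
  }
  isTRUE(all.equal(g1$atoms$element, g2$atoms$element)) &&
    identical(g1$atoms$charge, g2$atoms$charge) &&
    identical(g1$atoms$hcount, g2$atoms$hcount) &&
    identical(g1$atoms$parity, g2$atoms$parity) &&
    isTRUE(all.equal(norm_bonds(g1), norm_bonds(g2), check.attributes = FALSE))
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %s: %d atoms, %d bonds, net charge %d\n",
              serialize_formula(hill_formula(x)), n_atoms(x), nrow(x$bonds),
              net_charge(x)))
  invisible(x)
}
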