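#' @title Reference canonical labeling
#' @description
#' The package's embodiment of the identifier contract: one molecule, one
#' string, independent of input atom order. Atoms are first partitioned by an
#' order-free invariant (element, degree, attached hydrogens, formal charge),
#' the partition is refined to the coarsest equitable partition, and the
#' canonical labeling is the one — among all labelings consistent with that
#' ordered partition — whose serialized identifier text is lexicographically
#' smallest. When the consistent labelings are few they are enumerated
#' exhaustively; large symmetric cells are handled by individualization and
#' re-refinement. Both strategies are isomorphism-invariant, so the result
#' does not depend on the input numbering.
#' @name canonicalizer
NULL

# exhaustive-enumeration budget: up to 8! consistent labelings are tried
# directly, which covers every graph the n!-enumeration oracle accepts
EXHAUSTIVE_LIMIT <- 40320

#' Order-free initial invariant of one atom
#'
#' The tuple (element rank, degree, attached hydrogens, formal charge), with
#' carbon ranked first, heteroatoms alphabetically and `Zz` after every true
#' element. Atoms with identical tuples start in the same partition cell.
#'
#' @param g a `mol_graph`.
#' @param atom atom index.
#' @return named integer vector of length 4.
#' @export
initial_invariant <- function(g, atom) {
  deg <- graph_degrees(g)
  c(element = as.integer(element_rank(g$atoms$element[atom])),
    degree = deg[atom],
    hydrogens = g$atoms$hcount[atom],
    charge = g$atoms$charge[atom])
}

invariant_keys <- function(g) {
  deg <- graph_degrees(g)
  sprintf("%05d|%03d|%03d|%+04d",
          element_rank(g$atoms$element), deg, g$atoms$hcount, g$atoms$charge)
}

initial_partition <- function(g) {
  keys <- invariant_keys(g)
  split(seq_len(n_atoms(g)), factor(keys, levels = sort(unique(keys))))
}

cell_ids <- function(p, n) {
  id <- integer(n)
  for (k in seq_along(p)) id[p[[k]]] <- k
  id
}

#' Refine a partition to equitability
#'
#' Repeatedly splits cells until any two atoms sharing a cell have identical
#' multisets of neighbor-cell memberships. Split cells keep their parent's
#' position and are sub-ordered by their neighbor-count signature, so the
#' result is deterministic.
#'
#' @param g a `mol_graph`.
#' @param p a partition: list of disjoint atom-index vectors covering all
#'   atoms.
#' @return the refined partition (same representation).
#' @export
refine_partition <- function(g, p) {
  adj <- adjacency_list(g)
  refine_partition_adj(adj, n_atoms(g), p)
}

refine_partition_adj <- function(adj, n, p) {
  p <- lapply(p, sort)
  repeat {
    id <- cell_ids(p, n)
    k <- length(p)
    newp <- vector("list", 0L)
    changed <- FALSE
    for (cell in p) {
      if (length(cell) == 1L) { newp[[length(newp) + 1L]] <- cell; next }
      sig <- vapply(cell, function(a) {
        paste(sprintf("%03d", tabulate(id[adj[[a]]], nbins = k)), collapse = "")
      }, character(1))
      if (length(unique(sig)) == 1L) { newp[[length(newp) + 1L]] <- cell; next }
      for (s in sort(unique(sig)))
        newp[[length(newp) + 1L]] <- sort(cell[sig == s])
      changed <- TRUE
    }
    if (!changed) return(p)
    p <- newp
  }
}

## ---- certificate -----------------------------------------------------------

# permutation matrices of 1..n, cached (n <= 8)
.perm_cache <- new.env(parent = emptyenv())
perm_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  m <- if (n == 1L) matrix(1L, 1, 1) else {
    prev <- perm_matrix(n - 1L)
    # insert value n at every position of every (n-1)-permutation
    do.call(rbind, lapply(seq_len(n), function(pos) {
      if (pos == n) cbind(prev, n)
      else if (pos == 1L) cbind(n, prev)
      else cbind(prev[, seq_len(pos - 1L), drop = FALSE], n,
                 prev[, pos:(n - 1L), drop = FALSE])
    }))
  }
  storage.mode(m) <- "integer"
  .perm_cache[[key]] <- m
  m
}

# serialized identifier text of g under a labeling; this is the object the
# canonical search minimizes and the string users ultimately see
certificate_string <- function(g, perm, ctx = cert_context(g)) {
  n <- ctx$n
  newadj <- vector("list", n)
  for (v in seq_len(n)) newadj[[perm[v]]] <- sort.int(perm[ctx$adj[[v]]])
  parts <- paste0("InChI=1M/", ctx$formula_txt)
  if (n > 1L) {
    # the depth-first rendering that starts at label 1 is lexicographically
    # minimal over all start atoms: every other start opens with a larger
    # token, and "1" followed by any structural character sorts first
    parts <- paste0(parts, "/c", cert_dfs_render(newadj, n))
  }
  # hydrogen layer: fixed part excludes mobile-group placements
  fixed <- integer(n)
  fixed[perm] <- g$atoms$hcount
  mob_txt <- ""
  if (length(g$mobile_groups)) {
    for (gr in g$mobile_groups) {
      placed <- perm[gr$placed]
      tab <- table(placed)
      fixed[as.integer(names(tab))] <- fixed[as.integer(names(tab))] - as.integer(tab)
    }
    groups <- lapply(g$mobile_groups, function(gr)
      list(h = gr$h, atoms = sort.int(perm[gr$atoms])))
    keys <- vapply(groups, function(gr)
      paste(sprintf("%04d", c(gr$atoms, gr$h)), collapse = ""), character(1))
    groups <- groups[order(keys)]
    mob_txt <- paste(vapply(groups, function(gr) {
      paste0("(H", if (gr$h > 1L) gr$h, ",", paste(gr$atoms, collapse = ","), ")")
    }, character(1)), collapse = "")
  }
  fparts <- character(0)
  pos <- which(fixed > 0L)
  if (length(pos)) {
    for (cnt in sort(unique(fixed[pos]))) {
      ids <- pos[fixed[pos] == cnt]
      fparts <- c(fparts, paste0(compress_ranges(ids), "H", if (cnt > 1L) cnt))
    }
  }
  htxt <- paste(fparts, collapse = ",")
  if (nzchar(mob_txt)) htxt <- if (nzchar(htxt)) paste0(htxt, ",", mob_txt) else mob_txt
  if (nzchar(htxt)) parts <- paste0(parts, "/h", htxt)
  if (ctx$q != 0L) parts <- paste0(parts, "/q", sprintf("%+d", ctx$q))
  # stereo entries, re-expressed for the new ascending-neighbor convention
  if (length(ctx$stereo_atoms)) {
    idx <- integer(0); par <- character(0)
    for (a in ctx$stereo_atoms) {
      pa <- g$atoms$parity[a]
      if (pa %in% c("+", "-") && relabel_sort_sign(ctx$adj[[a]], perm) < 0L)
        pa <- if (pa == "+") "-" else "+"
      idx <- c(idx, perm[a]); par <- c(par, pa)
    }
    o <- order(idx)
    parts <- paste0(parts, "/t", paste0(idx[o], par[o], collapse = ","))
  }
  if (ctx$polymer) {
    zz_new <- sort.int(perm[ctx$zz_caps])
    att <- vapply(zz_new, function(z) newadj[[z]][1], integer(1))
    unit_hi <- n - length(zz_new)
    parts <- paste0(parts, "/z101-1",
                    if (unit_hi > 1L) paste0("-", unit_hi),
                    "(", paste(paste0(zz_new, "-", att), collapse = ","), ")")
  }
  parts
}

# depth-first /c rendering from label 1 (ascending branches, ring closures
# at the latest-visited endpoint); tight inner loop for the canonical search
cert_dfs_render <- function(adj, n) {
  visited <- logical(n)
  emitted <- matrix(FALSE, n, n)
  render <- function(u) {
    items <- character(0)
    for (v in adj[[u]]) {
      if (visited[v]) {
        if (!emitted[u, v]) {
          emitted[u, v] <<- TRUE; emitted[v, u] <<- TRUE
          items <- c(items, as.character(v))
        }
      } else {
        emitted[u, v] <<- TRUE; emitted[v, u] <<- TRUE
        visited[v] <<- TRUE
        items <- c(items, paste0(v, render(v)))
      }
    }
    k <- length(items)
    if (k == 0L) return("")
    if (k == 1L) return(paste0("-", items))
    paste0("(", paste(items[-k], collapse = ","), ")", items[k])
  }
  visited[1L] <- TRUE
  paste0("1", render(1L))
}

# per-graph constants shared by every certificate evaluation
cert_context <- function(g) {
  deg <- graph_degrees(g)
  zz <- which(g$atoms$element == "Zz")
  zz_caps <- zz[deg[zz] == 1L]
  stereo_atoms <- which(!is.na(g$atoms$parity))
  if (length(zz_caps) && !isTRUE(attr(g, "zz_stereo"))) {
    # stereochemistry adjacent to a cap atom is disabled by default
    adj <- adjacency_list(g)
    near_zz <- unique(unlist(adj[zz_caps]))
    stereo_atoms <- setdiff(stereo_atoms, near_zz)
  }
  list(n = n_atoms(g), adj = adjacency_list(g),
       formula_txt = serialize_formula(hill_formula(g)),
       q = net_charge(g),
       stereo_atoms = stereo_atoms,
       polymer = length(zz_caps) == 2L,
       zz_caps = zz_caps)
}

## ---- search ----------------------------------------------------------------

#' Canonical labeling of a connected graph
#'
#' @param g a connected `mol_graph` with at least one atom.
#' @return a `canonical_labeling`: list with `perm` (input index -> canonical
#'   label) and `certificate` (the serialized identifier text under `perm`,
#'   minimal over all labelings consistent with the refinement tree).
#' @examples
#' g <- graph_from_inchi(parse_inchi("InChI=1S/C6H7N/c1-6-4-2-3-5-7-6/h2-5H,1H3"))
#' canonical_labeling(g)$certificate
#' @export
canonical_labeling <- function(g) {
  if (n_atoms(g) < 1L) argument_error("atoms", "empty graph")
  if (!is_connected(g)) argument_error("disconnected", "canonical labeling needs a connected graph")
  ctx <- cert_context(g)
  n <- ctx$n
  p0 <- refine_partition_adj(ctx$adj, n, initial_partition(g))
  best <- new.env(parent = emptyenv())
  best$cert <- NULL; best$perm <- NULL
  search_partition(g, ctx, p0, best)
  structure(list(perm = best$perm, certificate = best$cert),
            class = "canonical_labeling")
}

search_partition <- function(g, ctx, p, best) {
  sizes <- lengths(p)
  fprod <- 1
  for (s in sizes) {
    fprod <- fprod * factorial(s)
    if (fprod > EXHAUSTIVE_LIMIT) break
  }
  if (fprod <= EXHAUSTIVE_LIMIT) {
    enumerate_consistent(g, ctx, p, best)
    return(invisible(NULL))
  }
  nonsingle <- which(sizes > 1L)
  target <- nonsingle[which.min(sizes[nonsingle])]
  cell <- p[[target]]
  for (a in cell) {
    p2 <- append(p[-target], list(a, sort(setdiff(cell, a))), after = target - 1L)
    p2 <- refine_partition_adj(ctx$adj, ctx$n, p2)
    search_partition(g, ctx, p2, best)
  }
  invisible(NULL)
}

enumerate_consistent <- function(g, ctx, p, best) {
  offsets <- c(0L, cumsum(lengths(p)))
  cell_orders <- lapply(p, function(cell) {
    k <- length(cell)
    if (k == 1L) matrix(cell, 1, 1) else {
      m <- perm_matrix(k)
      matrix(cell[m], nrow(m), k)
    }
  })
  counts <- vapply(cell_orders, nrow, integer(1))
  total <- prod(counts)
  n <- ctx$n
  # Within one partition every consistent labeling shares the formula, /h and
  # /q text (cells are invariant-homogeneous), so when no stereo or mobile-H
  # metadata is present and labels are single-digit the /c (+/z) rendering
  # alone orders the candidates; the full certificate is built once for the
  # winner. Multi-digit labels could make one rendering a prefix of another,
  # where concatenation order differs from segment order, so large graphs
  # always use the full text.
  fast <- n <= 9L && !length(ctx$stereo_atoms) && !length(g$mobile_groups)
  best_key <- NULL; best_local <- NULL
  perm <- integer(n)
  for (t in seq_len(total) - 1L) {
    rem <- t
    for (ci in seq_along(p)) {
      pick <- rem %% counts[ci] + 1L
      rem <- rem %/% counts[ci]
      ord <- cell_orders[[ci]][pick, ]
      perm[ord] <- offsets[ci] + seq_along(ord)
    }
    if (fast) {
      key <- cert_key(ctx, perm)
      if (is.null(best_key) || key < best_key) {
        best_key <- key
        best_local <- perm
      }
    } else {
      cert <- certificate_string(g, perm, ctx)
      if (is.null(best$cert) || cert < best$cert) {
        best$cert <- cert
        best$perm <- perm
      }
    }
  }
  if (fast && !is.null(best_local)) {
    cert <- certificate_string(g, best_local, ctx)
    if (is.null(best$cert) || cert < best$cert) {
      best$cert <- cert
      best$perm <- best_local
    }
  }
}

# comparison key for the fast enumeration path: /c rendering plus, for
# polymer units, the /z attachment text (the only other perm-dependent part)
cert_key <- function(ctx, perm) {
  n <- ctx$n
  newadj <- vector("list", n)
  for (v in seq_len(n)) newadj[[perm[v]]] <- sort.int(perm[ctx$adj[[v]]])
  key <- if (n > 1L) cert_dfs_render(newadj, n) else ""
  if (ctx$polymer) {
    zz_new <- sort.int(perm[ctx$zz_caps])
    att <- vapply(zz_new, function(z) newadj[[z]][1], integer(1))
    key <- paste0(key, "|", paste(paste0(zz_new, "-", att), collapse = ","))
  }
  key
}

#' Exhaustive canonical-labeling oracle
#'
#' Independent check for [canonical_labeling()]: enumerates all `n!`
#' permutations of the atoms, discards those inconsistent with the ordered
#' equitable partition (a labeling that scattered an element block would
#' serialize to a string that reconstructs a different molecule), and returns
#' the minimum certificate by flat enumeration — no search tree involved.
#'
#' @param g a connected `mol_graph` with at most 8 atoms.
#' @return a `canonical_labeling`.
#' @export
brute_force_labeling <- function(g) {
  n <- n_atoms(g)
  if (n > 8L) argument_error("size", "brute-force oracle limited to 8 atoms")
  if (!is_connected(g)) argument_error("disconnected", "needs a connected graph")
  ctx <- cert_context(g)
  p <- refine_partition_adj(ctx$adj, n, initial_partition(g))
  offsets <- c(0L, cumsum(lengths(p)))
  lo <- integer(n); hi <- integer(n)
  for (k in seq_along(p)) {
    lo[p[[k]]] <- offsets[k] + 1L
    hi[p[[k]]] <- offsets[k + 1L]
  }
  M <- perm_matrix(n)       # row r: labels assigned to atoms 1..n
  ok <- rep(TRUE, nrow(M))
  for (i in seq_len(n)) ok <- ok & M[, i] >= lo[i] & M[, i] <= hi[i]
  rows <- which(ok)
  best <- NULL; best_perm <- NULL
  for (r in rows) {
    perm <- M[r, ]
    cert <- certificate_string(g, perm, ctx)
    if (is.null(best) || cert < best) { best <- cert; best_perm <- perm }
  }
  structure(list(perm = best_perm, certificate = best),
            class = "canonical_labeling")
}

#' @export
print.canonical_labeling <- function(x, ...) {
  cat("<canonical_labeling>\n  perm: ", paste(x$perm, collapse = " "),
      "\n  certificate: ", x$certificate, "\n", sep = "")
  invisible(x)
}

## ---- identifier assembly ---------------------------------------------------

#' Assemble the canonical identifier of a molecular graph
#'
#' Relabels the atoms canonically and emits the layered identifier (dialect
#' `1M`): formula, `/c` as the lexicographically minimal depth-first
#' serialization, `/h` from hydrogen counts (mobile groups re-emitted as
#' metadata), `/q` from the net charge, `/t` from recanonicalized parities.
#' A graph carrying exactly two univalent `Zz` cap atoms is treated as a
#' polymer structural repeat unit: the caps are folded into a ring-closure
#' bond and the identifier is minimized over every connectivity-preserving
#' single-edge cut of the closed unit, so all equivalent cut/direction
#' representations of one repeat unit yield one identifier, with a `/z`
#' layer recording the unit range and cap attachments.
#'
#' @param g a connected, valence-valid `mol_graph`.
#' @return a `parsed_inchi` (dialect `"M"`).
#' @examples
#' serialize_inchi(assemble_identifier(mol_graph("C", hcount = 4L)))
#' @export
assemble_identifier <- function(g) {
  parse_inchi(identifier_string(g))
}

#' Canonical identifier text of a graph
#'
#' String-returning form of [assemble_identifier()]; this is the default
#' identifier function audited by the harness.
#'
#' @param g a connected `mol_graph`.
#' @return identifier text.
#' @export
identifier_string <- function(g) {
  if (!is_connected(g)) argument_error("disconnected", "multi-component input is not supported")
  if (any(g$bonds$order == 4L)) g <- kekulize(g)
  deg <- graph_degrees(g)
  zz <- which(g$atoms$element == "Zz")
  caps <- zz[deg[zz] == 1L]
  if (length(zz) == 2L && length(caps) == 2L) {
    adj <- adjacency_list(g)
    att <- c(adj[[caps[1]]], adj[[caps[2]]])
    if (att[1] != att[2] && !any((g$bonds$i == att[1] & g$bonds$j == att[2]) |
                                 (g$bonds$i == att[2] & g$bonds$j == att[1]))) {
      return(polymer_identifier_string(g, caps, att))
    }
  }
  canonical_labeling(g)$certificate
}

# close the capped repeat unit into a cycle, then minimize the capped
# identifier over every cut that keeps the unit connected (frame shift)
polymer_identifier_string <- function(g, caps, att) {
  keep <- setdiff(seq_len(n_atoms(g)), caps)
  remap <- integer(n_atoms(g)); remap[keep] <- seq_along(keep)
  closed <- g
  closed$atoms <- g$atoms[keep, , drop = FALSE]
  rownames(closed$atoms) <- NULL
  kb <- g$bonds[!(g$bonds$i %in% caps | g$bonds$j %in% caps), , drop = FALSE]
  kb$i <- remap[kb$i]; kb$j <- remap[kb$j]
  closed$bonds <- rbind(kb, data.frame(i = remap[att[1]], j = remap[att[2]],
                                       order = 1L, wedge = "none"))
  rownames(closed$bonds) <- NULL
  closed$mobile_groups <- lapply(g$mobile_groups, function(gr)
    list(h = gr$h, atoms = remap[gr$atoms], placed = remap[gr$placed]))
  best <- NULL
  for (e in seq_len(nrow(closed$bonds))) {
    cut <- closed$bonds[e, ]
    cand <- closed
    cand$bonds <- closed$bonds[-e, , drop = FALSE]
    if (!is_connected(cand)) next
    nc <- n_atoms(cand)
    cand$atoms <- rbind(cand$atoms,
                        data.frame(element = c("Zz", "Zz"), charge = 0L, hcount = 0L,
                                   x = NA_real_, y = NA_real_, parity = NA_character_,
                                   stringsAsFactors = FALSE))
    rownames(cand$atoms) <- NULL
    cand$bonds <- rbind(cand$bonds,
                        data.frame(i = c(cut$i, cut$j), j = c(nc + 1L, nc + 2L),
                                   order = 1L, wedge = "none"))
    attr(cand, "zz_stereo") <- attr(g, "zz_stereo")
    cert <- canonical_labeling(cand)$certificate
    if (is.null(best) || cert < best) best <- cert
  }
  if (is.null(best)) argument_error("polymer", "repeat unit cannot be re-cut")
  best
}

## ---- protonation normalization ---------------------------------------------

#' Fold a (de)protonation charge layer into the proton layer
#'
#' Identifiers for acidic hydroxy groups at cationic heteroatom centres were
#' historically written with both a charge layer and a proton layer (the
#' `/q-1/p+2` pattern); the current convention replaces the pair by a single
#' proton layer, with the extra hydrogen counted in the formula. The fold is
#' applied whenever `q < 0 <= p + q`; the bookkeeping quantity `q + p` is
#' conserved. Other nonzero-charge patterns are returned unchanged and
#' flagged for review rather than guessed at.
#'
#' @param q charge-layer value.
#' @param p proton-layer value.
#' @param h_total hydrogen count of the formula.
#' @return list with `q`, `p`, `h_total`, and logical `flagged`.
#' @examples
#' normalize_protonation(-1, 2, 10)   # -> q 0, p 1, h 11
#' @export
normalize_protonation <- function(q, p, h_total) {
  q <- as.integer(q); p <- as.integer(p); h_total <- as.integer(h_total)
  if (q == 0L) return(list(q = q, p = p, h_total = h_total, flagged = FALSE))
  if (q < 0L && p + q >= 0L) {
    # each folded negative charge adds one hydrogen to the formula
    return(list(q = 0L, p = p + q, h_total = h_total - q, flagged = FALSE))
  }
  list(q = q, p = p, h_total = h_total, flagged = TRUE)
}
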