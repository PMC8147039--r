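#' @title Tetrahedral stereo bookkeeping and 2D perception
#' @description
#' Parity bookkeeping for tetrahedral centres under relabeling, and the
#' 2D-depiction perception rules: a centre drawn with near-collinear
#' neighbor bonds gets no assignment (the drawing is ambiguous), unless the
#' loose check is enabled and the centre sits in a large ring, where the
#' overall ring geometry disambiguates an almost-straight local chain.
#' @name stereo
NULL

#' Sign of the permutation carrying one neighbor order to another
#'
#' @param order_a,order_b integer vectors holding the same elements.
#' @return `+1` for an even rearrangement, `-1` for an odd one.
#' @examples
#' neighbor_parity(c(1, 2, 3), c(2, 1, 3))   # one transposition -> -1
#' @export
neighbor_parity <- function(order_a, order_b) {
  if (length(order_a) != length(order_b) || !setequal(order_a, order_b) ||
      anyDuplicated(order_a))
    argument_error("neighbors", "orders must hold the same distinct elements")
  permutation_sign(match(order_b, order_a))
}

#' Construct a parity annotation
#'
#' @param center atom index of the stereocentre.
#' @param ordered_neighbors 3 or 4 neighbor atom indices; with 3, an implicit
#'   hydrogen occupies the last slot.
#' @param parity `"+"`, `"-"` or `"?"`.
#' @return a `parity_annotation`.
#' @export
parity_annotation <- function(center, ordered_neighbors, parity) {
  if (!length(ordered_neighbors) %in% c(3L, 4L))
    argument_error("neighbors", "a tetrahedral centre has 3 or 4 listed neighbors")
  if (!parity %in% c("+", "-", "?"))
    argument_error("parity", "parity must be '+', '-' or '?'")
  structure(list(center = as.integer(center),
                 ordered_neighbors = as.integer(ordered_neighbors),
                 parity = parity),
            class = "parity_annotation")
}

#' Re-express a parity annotation after relabeling
#'
#' Neighbor indices are mapped through `perm` and re-sorted ascending; the
#' parity flips exactly when that re-sort is an odd permutation. The
#' undefined parity `"?"` passes through unchanged. Applying a permutation
#' and then its inverse is the identity.
#'
#' @param a a `parity_annotation` whose neighbors are in ascending order.
#' @param perm integer bijection on the atom indices.
#' @return the relabeled `parity_annotation` (neighbors ascending).
#' @export
recanonicalize_parity <- function(a, perm) {
  mapped <- perm[a$ordered_neighbors]
  srt <- sort.int(mapped)
  parity <- a$parity
  if (parity %in% c("+", "-") && neighbor_parity(mapped, srt) < 0L)
    parity <- if (parity == "+") "-" else "+"
  parity_annotation(perm[a$center], srt, parity)
}

#' Perceive tetrahedral parities from a 2D depiction
#'
#' Candidate centres are the origin atoms of wedge bonds. A centre whose
#' in-plane neighbor bonds include a pair within `collinear_tol_deg` of
#' collinear is ambiguous and gets parity `"?"` — unless `loose_tsa_check`
#' is set and the centre lies in a ring of at least `min_loose_ring` atoms
#' (smallest ring through the centre), in which case the parity is computed
#' anyway: macrocycle depictions routinely run chains almost straight while
#' the ring as a whole makes the geometry unambiguous.
#'
#' The parity convention: neighbors are taken in ascending index order with
#' an implicit hydrogen in the last slot; wedge bonds lift their far atom
#' out of plane (up toward the viewer), an implicit hydrogen takes the
#' opposite side of the lifted neighbors; `"+"` means the signed volume of
#' the ordered neighbor tetrahedron is positive. Parity is invariant under
#' rotation and translation of the depiction and flips under mirror
#' reflection.
#'
#' Stereochemistry adjacent to `Zz` cap atoms is disabled by default; set
#' `zz_stereo` (or cap with [cap_with_zz()]`(..., enable_stereo = TRUE)`) to
#' switch it on.
#'
#' @param g a `mol_graph` with 2D coordinates and at least one wedge bond.
#' @param loose_tsa_check enable the large-ring relaxation.
#' @param collinear_tol_deg tolerance (degrees) around 0/180 within which
#'   two neighbor bonds count as collinear.
#' @param min_loose_ring smallest ring size that qualifies for the
#'   relaxation.
#' @param zz_stereo allow parities on atoms bonded to a `Zz` atom.
#' @return list of `parity_annotation` objects, one per candidate centre.
#' @export
perceive_tetrahedral_2d <- function(g, loose_tsa_check = FALSE,
                                    collinear_tol_deg = 3,
                                    min_loose_ring = 8L,
                                    zz_stereo = isTRUE(attr(g, "zz_stereo"))) {
  wrows <- which(g$bonds$wedge != "none")
  if (!length(wrows)) return(list())
  adj <- adjacency_list(g)
  centers <- unique(g$bonds$i[wrows])
  anns <- list()
  for (c0 in centers) {
    nbrs <- adj[[c0]]
    if (length(nbrs) < 3L || length(nbrs) > 4L)
      perception_error("wedge",
                       sprintf("wedge at atom %d, which has %d heavy neighbors (not a tetrahedral candidate)",
                               c0, length(nbrs)))
    implicit_h <- length(nbrs) == 3L
    if (implicit_h && g$atoms$hcount[c0] < 1L)
      perception_error("wedge", sprintf("atom %d has 3 neighbors but no hydrogen", c0))
    if (anyNA(g$atoms$x[c(c0, nbrs)]) || anyNA(g$atoms$y[c(c0, nbrs)]))
      perception_error("coords", sprintf("atom %d lacks 2D coordinates", c0))
    if (any(g$atoms$element[nbrs] == "Zz") && !zz_stereo) {
      anns[[length(anns) + 1L]] <- parity_annotation(c0, nbrs, "?")
      next
    }
    vx <- g$atoms$x[nbrs] - g$atoms$x[c0]
    vy <- g$atoms$y[nbrs] - g$atoms$y[c0]
    collinear <- FALSE
    for (a in seq_along(nbrs)[-length(nbrs)]) {
      for (b in (a + 1L):length(nbrs)) {
        ang <- angle_deg(vx[a], vy[a], vx[b], vy[b])
        if (ang < collinear_tol_deg || ang > 180 - collinear_tol_deg) collinear <- TRUE
      }
    }
    if (collinear) {
      relax <- loose_tsa_check && smallest_ring_through(adj, c0) >= min_loose_ring
      if (!relax) {
        anns[[length(anns) + 1L]] <- parity_annotation(c0, nbrs, "?")
        next
      }
    }
    # lift wedged neighbors out of plane; implicit H balances on the far side
    z <- numeric(length(nbrs))
    for (r in wrows) {
      if (g$bonds$i[r] != c0) next
      far <- g$bonds$j[r]
      z[match(far, nbrs)] <- if (g$bonds$wedge[r] == "up") 0.8 else -0.8
    }
    pts <- cbind(vx, vy, z)
    if (implicit_h)   # implicit H sits opposite the explicit neighbors
      pts <- rbind(pts, c(-mean(vx), -mean(vy), -sign(sum(z)) * 0.8))
    vol <- det(rbind(pts[2, ] - pts[1, ], pts[3, ] - pts[1, ], pts[4, ] - pts[1, ]))
    parity <- if (abs(vol) < 1e-9) "?" else if (vol > 0) "+" else "-"
    anns[[length(anns) + 1L]] <- parity_annotation(c0, nbrs, parity)
  }
  anns
}

angle_deg <- function(x1, y1, x2, y2) {
  d <- sum(c(x1, y1) * c(x2, y2)) / (sqrt(x1^2 + y1^2) * sqrt(x2^2 + y2^2))
  acos(pmin(1, pmax(-1, d))) * 180 / pi
}

# size of the smallest ring containing `v`; Inf when v is in no ring.
# For each neighbor pair (a, b) of v, the shortest a..b path avoiding v
# closes a ring of that length + 2.
smallest_ring_through <- function(adj, v) {
  nbrs <- adj[[v]]
  if (length(nbrs) < 2L) return(Inf)
  best <- Inf
  n <- length(adj)
  for (ai in seq_along(nbrs)[-length(nbrs)]) {
    for (bi in (ai + 1L):length(nbrs)) {
      a <- nbrs[ai]; b <- nbrs[bi]
      dist <- rep(Inf, n); dist[a] <- 0
      queue <- a
      while (length(queue)) {
        u <- queue[1]; queue <- queue[-1]
        if (u == b) break
        for (w in adj[[u]]) {
          if (w == v || dist[w] < Inf) next
          dist[w] <- dist[u] + 1
          queue <- c(queue, w)
        }
      }
      if (is.finite(dist[b])) best <- min(best, dist[b] + 2)
    }
  }
  best
}

#' Copy perceived parities onto a graph
#'
#' @param g a `mol_graph`.
#' @param annotations list of `parity_annotation` (e.g. from
#'   [perceive_tetrahedral_2d()]).
#' @return `g` with its per-atom `parity` column updated.
#' @export
set_parities <- function(g, annotations) {
  for (a in annotations) g$atoms$parity[a$center] <- a$parity
  g
}
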