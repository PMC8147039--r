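#' @title Polymer structural repeat units
#' @description
#' Structure-based polymer encoding: a structural (constitutional) repeat
#' unit is written with two `Zz` pseudo-atoms capping the positions where
#' consecutive units join. One repeat unit can be cut from the polymer chain
#' at any backbone bond and read in either direction, so several different
#' capped drawings describe the same polymer; this module enumerates those
#' representations and selects a canonical one.
#' @name polymer
NULL

#' Cap a repeat unit's open positions with Zz pseudo-atoms
#'
#' @param chain a `mol_graph`; the open positions must carry free valence
#'   (at least one hydrogen to give up, two when both caps land on the same
#'   atom).
#' @param open_positions integer vector of two atom indices (possibly the
#'   same atom twice).
#' @param enable_stereo keep tetrahedral parities on atoms adjacent to the
#'   caps; by default such parities are disabled.
#' @return the capped `mol_graph` (caps appended as the last two atoms).
#' @export
cap_with_zz <- function(chain, open_positions, enable_stereo = FALSE) {
  if (length(open_positions) != 2L)
    argument_error("positions", "exactly two open positions are required")
  n <- n_atoms(chain)
  if (any(open_positions < 1L | open_positions > n))
    argument_error("positions", "open position out of range")
  need <- table(open_positions)
  have <- chain$atoms$hcount[as.integer(names(need))]
  if (any(have < as.integer(need)))
    argument_error("valence", "open position has no free valence to cap")
  g <- chain
  g$atoms <- rbind(g$atoms,
                   data.frame(element = c("Zz", "Zz"), charge = 0L, hcount = 0L,
                              x = NA_real_, y = NA_real_, parity = NA_character_,
                              stringsAsFactors = FALSE))
  rownames(g$atoms) <- NULL
  g$bonds <- rbind(g$bonds,
                   data.frame(i = open_positions, j = c(n + 1L, n + 2L),
                              order = 1L, wedge = "none", stringsAsFactors = FALSE))
  rownames(g$bonds) <- NULL
  for (a in as.integer(names(need)))
    g$atoms$hcount[a] <- g$atoms$hcount[a] - need[[as.character(a)]]
  attr(g, "zz_stereo") <- isTRUE(enable_stereo)
  g
}

#' Enumerate the capped representations of a repeat unit
#'
#' The repeat unit is given as a graph whose `backbone` atoms form a simple
#' path with free valence at both ends (the implied bond back to the next
#' unit closes the repeat cycle). Each choice of cut bond and reading
#' direction yields one capped representation; a backbone of `k` atoms gives
#' `2k` of them (cuts at the `k` repeat-cycle bonds, two directions each).
#' Representations sharing a cut have identical graphs and differ only in
#' their recorded depiction ordering.
#'
#' @param unit a `mol_graph` of the repeat unit with open valence at the
#'   backbone ends.
#' @param backbone ordered integer vector of backbone atom indices.
#' @return list of representations, each a list with `graph` (capped
#'   `mol_graph`), `order` (backbone depiction order), `cut` and
#'   `direction`.
#' @export
enumerate_sru_representations <- function(unit, backbone) {
  k <- length(backbone)
  if (k < 1L) argument_error("backbone", "empty backbone")
  if (anyDuplicated(backbone) || any(backbone < 1L | backbone > n_atoms(unit)))
    argument_error("backbone", "backbone must be distinct atom indices")
  bonded <- function(a, b) any((unit$bonds$i == a & unit$bonds$j == b) |
                               (unit$bonds$i == b & unit$bonds$j == a))
  if (k > 1L) {
    for (i in seq_len(k - 1L))
      if (!bonded(backbone[i], backbone[i + 1L]))
        argument_error("backbone", "consecutive backbone atoms must be bonded")
    for (i in seq_len(k))
      for (j in seq_len(k))
        if (j > i + 1L && !(i == 1L && j == k) && bonded(backbone[i], backbone[j]))
          argument_error("backbone", "branched or ring backbone")
    if (k > 2L && bonded(backbone[1L], backbone[k]))
      argument_error("backbone", "ring backbone")
  }
  if (k == 1L) {
    if (unit$atoms$hcount[backbone[1L]] < 2L)
      argument_error("valence", "a one-atom backbone needs two free valences")
  } else if (unit$atoms$hcount[backbone[1L]] < 1L ||
             unit$atoms$hcount[backbone[k]] < 1L) {
    argument_error("valence", "backbone ends need free valence for the repeat bond")
  }

  reps <- list()
  for (cut in seq_len(k)) {
    # cycle order b1..bk with closure bk-b1; cutting cycle bond `cut`
    # (between cyc[cut] and cyc[cut+1]) opens the unit there
    fwd <- if (cut == k) backbone else backbone[c((cut + 1L):k, seq_len(cut))]
    for (direction in c("forward", "reverse")) {
      ord <- if (direction == "forward") fwd else rev(fwd)
      g <- unit
      # close the repeat cycle, reopen at the cut
      if (k > 1L) {
        if (cut != k) {
          drop <- (g$bonds$i == backbone[cut] & g$bonds$j == backbone[cut + 1L]) |
                  (g$bonds$j == backbone[cut] & g$bonds$i == backbone[cut + 1L])
          g$bonds <- g$bonds[!drop, , drop = FALSE]
          g$bonds <- rbind(g$bonds,
                           data.frame(i = backbone[k], j = backbone[1L],
                                      order = 1L, wedge = "none",
                                      stringsAsFactors = FALSE))
        }
        g$atoms$hcount[backbone[1L]] <- g$atoms$hcount[backbone[1L]] - 1L
        g$atoms$hcount[backbone[k]] <- g$atoms$hcount[backbone[k]] - 1L
        # the cut endpoints got their valence back and give it to the caps
        g$atoms$hcount[ord[1L]] <- g$atoms$hcount[ord[1L]] + 1L
        g$atoms$hcount[ord[k]] <- g$atoms$hcount[ord[k]] + 1L
        capped <- cap_with_zz(g, c(ord[1L], ord[k]))
      } else {
        capped <- cap_with_zz(g, c(ord[1L], ord[1L]))
      }
      reps[[length(reps) + 1L]] <- list(graph = capped, order = ord,
                                        cut = cut, direction = direction)
    }
  }
  reps
}

#' Canonical representation of a repeat unit
#'
#' Computes the identifier of every representation — all must agree, since
#' they describe one polymer — and returns the representation whose own
#' capped-graph labeling realizes that identifier, together with the
#' identifier itself (dialect `1M`, `/z` layer included).
#'
#' @param reps nonempty list of representations from
#'   [enumerate_sru_representations()] (or single capped graphs).
#' @return list with `representation`, `identifier` (a `parsed_inchi`) and
#'   `identifier_string`.
#' @export
canonical_sru <- function(reps) {
  if (!length(reps)) argument_error("reps", "no representations given")
  reps <- lapply(reps, function(r) if (inherits(r, "mol_graph")) list(graph = r) else r)
  formulas <- vapply(reps, function(r) serialize_formula(hill_formula(r$graph)),
                     character(1))
  if (length(unique(formulas)) != 1L ||
      length(unique(vapply(reps, function(r) n_atoms(r$graph), integer(1)))) != 1L)
    argument_error("iso", "representations are not the same repeat unit")
  ids <- vapply(reps, function(r) identifier_string(r$graph), character(1))
  if (length(unique(ids)) != 1L)
    instability_error("sru", sprintf("representations yield %d distinct identifiers",
                                     length(unique(ids))))
  plain <- vapply(reps, function(r) canonical_labeling(r$graph)$certificate,
                  character(1))
  pick <- match(ids[1], plain)
  if (is.na(pick)) pick <- 1L
  list(representation = reps[[pick]],
       identifier = parse_inchi(ids[1]),
       identifier_string = ids[1])
}
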