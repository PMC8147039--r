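# Reference identifiers produced by the official InChI software (v1.05/v1.06
# output for picoline, a polypropylene-glycol repeat unit, an ADP-ribosyl
# fragment, two stereochemically demanding ester structures and a
# spiroketal), used as golden
# parsing data. The package's own generated identifiers use the 1M dialect
# and are validated by properties, not by string equality with these.
GOLDEN_PICOLINE <- "InChI=1S/C6H7N/c1-6-4-2-3-5-7-6/h2-5H,1H3"
GOLDEN_PPG <- "InChI=1B/C3H6OZz2/c1-3(2-5)4-6/h3H,2H2,1H3/z101-1-4(6-4,5-2)"
GOLDEN_FRAGMENT <- paste0(
  "InChI=1B/C15H22N5O13P2Zz/c16-12-7-13(18-3-17-12)20(4-19-7)14-10(23)8(21)",
  "5(31-14)1-29-34(25,26)33-35(27,28)30-2-6-9(22)11(24)15(36)32-6",
  "/h3-6,8-11,14-15,21-24H,1-2H2,(H,25,26)(H,27,28)(H2,16,17,18)",
  "/t5-,6-,8-,9-,10-,11-,14-/m1/s1")
GOLDEN_A <- paste0(
  "InChI=1S/C48H72O4/c1-44(2,3)36-26-32(27-37(30-36)45(4,5)6)42(49)51-40-20-",
  "16-34(17-21-40)48(24-14-13-15-25-48)35-18-22-41(23-19-35)52-43(50)33-28-",
  "38(46(7,8)9)31-39(29-33)47(10,11)12",
  "/h16-23,32-33,36-39H,13-15,24-31H2,1-12H3/t32?,36-,37+,38-,39-/m0/s1")
GOLDEN_B <- paste0(
  "InChI=1S/C10H10O8/c11-7(12)3-1(4(3)8(13)14)2-5(9(15)16)6(2)10(17)18",
  "/h1-6H,(H,11,12)(H,13,14)(H,15,16)(H,17,18)/t1?,3-,4+,5-,6-/m0/s1")
GOLDEN_SPIRO_105 <- "InChI=1S/C9H16O2/c1-3-7-10-9(5-1)6-2-4-8-11-9/h1-8H2"
GOLDEN_SPIRO_106 <- "InChI=1S/C9H16O2/c1-3-7-10-9(5-1)6-2-4-8-11-9/h1-8H2/t9-/m1/s1"

GOLDEN_ALL <- c(picoline = GOLDEN_PICOLINE, ppg = GOLDEN_PPG,
                fragment = GOLDEN_FRAGMENT, mol_a = GOLDEN_A, mol_b = GOLDEN_B,
                spiro105 = GOLDEN_SPIRO_105, spiro106 = GOLDEN_SPIRO_106)

picoline_graph <- function() graph_from_inchi(parse_inchi(GOLDEN_PICOLINE))

benzene_graph <- function() {
  mol_graph(rep("C", 6),
            bonds = data.frame(i = 1:6, j = c(2:6, 1),
                               order = c(2L, 1L, 2L, 1L, 2L, 1L),
                               wedge = "none"))
}

cube_graph <- function() {
  mol_graph(rep("C", 8),
            bonds = cbind(c(1, 2, 3, 4, 1, 2, 3, 4, 5, 6, 7, 8),
                          c(2, 3, 4, 1, 5, 6, 7, 8, 6, 7, 8, 5)))
}

# butan-2-ol depiction: C1(methyl)-C2(*)-C3-C4 chain with OH on C2 drawn as a
# wedge; `collinear` runs the C1-C2-C3 chain along one straight line
butanol_2d <- function(collinear = FALSE) {
  co <- if (collinear) cbind(x = c(-1, 0, 1, 2, 0), y = c(0, 0, 0, 0, 1))
  else cbind(x = c(-1, 0, 1, 2, 0.5), y = c(0.5, 0, 0.5, 0, 1))
  mol_graph(c("C", "C", "C", "C", "O"),
            bonds = data.frame(i = c(1, 2, 3, 2), j = c(2, 3, 4, 5), order = 1L,
                               wedge = c("none", "none", "none", "up")),
            coords = co)
}

# 12-membered carbocycle drawn as a regular polygon except at atom 1, whose
# two ring bonds are pulled almost straight; a wedged methyl hangs off atom 1
macrocycle_2d <- function() {
  n <- 12
  th <- 2 * pi * (0:(n - 1)) / n
  co <- cbind(x = cos(th) * 3, y = sin(th) * 3)
  co[2, ] <- co[1, ] + c(1, 0.01)
  co[n, ] <- co[1, ] - c(1, 0.012)
  co <- rbind(co, co[1, ] + c(0.05, 1))
  mol_graph(rep("C", 13),
            bonds = data.frame(i = c(1:12, 1), j = c(2:12, 1, 13), order = 1L,
                               wedge = c(rep("none", 12), "up")),
            coords = co)
}

# polypropylene-glycol repeat unit -O-CH2-CH(CH3)- with free valence at the
# backbone ends (O and the methyl-bearing carbon)
ppg_unit <- function() {
  mol_graph(c("O", "C", "C", "C"), bonds = cbind(c(1, 2, 3), c(2, 3, 4)))
}

# random linear repeat unit: backbone path of 2..4 C/O atoms plus a few
# methyl substituents; returns list(unit, backbone)
random_sru_unit <- function(seed) {
  set.seed(seed)
  k <- sample(2:4, 1)
  el <- sample(c("C", "C", "C", "O"), k, replace = TRUE)
  # an O backbone end cannot also bond a substituent and stay cappable
  bonds <- cbind(seq_len(k - 1L), 2:k)
  n <- k
  for (pos in seq_len(k)) {
    if (el[pos] == "C" && stats::runif(1) < 0.4) {
      n <- n + 1L
      el <- c(el, "C")
      bonds <- rbind(bonds, c(pos, n))
    }
  }
  list(unit = mol_graph(el, bonds = bonds), backbone = seq_len(k))
}

expect_minichi_error <- function(expr, class, code = NULL) {
  err <- tryCatch({ expr; NULL }, error = function(e) e)
  expect_true(inherits(err, class),
              label = sprintf("error of class %s was signalled", class))
  if (!is.null(code) && inherits(err, class)) expect_identical(err$code, code)
  invisible(err)
}

# all connected unlabeled graphs on up to `max_n` vertices, deduplicated with
# igraph's BLISS canonical form (independent of the package's own labeler);
# returns a list of edge matrices
enumerate_connected_graphs <- function(max_n) {
  out <- list()
  for (n in seq_len(max_n)) {
    if (n == 1L) { out[[length(out) + 1L]] <- list(n = 1L, edges = NULL); next }
    pairs <- t(utils::combn(n, 2))
    m <- nrow(pairs)
    seen <- new.env(hash = TRUE, parent = emptyenv())
    for (mask in 0:(2^m - 1)) {
      rows <- which(bitwAnd(mask, 2^(0:(m - 1))) > 0)
      if (length(rows) < n - 1L) next
      edges <- pairs[rows, , drop = FALSE]
      ig <- igraph::graph_from_edgelist(edges, directed = FALSE)
      if (igraph::vcount(ig) < n) ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
      if (!igraph::is_connected(ig)) next
      cp <- igraph::canonical_permutation(ig)$labeling
      can <- igraph::permute(ig, cp)
      e <- igraph::as_edgelist(can)
      e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
      e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
      key <- paste(n, paste(t(e), collapse = ","))
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <- list(n = n, edges = edges)
      }
    }
  }
  out
}
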