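test_that("Molfile round trip preserves atoms, bonds, charges and wedges", {
  g <- picoline_graph()
  expect_true(graph_identical(g, read_molfile(write_molfile(g))))

  gw <- butanol_2d()
  g2 <- read_molfile(write_molfile(gw))
  expect_identical(g2$bonds$wedge, gw$bonds$wedge)
  expect_true(graph_identical(gw, g2))

  gq <- mol_graph(c("C", "C", "O"), bonds = cbind(c(1, 2), c(2, 3)),
                  charge = c(0L, 0L, -1L))
  txt <- write_molfile(gq)
  expect_match(txt, "M  CHG", fixed = TRUE)
  gq2 <- read_molfile(txt)
  expect_identical(gq2$atoms$charge, c(0L, 0L, -1L))
  expect_identical(net_charge(gq2), -1L)
})

test_that("Molfile reader handles the format's edge cases", {
  # M CHG overrides the legacy charge column
  lines <- c("", "", "", "  1  0  0  0  0  0  0  0  0  0999 V2000",
             "    0.0000    0.0000    0.0000 N   0  3  0  0  0  0  0  0  0  0  0  0",
             "M  CHG  1   1  -1", "M  END")
  g <- read_molfile(lines)
  expect_identical(g$atoms$charge, -1L)

  expect_minichi_error(read_molfile(c("", "", "", "  0  0  0  0  0  0  0  0  0  0999 V2000", "M  END")),
                       "minichi_format_error", "empty")
  big <- paste0("1000  0  0  0  0  0  0  0  0  0999 V2000")
  expect_minichi_error(read_molfile(c("", "", "", big)),
                       "minichi_format_error", "v2000-limit")
  expect_minichi_error(write_molfile(mol_graph(rep("C", 1000),
                                               bonds = cbind(1:999, 2:1000))),
                       "minichi_format_error", "v2000-limit")
})

test_that("explicit hydrogens fold into heavy-atom counts", {
  lines <- c("", "", "", "  3  2  0  0  0  0  0  0  0  0999 V2000",
             "    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
             "    1.0000    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
             "   -1.0000    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
             "  1  2  1  0", "  1  3  1  0", "M  END")
  g <- read_molfile(lines)
  expect_identical(n_atoms(g), 1L)
  expect_identical(g$atoms$hcount, 2L)
  expect_identical(format(hill_formula(g)), "H2O")
})

test_that("aromatic bonds kekulize deterministically", {
  lines <- c("", "", "", "  6  6  0  0  0  0  0  0  0  0999 V2000")
  for (k in 1:6) lines <- c(lines,
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0")
  for (k in 1:6) lines <- c(lines, sprintf("%3d%3d  4  0", k, k %% 6 + 1))
  g <- read_molfile(c(lines, "M  END"))
  expect_identical(sort(g$bonds$order), c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_identical(g$atoms$hcount, rep(1L, 6))   # benzene CH each
  g2 <- read_molfile(c(lines, "M  END"))
  expect_identical(g$bonds$order, g2$bonds$order)
})

test_that("graphs reconstructed from identifiers match their layers", {
  g <- picoline_graph()
  expect_identical(n_atoms(g), 7L)
  expect_identical(nrow(g$bonds), 7L)
  expect_identical(sum(g$atoms$hcount), 7L)
  expect_identical(g$atoms$element, c(rep("C", 6), "N"))
  expect_identical(format(hill_formula(g)), "C6H7N")

  spiro <- graph_from_inchi(parse_inchi(GOLDEN_SPIRO_106))
  expect_identical(n_atoms(spiro), 11L)
  expect_identical(nrow(spiro$bonds), 12L)
  expect_identical(spiro$atoms$parity[9], "-")

  ppg <- graph_from_inchi(parse_inchi(GOLDEN_PPG))
  expect_identical(sum(ppg$atoms$element == "Zz"), 2L)
  expect_identical(format(hill_formula(ppg)), "C3H6OZz2")

  # heavy-atom count and ring count agree with the /c serialization
  for (nm in names(GOLDEN_ALL)) {
    p <- parse_inchi(GOLDEN_ALL[[nm]])
    gg <- graph_from_inchi(p)
    expect_identical(n_atoms(gg), as.integer(heavy_atom_count(p$formula)), label = nm)
    expect_identical(nrow(gg$bonds), nrow(p$connections$bonds), label = nm)
  }

  bad <- parse_inchi("InChI=1S/C2H6/c1-3/h1-2H3")
  expect_minichi_error(graph_from_inchi(bad), "minichi_reconstruct_error", "index")
})

test_that("mobile hydrogens are placed deterministically and flagged", {
  g <- graph_from_inchi(parse_inchi(GOLDEN_B))
  expect_length(g$mobile_groups, 4L)
  expect_identical(g$mobile_groups[[1]]$placed, 11L)   # lowest member gets the H
  expect_identical(sum(g$atoms$hcount), 10L)
})

test_that("permutation relabels without changing the molecule", {
  g <- picoline_graph()
  expect_true(graph_identical(g, permute(g, 1:7)))
  set.seed(11)
  for (k in 1:10) {
    perm <- sample(7)
    gp <- permute(g, perm)
    expect_identical(format(hill_formula(gp)), "C6H7N")
    expect_true(graphs_isomorphic(g, gp))
  }
  expect_minichi_error(permute(g, 1:5), "minichi_argument_error", "perm")
  # reversal gives different Molfile text but an isomorphic graph
  rev_g <- permute(g, 7:1)
  expect_false(identical(write_molfile(g), write_molfile(rev_g)))
  expect_true(graphs_isomorphic(g, rev_g))
})

test_that("the fixture generator is seeded, connected and valence-valid", {
  expect_identical(n_atoms(random_graph(1, seed = 0)), 1L)
  g1 <- random_graph(20, seed = 1); g2 <- random_graph(20, seed = 1)
  expect_true(graph_identical(g1, g2))
  for (s in 1:50) {
    n <- 5L + (s * 7L) %% 26L
    g <- random_graph(n, seed = s)
    expect_identical(n_atoms(g), n)
    deg <- integer(n)
    for (r in seq_len(nrow(g$bonds))) {
      deg[g$bonds$i[r]] <- deg[g$bonds$i[r]] + 1L
      deg[g$bonds$j[r]] <- deg[g$bonds$j[r]] + 1L
    }
    eff <- minichi:::default_valence(g$atoms$element, g$atoms$charge)
    expect_true(all(deg + g$atoms$hcount == eff),
                label = sprintf("valences hold for seed %d", s))
  }
  expect_minichi_error(random_graph(0, seed = 1), "minichi_generate_error")
})

test_that("SDF batches split on record separators", {
  txt <- paste(write_molfile(picoline_graph()), "$$$$",
               write_molfile(benzene_graph()), "$$$$", sep = "\n")
  gs <- read_sdf(txt)
  expect_length(gs, 2L)
  expect_identical(format(hill_formula(gs[[2]])), "C6H6")
})
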