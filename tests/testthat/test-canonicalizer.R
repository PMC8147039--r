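test_that("initial invariants separate atoms by element, degree, hydrogens, charge", {
  g <- picoline_graph()
  inv <- sapply(1:7, function(a) paste(initial_invariant(g, a), collapse = "|"))
  expect_identical(sum(inv == inv[7]), 1L)   # the nitrogen is alone in its cell

  benz <- benzene_graph()
  invb <- sapply(1:6, function(a) paste(initial_invariant(benz, a), collapse = "|"))
  expect_identical(length(unique(invb)), 1L) # all six CH equivalent

  ppg <- graph_from_inchi(parse_inchi(GOLDEN_PPG))
  zz <- which(ppg$atoms$element == "Zz")
  invz <- sapply(zz, function(a) paste(initial_invariant(ppg, a), collapse = "|"))
  expect_identical(length(unique(invz)), 1L) # both caps share one cell
  expect_length(zz, 2L)
})

test_that("partition refinement reaches a deterministic equitable fixed point", {
  path3 <- mol_graph(rep("C", 3), bonds = cbind(c(1, 2), c(2, 3)), hcount = 0L)
  p <- refine_partition(path3, list(1:3))
  expect_identical(lengths(p), c(2L, 1L))    # ends split from the middle
  expect_identical(p[[2]], 2L)

  benz <- benzene_graph()
  expect_identical(refine_partition(benz, list(1:6)), list(1:6))

  pico <- picoline_graph()
  p0 <- minichi:::initial_partition(pico)
  expect_identical(lengths(refine_partition(pico, p0)), rep(1L, 7))

  # refinement never merges cells and is idempotent
  g <- random_graph(15, seed = 5)
  p1 <- refine_partition(g, minichi:::initial_partition(g))
  expect_identical(refine_partition(g, p1), p1)
  expect_identical(sort(unlist(p1)), 1:15)
})

test_that("canonical labeling matches the exhaustive oracle on small graphs", {
  path3 <- mol_graph(rep("C", 3), bonds = cbind(c(1, 2), c(2, 3)))
  expect_identical(canonical_labeling(path3)$certificate,
                   brute_force_labeling(path3)$certificate)
  for (s in 1:40) {
    g <- random_graph(4 + s %% 5, seed = 900 + s)
    expect_identical(canonical_labeling(g)$certificate,
                     brute_force_labeling(g)$certificate,
                     label = sprintf("seed %d", 900 + s))
  }
  single <- mol_graph("C", hcount = 4L)
  cl <- canonical_labeling(single)
  expect_identical(cl$perm, 1L)
  expect_minichi_error(brute_force_labeling(random_graph(9, seed = 1)),
                       "minichi_argument_error", "size")
})

test_that("assembled identifiers are invariant under renumbering", {
  pico <- picoline_graph()
  ids <- vapply(1:16, function(k)
    identifier_string(permute(pico, random_permutation(7, 100 + k))),
    character(1))
  expect_identical(length(unique(ids)), 1L)
  expect_identical(ids[1], identifier_string(pico))

  expect_identical(identifier_string(mol_graph("C", hcount = 4L)),
                   "InChI=1M/CH4/h1H4")

  # two Molfiles of one molecule differing only in atom order
  m1 <- read_molfile(write_molfile(pico))
  m2 <- read_molfile(write_molfile(permute(pico, c(3, 1, 7, 2, 6, 4, 5))))
  expect_identical(identifier_string(m1), identifier_string(m2))
})

test_that("assembly round-trips through parsing (idempotence)", {
  for (s in c(3, 8, 21)) {
    g <- random_graph(6 + s, seed = s)
    id1 <- identifier_string(g)
    id2 <- identifier_string(graph_from_inchi(parse_inchi(id1)))
    expect_identical(id2, id1, label = sprintf("seed %d", s))
  }
})

test_that("identifiers carry charge and stereo layers", {
  gq <- mol_graph(c("C", "C", "O"), bonds = cbind(c(1, 2), c(2, 3)),
                  charge = c(0L, 0L, -1L))
  p <- assemble_identifier(gq)
  expect_identical(p$charge_q, -1L)
  expect_identical(p$dialect, "M")

  spiro <- graph_from_inchi(parse_inchi(GOLDEN_SPIRO_106))
  id <- identifier_string(spiro)
  expect_match(id, "/t", fixed = TRUE)
  # the stereo layer survives 16 renumberings unchanged
  ids <- vapply(1:16, function(k)
    identifier_string(permute(spiro, random_permutation(11, 300 + k))),
    character(1))
  expect_identical(length(unique(ids)), 1L)

  disconnected <- mol_graph(c("C", "C"), hcount = 4L)
  expect_minichi_error(identifier_string(disconnected),
                       "minichi_argument_error", "disconnected")
})

test_that("protonation folding conserves q + p and flags odd patterns", {
  r <- normalize_protonation(-1, 2, 10)
  expect_identical(r$q, 0L)
  expect_identical(r$p, 1L)
  expect_identical(r$h_total, 11L)
  expect_false(r$flagged)

  expect_identical(normalize_protonation(0, 0, 4),
                   list(q = 0L, p = 0L, h_total = 4L, flagged = FALSE))

  set.seed(42)
  for (k in 1:100) {
    q <- sample(-3:3, 1); p <- sample(-3:3, 1); h <- sample(0:40, 1)
    r <- normalize_protonation(q, p, h)
    expect_identical(r$q + r$p, q + p)
    if (q < 0 && p + q >= 0) expect_identical(r$q, 0L)
  }
  expect_true(normalize_protonation(2, 0, 4)$flagged)
  expect_true(normalize_protonation(-2, 1, 4)$flagged)
})
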