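test_that("neighbor_parity is the sign of the carrying permutation", {
  expect_identical(neighbor_parity(c(1, 2, 3), c(1, 2, 3)), 1L)
  expect_identical(neighbor_parity(c(1, 2, 3), c(2, 1, 3)), -1L)
  expect_identical(neighbor_parity(c(1, 2, 3), c(2, 3, 1)), 1L)   # 3-cycle, even
  expect_identical(neighbor_parity(c(4, 7, 9, 12), c(7, 4, 12, 9)), 1L)
  expect_minichi_error(neighbor_parity(c(1, 2), c(1, 3)),
                       "minichi_argument_error", "neighbors")
})

test_that("parity annotations relabel consistently", {
  ann <- parity_annotation(2L, c(1L, 3L, 5L), "+")
  expect_identical(recanonicalize_parity(ann, 1:5)$parity, "+")

  # swapping two neighbor labels flips the sign
  swap <- c(3L, 2L, 1L, 4L, 5L)
  expect_identical(recanonicalize_parity(ann, swap)$parity, "-")

  # undefined parity passes through
  unk <- parity_annotation(2L, c(1L, 3L, 5L), "?")
  expect_identical(recanonicalize_parity(unk, swap)$parity, "?")

  # perm then inverse is the identity, for random permutations
  set.seed(9)
  for (k in 1:20) {
    perm <- sample(5)
    back <- order(perm)
    r <- recanonicalize_parity(recanonicalize_parity(ann, perm), back)
    expect_identical(r$parity, ann$parity)
    expect_identical(r$ordered_neighbors, ann$ordered_neighbors)
  }
})

test_that("2D perception rejects ambiguous collinear drawings", {
  clear <- perceive_tetrahedral_2d(butanol_2d(collinear = FALSE))
  expect_length(clear, 1L)
  expect_true(clear[[1]]$parity %in% c("+", "-"))

  flat <- perceive_tetrahedral_2d(butanol_2d(collinear = TRUE))
  expect_identical(flat[[1]]$parity, "?")

  # the tolerance is a knob: a wide tolerance rejects the clear drawing too
  wide <- perceive_tetrahedral_2d(butanol_2d(FALSE), collinear_tol_deg = 60)
  expect_identical(wide[[1]]$parity, "?")
})

test_that("parity is rigid-motion invariant and flips under mirroring", {
  base <- perceive_tetrahedral_2d(butanol_2d())[[1]]$parity
  g <- butanol_2d()
  th <- 0.93
  x <- g$atoms$x * cos(th) - g$atoms$y * sin(th) + 4
  g$atoms$y <- g$atoms$x * sin(th) + g$atoms$y * cos(th) - 2
  g$atoms$x <- x
  expect_identical(perceive_tetrahedral_2d(g)[[1]]$parity, base)

  m <- butanol_2d()
  m$atoms$x <- -m$atoms$x
  expect_identical(perceive_tetrahedral_2d(m)[[1]]$parity,
                   if (base == "+") "-" else "+")
})

test_that("the loose check assigns stereo in large rings only", {
  g <- macrocycle_2d()
  strict <- perceive_tetrahedral_2d(g, loose_tsa_check = FALSE)
  expect_identical(strict[[1]]$parity, "?")

  loose <- perceive_tetrahedral_2d(g, loose_tsa_check = TRUE)
  expect_true(loose[[1]]$parity %in% c("+", "-"))

  # a ring below the threshold does not qualify
  high <- perceive_tetrahedral_2d(g, loose_tsa_check = TRUE, min_loose_ring = 20L)
  expect_identical(high[[1]]$parity, "?")

  # loose assignments are a strict superset of the strict ones
  defined <- function(anns) sum(vapply(anns, function(a) a$parity != "?", logical(1)))
  expect_gt(defined(loose), defined(strict))
})

test_that("stereo adjacent to Zz caps is disabled unless requested", {
  g <- butanol_2d()
  g$atoms$hcount[4] <- g$atoms$hcount[4]  # C4 is a chain end with 3 H
  capped <- cap_with_zz(g, c(4L, 4L))
  capped$atoms$x[6:7] <- c(2.5, 2.5); capped$atoms$y[6:7] <- c(0.6, -0.6)
  # move the wedge onto C2 still; its neighbors exclude Zz -> unaffected
  anns <- perceive_tetrahedral_2d(capped)
  expect_true(anns[[1]]$parity %in% c("+", "-"))

  # wedge a centre bonded to a cap
  gz <- mol_graph(c("C", "C", "C", "Zz"),
                  bonds = data.frame(i = c(1, 1, 1), j = c(2, 3, 4), order = 1L,
                                     wedge = c("up", "none", "none")),
                  coords = cbind(x = c(0, -1, 1, 0), y = c(0, 0.6, 0.6, -1)))
  expect_identical(perceive_tetrahedral_2d(gz)[[1]]$parity, "?")
  on <- perceive_tetrahedral_2d(gz, zz_stereo = TRUE)
  expect_true(on[[1]]$parity %in% c("+", "-"))
})

test_that("misplaced wedges are perception errors", {
  g <- butanol_2d()
  g$bonds$wedge <- c("up", "none", "none", "none")   # wedge from CH3 end
  expect_minichi_error(perceive_tetrahedral_2d(g),
                       "minichi_perception_error", "wedge")
  g2 <- butanol_2d()
  g2$atoms$x[5] <- NA_real_
  expect_minichi_error(perceive_tetrahedral_2d(g2),
                       "minichi_perception_error", "coords")
})
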