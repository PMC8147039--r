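test_that("a canonical generator is stable under 16 seeded renumberings", {
  r <- renumbering_stability(picoline_graph(), n_perms = 16L, seed = 42L,
                             molecule_id = "picoline")
  expect_identical(r$distinct_count, 1L)
  expect_identical(r$n_fail, 0L)
  expect_true(r$stable)
  expect_identical(r$seeds, 42L + 0:15)
  expect_identical(length(unique(r$digests)), 1L)
  # deterministic given the seed
  r2 <- renumbering_stability(picoline_graph(), n_perms = 16L, seed = 42L)
  expect_identical(r2$identifiers, r$identifiers)
  # the default protocol is 16 renumberings
  expect_identical(formals(renumbering_stability)$n_perms, 16L)
})

test_that("a non-canonical generator is flagged unstable", {
  r <- renumbering_stability(picoline_graph(), identifier_fn = write_molfile,
                             n_perms = 4L, seed = 1L)
  expect_gt(r$distinct_count, 1L)
  expect_false(r$stable)
  expect_false(is.na(r$first_divergent_seed))
})

test_that("generator errors are recorded as failures, not harness crashes", {
  flaky <- function(g) stop("engine exploded")
  r <- renumbering_stability(picoline_graph(), identifier_fn = flaky,
                             n_perms = 3L, seed = 1L)
  expect_identical(r$n_fail, 3L)
  expect_identical(r$distinct_count, 0L)
})

test_that("layer diffs capture the charge-fold and stereo-difference patterns", {
  a <- "InChI=1S/C3H8NO/c1-3(2)4-5/h3-4H,1-2H3/q-1/p+2"
  b <- "InChI=1S/C3H9NO/c1-3(2)4-5/h3-4H,1-2H3/p+1"
  d <- classify_pair(a, b)
  expect_true(d$q1p2_pattern)
  expect_true(d$has_p_a && d$has_q_a && d$has_p_b && !d$has_q_b)
  expect_true(d$contains_n)
  expect_false(d$contains_s)

  same <- classify_pair(GOLDEN_PICOLINE, GOLDEN_PICOLINE)
  expect_true(all(same$layer_equal))
  expect_true(same$identical_strings)
  expect_false(same$q1p2_pattern)

  spiro <- classify_pair(GOLDEN_SPIRO_105, GOLDEN_SPIRO_106)
  expect_true(spiro$t_differs)
  expect_true(spiro$layer_equal[["formula"]] && spiro$layer_equal[["c"]] &&
              spiro$layer_equal[["h"]])

  # equality flags are symmetric
  for (pair in list(c(a, b), c(GOLDEN_SPIRO_105, GOLDEN_SPIRO_106))) {
    f <- classify_pair(pair[1], pair[2])
    g <- classify_pair(pair[2], pair[1])
    expect_identical(f$layer_equal, g$layer_equal)
  }
})

test_that("cohort summaries tabulate the prose breakdown", {
  a <- "InChI=1S/C3H8NO/c1-3(2)4-5/h3-4H,1-2H3/q-1/p+2"
  b <- "InChI=1S/C3H9NO/c1-3(2)4-5/h3-4H,1-2H3/p+1"
  reports <- list(classify_pair(a, b),
                  classify_pair(GOLDEN_SPIRO_105, GOLDEN_SPIRO_106))
  cs <- cohort_summary(reports)
  expect_identical(cs$n, 2L)
  expect_identical(cs$q1p2, 1L)
  expect_identical(cs$t_differs, 1L)
  expect_identical(cs$has_p_a, 1L)
  expect_identical(cs$has_q_b, 0L)
  expect_identical(cs$contains_n, 1L)
  # every member has p on side b or not; categories partition the cohort
  expect_identical(cs$both_b + (cs$has_p_b - cs$both_b) +
                     (cs$has_q_b - cs$both_b) + cs$neither_b, cs$n)

  all_p <- replicate(5, classify_pair(b, b), simplify = FALSE)
  expect_identical(cohort_summary(all_p)$has_p_a, 5L)
  expect_minichi_error(cohort_summary(list()), "minichi_argument_error", "reports")
})

test_that("outcomes classify into the imperfection taxonomy by priority", {
  expect_identical(classify_outcome(list(success = FALSE, ids = character(0))),
                   "GEN_FAIL")
  expect_identical(classify_outcome(list(success = TRUE, ids = c("x", "y"))),
                   "INSTABILITY")
  expect_identical(classify_outcome(list(success = TRUE, ids = c("x", "x"),
                                         collision = TRUE)), "COLLISION")
  expect_identical(classify_outcome(list(success = TRUE, ids = "x",
                                         id_other_version = "y")), "VERSION_DIFF")
  expect_identical(classify_outcome(list(success = TRUE, ids = "x",
                                         id_other_version = "x")), "OK")
  # failure trumps instability
  expect_identical(classify_outcome(list(success = FALSE, ids = c("x", "y"))),
                   "GEN_FAIL")
})

test_that("batch audits detect collisions and honor the time budget", {
  graphs <- lapply(1:8, function(s) random_graph(5 + s, seed = 2500 + s))
  aud <- audit_molecules(graphs, n_perms = 4L, seed = 3L)
  expect_identical(aud$summary$gen_fail, 0L)
  expect_identical(aud$summary$instability, 0L)
  expect_identical(aud$summary$collision, 0L)
  expect_identical(nrow(aud$table), 8L)

  # a constant generator collides every pair of non-isomorphic molecules
  const_fn <- function(g) "InChI=1M/CH4/h1H4"
  two <- list(a = random_graph(5, seed = 1), b = random_graph(6, seed = 2))
  aud2 <- audit_molecules(two, identifier_fn = const_fn, n_perms = 2L, seed = 1L)
  expect_identical(aud2$summary$collision, 2L)

  # time budget expiry records a failure with reason "timeout"
  slow <- function(g) { s <- 0; for (i in 1:1e8) s <- s + i; identifier_string(g) }
  aud3 <- audit_molecules(list(m = random_graph(6, seed = 4)),
                          identifier_fn = slow, n_perms = 2L, seed = 1L,
                          timeout_ms = 100)
  expect_identical(aud3$table$category, "GEN_FAIL")
  expect_identical(aud3$table$reason, "timeout")
})

test_that("audit tables serialize to TSV and JSON", {
  graphs <- lapply(1:3, function(s) random_graph(6, seed = 2600 + s))
  aud <- audit_molecules(graphs, n_perms = 2L, seed = 5L)
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_audit(aud, tsv, js)
  tab <- utils::read.delim(tsv)
  expect_identical(nrow(tab), 3L)
  expect_identical(jsonlite::read_json(js)$instability, 0L)
  unlink(c(tsv, js))
})

test_that("identifier digests are whitespace-insensitive and 8 hex digits", {
  d1 <- identifier_digest(GOLDEN_PICOLINE)
  d2 <- identifier_digest("InChI = 1 S/C6H7N/c1-6-4-2-3-5-7-6/h2-5 H,1H3")
  expect_identical(d1, d2)
  expect_match(d1, "^[0-9a-f]{8}$")
  expect_false(identifier_digest(GOLDEN_PPG) == d1)
})
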