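test_that("reference identifiers parse and round-trip byte-identically", {
  for (nm in names(GOLDEN_ALL)) {
    p <- parse_inchi(GOLDEN_ALL[[nm]])
    expect_s3_class(p, "parsed_inchi")
    expect_identical(serialize_inchi(p), GOLDEN_ALL[[nm]], label = nm)
  }
  # typeset copies carry stray spaces; the tokenizer strips them
  spaced <- "InChI = 1 S/C6H7N/c1-6-4-2-3-5-7-6/h2-5 H,1H3"
  expect_identical(serialize_inchi(parse_inchi(spaced)), GOLDEN_PICOLINE)
  spaced_ppg <- "InChI = 1B/C3H6OZz2/c1-3(2-5)4-6/h3H,2H2,1H3/z101-1-4(6 -4, 5-2)"
  expect_identical(serialize_inchi(parse_inchi(spaced_ppg)), GOLDEN_PPG)
})

test_that("parsed layers carry the expected structure", {
  p <- parse_inchi(GOLDEN_PICOLINE)
  expect_identical(p$dialect, "S")
  expect_identical(p$formula$components[[1]]$counts, c(C = 6L, H = 7L, N = 1L))
  expect_identical(nrow(p$connections$bonds), 7L)
  expect_identical(p$connections$max_index, 7L)
  expect_identical(sum(p$hydrogens$fixed), 7L)

  ppg <- parse_inchi(GOLDEN_PPG)
  expect_identical(ppg$dialect, "B")
  expect_identical(ppg$formula$components[[1]]$counts[["Zz"]], 2L)
  expect_false(is.null(ppg$polymer))
  expect_identical(ppg$polymer$units[[1]]$kind, 101L)
  expect_identical(ppg$polymer$units[[1]]$caps[, "cap"], c(6L, 5L))

  ch4 <- parse_inchi("InChI=1S/CH4/h1H4")
  expect_null(ch4$connections)   # a single heavy atom has no /c layer
  expect_equal(hydrogen_total(ch4$hydrogens), 4)
})

test_that("formula parsing follows Hill order with Zz last", {
  f <- parse_formula("C15H22N5O13P2Zz")
  expect_identical(f$components[[1]]$counts,
                   c(C = 15L, H = 22L, N = 5L, O = 13L, P = 2L, Zz = 1L))
  expect_identical(heavy_atom_count(f), 36)
  expect_identical(parse_formula("C48H72O4")$components[[1]]$counts,
                   c(C = 48L, H = 72L, O = 4L))
  expect_identical(parse_formula("H2O")$components[[1]]$counts, c(H = 2L, O = 1L))
  # multi-component with multiplier
  f2 <- parse_formula("2H2O.Na")
  expect_length(f2$components, 2L)
  expect_identical(f2$components[[1]]$multiplier, 2L)
  expect_identical(formula_h_count(f2), 4)
  expect_minichi_error(parse_formula("C3Xx2"), "minichi_parse_error", "element")
  expect_minichi_error(parse_formula("C0H4"), "minichi_parse_error", "count")
})

test_that("connection layer is a depth-first serialization with branches and ring closures", {
  pico <- parse_connections("1-6-4-2-3-5-7-6")
  expect_identical(nrow(pico$bonds), 7L)
  expect_identical(pico$max_index, 7L)
  # cyclomatic number: bonds - atoms + 1 ring
  expect_identical(nrow(pico$bonds) - pico$max_index + 1L, 1L)
  key <- function(cl) paste(cl$bonds[, 1], cl$bonds[, 2], sep = "-")
  expect_setequal(key(pico), c("1-6", "4-6", "2-4", "2-3", "3-5", "5-7", "6-7"))

  spiro <- parse_connections("1-3-7-10-9(5-1)6-2-4-8-11-9")
  expect_identical(nrow(spiro$bonds), 12L)
  expect_identical(spiro$max_index, 11L)
  expect_identical(nrow(spiro$bonds) - spiro$max_index + 1L, 2L)

  # sibling branches separated by commas inside parentheses
  tert <- parse_connections("1-44(2,3)36")
  expect_setequal(key(tert), c("1-44", "2-44", "3-44", "36-44"))

  expect_identical(nrow(parse_connections("1-2")$bonds), 1L)
  expect_minichi_error(parse_connections("1-2-(3"), "minichi_parse_error", "paren")
  expect_minichi_error(parse_connections("1-2-1-2"), "minichi_parse_error", "dup-bond")
  expect_minichi_error(parse_connections("1-x-3"), "minichi_parse_error", "connections")
})

test_that("hydrogen layer handles shared suffixes and mobile groups", {
  h <- parse_hydrogens("2-5H,1H3")
  expect_identical(h$fixed[["1"]], 3L)
  expect_identical(sum(h$fixed), 7L)

  hb <- parse_hydrogens("1-6H,(H,11,12)(H,13,14)(H,15,16)(H,17,18)")
  expect_identical(sum(hb$fixed), 6L)
  expect_length(hb$mobile_groups, 4L)
  expect_identical(hydrogen_total(hb), 10)

  expect_identical(sum(parse_hydrogens("1-8H2")$fixed), 16L)
  # several ranges share one suffix
  hf <- parse_hydrogens("3-6,8-11,14-15,21-24H,1-2H2")
  expect_identical(sum(hf$fixed), 14L + 4L)

  expect_minichi_error(parse_hydrogens("5-2H"), "minichi_parse_error", "range")
  expect_minichi_error(parse_hydrogens("(H,11)"), "minichi_parse_error", "mobile")
})

test_that("stereo layer parses ordered parity entries", {
  st <- parse_stereo("32?,36-,37+,38-,39-")
  expect_identical(nrow(st$t_entries), 5L)
  expect_identical(sum(st$t_entries$parity == "?"), 1L)
  st2 <- parse_stereo("9-", m_text = "1", s_text = "1")
  expect_identical(st2$t_entries$idx, 9L)
  expect_identical(st2$m_flag, 1L)
  expect_null(parse_stereo(""))
  expect_minichi_error(parse_stereo("9*"), "minichi_parse_error", "parity")
  expect_minichi_error(parse_stereo("9-,3+"), "minichi_parse_error", "t-order")
})

test_that("layer bookkeeping is validated across layers", {
  # hydrogen conservation holds for every golden identifier (none carries /p)
  for (nm in names(GOLDEN_ALL)) {
    p <- parse_inchi(GOLDEN_ALL[[nm]])
    if (is.null(p$hydrogens)) next
    expect_identical(hydrogen_total(p$hydrogens), formula_h_count(p$formula),
                     label = nm)
  }
  # an /h index beyond the heavy-atom count is rejected
  expect_minichi_error(parse_inchi("InChI=1S/CH4/h2H4"),
                       "minichi_parse_error", "index")
  # layers out of canonical order are rejected
  expect_minichi_error(parse_inchi("InChI=1S/C2H6/h1-2H3/c1-2"),
                       "minichi_parse_error", "layer-order")
  expect_minichi_error(parse_inchi("NotAnInChI"), "minichi_parse_error", "prefix")
})

test_that("unknown layers are preserved verbatim", {
  s <- "InChI=1S/C2H6/c1-2/h1-2H3/i1+1/f2/r1"
  p <- parse_inchi(s)
  expect_identical(p$isotope_raw, "1+1")
  expect_identical(serialize_inchi(p), s)
})

test_that("serialization enforces the type invariants", {
  p <- parse_inchi(GOLDEN_PICOLINE)
  p$formula$components <- list()
  expect_minichi_error(serialize_inchi(p), "minichi_serialize_error", "formula")
  p2 <- parse_inchi(GOLDEN_PICOLINE)
  p2$hydrogens$components[[1]]$fixed["1"] <- 5L
  expect_minichi_error(serialize_inchi(p2), "minichi_serialize_error", "hydrogen")
})

test_that("arbitrary bytes terminate in a parse error, never a crash", {
  set.seed(20260928)
  for (k in 1:300) {
    s <- rawToChar(as.raw(sample(c(9L, 10L, 32:126), sample(0:60, 1), replace = TRUE)))
    out <- tryCatch(parse_inchi(s), error = function(e) e)
    expect_true(inherits(out, "parsed_inchi") || inherits(out, "minichi_parse_error"),
                label = sprintf("input %s handled", deparse(s)))
  }
})
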