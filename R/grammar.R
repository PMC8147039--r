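#' @title Layered identifier grammar
#' @description Parse and serialize the layered text format of the chemical
#' identifier, covering the standard (`1S`) and beta (`1B`) dialects plus the
#' package's own `1M` dialect for identifiers it generates itself. Layers
#' handled structurally: formula, `/c` connections, `/h` hydrogens, `/q`
#' charge, `/p` protons, `/b` `/t` `/m` `/s` stereo, `/i` isotopes (raw),
#' `/z` polymer units. Unrecognized layer letters are preserved verbatim.
#' @name grammar
NULL

# canonical output order of known layer letters
LAYER_ORDER <- c(c = 1L, h = 2L, q = 3L, p = 4L, b = 5L, t = 6L,
                 m = 7L, s = 8L, i = 9L, z = 10L)

# Typeset identifiers come with stray spaces ("1 S", "(6 -4, 5-2)") and
# occasionally a unicode minus; normalize before tokenizing.
normalize_identifier_text <- function(text) {
  text <- gsub("[−–]", "-", text)
  gsub("[[:space:] ]+", "", text)
}

## ---- formula layer ---------------------------------------------------------

hill_sort_symbols <- function(sym) {
  key <- ifelse(sym == "C", 0L, ifelse(sym == "H", 1L, ifelse(sym == "Zz", 3L, 2L)))
  sym[order(key, sym)]
}

new_formula_layer <- function(components) {
  structure(list(components = components), class = "formula_layer")
}

#' Parse a molecular formula layer
#'
#' Element symbols with optional counts, Hill-ordered on output (C, H, then
#' alphabetical, with the pseudo-element `Zz` sorting after all true
#' elements). `.` separates components of multi-component systems; a leading
#' integer on a component is a multiplier.
#'
#' @param text formula text, e.g. `"C3H6OZz2"`.
#' @return a `formula_layer`: a list with `components`, each holding a named
#'   integer vector `counts` (Hill order) and an integer `multiplier`.
#' @examples
#' parse_formula("C15H22N5O13P2Zz")$components[[1]]$counts
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) || !nzchar(text))
    parse_error("element", "empty formula")
  comps <- strsplit(text, ".", fixed = TRUE)[[1]]
  if (!length(comps) || any(!nzchar(comps)))
    parse_error("element", "empty formula component")
  components <- lapply(comps, function(comp) {
    mult <- 1L
    m <- regmatches(comp, regexec("^([0-9]+)", comp))[[1]]
    if (length(m)) {
      mult <- suppressWarnings(as.integer(m[2]))
      if (is.na(mult) || mult < 1) parse_error("count", "component multiplier must be >= 1")
      comp <- substring(comp, nchar(m[2]) + 1L)
    }
    rx <- gregexpr("[A-Z][a-z]?[0-9]*", comp)[[1]]
    toks <- regmatches(comp, list(rx))[[1]]
    if (sum(attr(rx, "match.length")) != nchar(comp) || !length(toks))
      parse_error("element", sprintf("cannot tokenize formula component '%s'", comp))
    sym <- sub("[0-9]*$", "", toks)
    cnt <- sub("^[A-Z][a-z]?", "", toks)
    cnt <- ifelse(nzchar(cnt), suppressWarnings(as.integer(cnt)), 1L)
    if (anyNA(cnt)) parse_error("count", "unreadable element count")
    if (any(cnt < 1)) parse_error("count", "element count must be >= 1")
    bad <- !is_known_symbol(sym)
    if (any(bad)) parse_error("element", sprintf("unknown element symbol '%s'", sym[bad][1]))
    counts <- tapply(cnt, sym, sum)
    counts <- stats::setNames(as.integer(counts), names(counts))
    counts <- counts[hill_sort_symbols(names(counts))]
    list(counts = counts, multiplier = mult)
  })
  new_formula_layer(components)
}

serialize_formula <- function(f) {
  paste(vapply(f$components, function(comp) {
    body <- paste0(names(comp$counts),
                   ifelse(comp$counts > 1L, comp$counts, ""), collapse = "")
    if (comp$multiplier > 1L) paste0(comp$multiplier, body) else body
  }, character(1)), collapse = ".")
}

#' Heavy-atom (non-hydrogen) total of a formula layer
#' @param f a `formula_layer`.
#' @return integer count over all components (multipliers applied).
#' @export
heavy_atom_count <- function(f) {
  sum(vapply(f$components, function(comp) {
    comp$multiplier * sum(comp$counts[names(comp$counts) != "H"])
  }, numeric(1)))
}

#' Hydrogen total of a formula layer
#' @param f a `formula_layer`.
#' @return integer hydrogen count (multipliers applied).
#' @export
formula_h_count <- function(f) {
  sum(vapply(f$components, function(comp) {
    comp$multiplier * sum(comp$counts[names(comp$counts) == "H"])
  }, numeric(1)))
}

## ---- connection layer ------------------------------------------------------

new_connection_layer <- function(components) {
  structure(list(components = components,
                 bonds = components[[1]]$bonds,
                 max_index = components[[1]]$max_index),
            class = "connection_layer")
}

parse_connection_component <- function(text) {
  if (!nzchar(text)) return(list(bonds = matrix(integer(0), 0, 2), max_index = 0L, raw = ""))
  rx <- gregexpr("[0-9]+|[-(),]", text)[[1]]
  toks <- regmatches(text, list(rx))[[1]]
  if (sum(attr(rx, "match.length")) != nchar(text))
    parse_error("connections", "non-numeric token in connection layer")
  cur <- NA_integer_
  stack <- integer(0)
  seen <- integer(0)
  bi <- integer(0); bj <- integer(0)
  keys <- character(0)
  expect_number <- TRUE
  for (tok in toks) {
    if (tok == "-") {
      expect_number <- TRUE
    } else if (tok == "(") {
      if (is.na(cur)) parse_error("paren", "branch opened before any atom")
      stack <- c(stack, cur)
      expect_number <- TRUE
    } else if (tok == ")") {
      if (!length(stack)) parse_error("paren", "unbalanced ')'")
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      expect_number <- FALSE
    } else if (tok == ",") {
      if (!length(stack)) parse_error("paren", "',' outside a branch")
      cur <- stack[length(stack)]
      expect_number <- TRUE
    } else {
      n <- suppressWarnings(as.integer(tok))
      if (is.na(n) || n < 1) parse_error("connections", "atom indices are positive integers")
      if (is.na(cur)) {
        cur <- n
        seen <- c(seen, n)
      } else {
        if (n == cur) parse_error("connections", "self-loop in connection layer")
        key <- paste(min(cur, n), max(cur, n))
        if (key %in% keys) parse_error("dup-bond", sprintf("bond %s listed twice", key))
        keys <- c(keys, key)
        bi <- c(bi, min(cur, n)); bj <- c(bj, max(cur, n))
        if (!(n %in% seen)) {     # first visit opens the atom
          seen <- c(seen, n)
          cur <- n
        }                         # a ring closure does not re-open the atom
      }
      expect_number <- FALSE
    }
  }
  if (length(stack)) parse_error("paren", "unbalanced '('")
  # the raw traversal text is preserved so that serialization reproduces the
  # exact depth-first rendering the identifier was written with
  list(bonds = cbind(i = bi, j = bj),
       max_index = max(c(seen, bi, bj), 0L),
       raw = text)
}

#' Parse a `/c` connection layer
#'
#' The layer is a depth-first serialization of the heavy-atom skeleton:
#' `-` joins an atom to the next token, `(` pushes the current atom, `)` pops
#' it, `,` returns to the branch point for a sibling branch, and a token whose
#' index already appeared closes a ring without re-opening that atom.
#' Components of multi-component systems are separated by `;`.
#'
#' @param text connection text, e.g. `"1-6-4-2-3-5-7-6"`.
#' @return a `connection_layer` with `bonds` (two-column integer matrix,
#'   `i < j`) and `max_index`; multi-component input is kept per component
#'   under `components` with `bonds`/`max_index` exposing the first.
#' @examples
#' parse_connections("1-3-7-10-9(5-1)6-2-4-8-11-9")$max_index
#' @export
parse_connections <- function(text) {
  comps <- strsplit(text, ";", fixed = TRUE)[[1]]
  if (!length(comps)) comps <- ""
  new_connection_layer(lapply(comps, parse_connection_component))
}

serialize_connections <- function(cl) {
  paste(vapply(cl$components, function(comp) {
    if (!is.null(comp$raw)) return(comp$raw)
    if (!nrow(comp$bonds)) return("")
    serialize_connection_component(comp$bonds, comp$max_index)
  }, character(1)), collapse = ";")
}

# Re-emit a bond set as a depth-first string; used both when echoing a parsed
# layer and when serializing a canonical labeling. The traversal starts at
# each atom in turn and the lexicographically smallest rendering wins;
# branches are expanded toward ascending neighbor labels and ring closures
# are written at the latest-visited endpoint.
serialize_connection_component <- function(bonds, max_index) {
  adj <- vector("list", max_index)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj <- lapply(adj, sort)
  present <- which(vapply(adj, length, integer(1)) > 0)
  best <- NULL
  for (start in present) {
    s <- dfs_render(adj, start)
    if (is.null(best) || s < best) best <- s
  }
  best
}

dfs_render <- function(adj, start) {
  n <- length(adj)
  visited <- logical(n)
  emitted <- new.env(hash = TRUE, parent = emptyenv())
  edge_key <- function(a, b) paste(min(a, b), max(a, b))
  render <- function(u) {
    items <- character(0)
    for (v in adj[[u]]) {
      k <- edge_key(u, v)
      if (visited[v]) {
        if (is.null(emitted[[k]])) {
          emitted[[k]] <- TRUE
          items <- c(items, as.character(v))
        }
      } else {
        emitted[[k]] <- TRUE
        visited[v] <<- TRUE
        items <- c(items, paste0(v, render(v)))
      }
    }
    k <- length(items)
    if (k == 0L) return("")
    if (k == 1L) return(paste0("-", items))
    paste0("(", paste(items[-k], collapse = ","), ")", items[k])
  }
  visited[start] <- TRUE
  paste0(start, render(start))
}

## ---- hydrogen layer --------------------------------------------------------

new_hydrogen_layer <- function(components) {
  structure(list(components = components,
                 fixed = components[[1]]$fixed,
                 mobile_groups = components[[1]]$mobile_groups),
            class = "hydrogen_layer")
}

expand_index_tokens <- function(toks, what) {
  out <- integer(0)
  for (tok in toks) {
    m <- regmatches(tok, regexec("^([0-9]+)(-([0-9]+))?$", tok))[[1]]
    if (!length(m)) parse_error(what, sprintf("bad index term '%s'", tok))
    a <- as.integer(m[2])
    b <- if (nzchar(m[4])) as.integer(m[4]) else a
    if (b < a) parse_error("range", sprintf("reversed range '%s'", tok))
    out <- c(out, a:b)
  }
  out
}

parse_hydrogen_component <- function(text) {
  if (!nzchar(text)) return(list(fixed = integer(0), mobile_groups = list()))
  mobile_groups <- list()
  rx <- gregexpr("\\(H[0-9]*,[-0-9,]+\\)", text)[[1]]
  if (rx[1] != -1L) {
    for (grp in regmatches(text, list(rx))[[1]]) {
      inner <- substr(grp, 2, nchar(grp) - 1L)
      parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
      hdig <- sub("^H", "", parts[1])
      h <- if (nzchar(hdig)) suppressWarnings(as.integer(hdig)) else 1L
      if (is.na(h) || h < 1) parse_error("mobile", "mobile group hydrogen count must be >= 1")
      atoms <- expand_index_tokens(parts[-1], "mobile")
      if (length(atoms) < 2) parse_error("mobile", "mobile group needs >= 2 member atoms")
      if (anyDuplicated(atoms)) parse_error("mobile", "duplicate atom in mobile group")
      mobile_groups[[length(mobile_groups) + 1L]] <- list(h = h, atoms = sort(atoms))
    }
    text <- gsub("\\(H[0-9]*,[-0-9,]+\\)", "", text)
  }
  if (grepl("[()]", text)) parse_error("mobile", "malformed mobile hydrogen group")
  fixed <- integer(0)
  toks <- strsplit(text, ",", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  pending <- character(0)
  for (tok in toks) {
    m <- regmatches(tok, regexec("^([0-9]+(-[0-9]+)?)(H([0-9]*))?$", tok))[[1]]
    if (!length(m)) parse_error("range", sprintf("bad fixed-hydrogen term '%s'", tok))
    pending <- c(pending, m[2])
    if (nzchar(m[4])) {
      cnt <- if (nzchar(m[5])) as.integer(m[5]) else 1L
      if (is.na(cnt) || cnt < 1) parse_error("count", "hydrogen count must be >= 1")
      idx <- expand_index_tokens(pending, "range")
      if (any(idx %in% names2int(fixed))) parse_error("range", "atom listed twice in fixed hydrogens")
      add <- stats::setNames(rep(cnt, length(idx)), idx)
      fixed <- c(fixed, add)
      pending <- character(0)
    }
  }
  if (length(pending)) parse_error("range", "fixed indices without an H suffix")
  list(fixed = fixed, mobile_groups = mobile_groups)
}

names2int <- function(x) as.integer(names(x))

#' Parse a `/h` hydrogen layer
#'
#' Fixed hydrogens are comma-separated index terms (singletons or ranges)
#' sharing a trailing `H`/`H2`/`H3`... suffix; mobile (tautomeric) groups are
#' written `(Hn,a1,a2,...)` with `n` defaulting to 1. `;` separates
#' components.
#'
#' @param text hydrogen layer text, e.g. `"2-5H,1H3"`.
#' @return a `hydrogen_layer` with `fixed` (named integer vector keyed by atom
#'   index) and `mobile_groups` (list of `h` count plus sorted member atoms).
#' @examples
#' sum(parse_hydrogens("2-5H,1H3")$fixed)
#' @export
parse_hydrogens <- function(text) {
  comps <- strsplit(text, ";", fixed = TRUE)[[1]]
  if (!length(comps)) comps <- ""
  new_hydrogen_layer(lapply(comps, parse_hydrogen_component))
}

serialize_hydrogen_component <- function(comp) {
  parts <- character(0)
  if (length(comp$fixed)) {
    idx <- names2int(comp$fixed)
    for (cnt in sort(unique(comp$fixed))) {
      ids <- sort(idx[comp$fixed == cnt])
      parts <- c(parts, paste0(compress_ranges(ids), "H", if (cnt > 1L) cnt))
    }
  }
  fixed_txt <- paste(parts, collapse = ",")
  mob_txt <- paste(vapply(comp$mobile_groups, function(gr) {
    paste0("(H", if (gr$h > 1L) gr$h, ",", paste(gr$atoms, collapse = ","), ")")
  }, character(1)), collapse = "")
  if (nzchar(fixed_txt) && nzchar(mob_txt)) paste0(fixed_txt, ",", mob_txt)
  else paste0(fixed_txt, mob_txt)
}

serialize_hydrogens <- function(hl) {
  paste(vapply(hl$components, serialize_hydrogen_component, character(1)),
        collapse = ";")
}

compress_ranges <- function(ids) {
  if (!length(ids)) return("")
  breaks <- c(0L, which(diff(ids) != 1L), length(ids))
  paste(vapply(seq_len(length(breaks) - 1L), function(k) {
    run <- ids[(breaks[k] + 1L):breaks[k + 1L]]
    if (length(run) == 1L) as.character(run) else paste0(run[1], "-", run[length(run)])
  }, character(1)), collapse = ",")
}

#' Total hydrogen count carried by a hydrogen layer
#' @param hl a `hydrogen_layer`.
#' @return integer: fixed hydrogens plus mobile-group counts, all components.
#' @export
hydrogen_total <- function(hl) {
  sum(vapply(hl$components, function(comp) {
    sum(comp$fixed) + sum(vapply(comp$mobile_groups, `[[`, integer(1), "h"))
  }, numeric(1)))
}

## ---- stereo layer ----------------------------------------------------------

#' Parse stereo layer texts
#'
#' @param t_text `/t` body: comma-separated `index` + parity (`+`, `-`, `?`);
#'   indices strictly increasing. `""` or `NULL` means absent.
#' @param m_text `/m` body (`"0"` or `"1"`) or `NULL`.
#' @param s_text `/s` body (`"1"`, `"2"`, `"3"`) or `NULL`.
#' @param b_text `/b` body, preserved raw, or `NULL`.
#' @return a `stereo_layer` (list with `t_entries` data frame, `m_flag`,
#'   `s_flag`, `b_raw`) or `NULL` when every part is absent.
#' @examples
#' parse_stereo("32?,36-,37+,38-,39-")$t_entries
#' @export
parse_stereo <- function(t_text = NULL, m_text = NULL, s_text = NULL, b_text = NULL) {
  empty <- function(x) is.null(x) || !nzchar(x)
  if (empty(t_text) && empty(m_text) && empty(s_text) && empty(b_text)) return(NULL)
  t_entries <- data.frame(idx = integer(0), parity = character(0),
                          stringsAsFactors = FALSE)
  if (!empty(t_text)) {
    toks <- strsplit(t_text, ",", fixed = TRUE)[[1]]
    idx <- integer(length(toks)); par <- character(length(toks))
    for (k in seq_along(toks)) {
      m <- regmatches(toks[k], regexec("^([0-9]+)([+?-])$", toks[k]))[[1]]
      if (!length(m)) parse_error("parity", sprintf("bad stereo entry '%s'", toks[k]))
      idx[k] <- as.integer(m[2]); par[k] <- m[3]
    }
    if (is.unsorted(idx, strictly = TRUE))
      parse_error("t-order", "stereo atom indices must be strictly increasing")
    t_entries <- data.frame(idx = idx, parity = par, stringsAsFactors = FALSE)
  }
  m_flag <- NA_integer_
  if (!empty(m_text)) {
    if (!m_text %in% c("0", "1")) parse_error("m-flag", "mirror flag must be 0 or 1")
    m_flag <- as.integer(m_text)
  }
  s_flag <- NA_integer_
  if (!empty(s_text)) {
    if (!s_text %in% c("1", "2", "3")) parse_error("s-flag", "stereo type flag must be 1, 2 or 3")
    s_flag <- as.integer(s_text)
  }
  structure(list(t_entries = t_entries, m_flag = m_flag, s_flag = s_flag,
                 b_raw = if (empty(b_text)) NA_character_ else b_text),
            class = "stereo_layer")
}

## ---- polymer layer ---------------------------------------------------------

#' Parse a `/z` polymer layer
#'
#' Each unit reads `kind-ranges(cap-backbone,cap-backbone,...)`: an integer
#' kind code (101 in all known examples), the index range(s) of the repeat
#' unit's atoms, and cap attachments pairing each cap (Zz) atom with its
#' backbone atom. Units are separated by `;`.
#'
#' @param text polymer layer body, e.g. `"101-1-4(6-4,5-2)"`.
#' @return a `polymer_layer`: list with `units`, each holding `kind`,
#'   `ranges` (two-column matrix lo/hi) and `caps` (two-column matrix
#'   cap/backbone, input order preserved).
#' @export
parse_polymer <- function(text) {
  units <- lapply(strsplit(text, ";", fixed = TRUE)[[1]], function(u) {
    m <- regmatches(u, regexec("^([0-9]+)-([-0-9,]+?)(\\(([-0-9,]*)\\))?$", u, perl = TRUE))[[1]]
    if (!length(m)) parse_error("polymer", sprintf("cannot parse polymer unit '%s'", u))
    kind <- as.integer(m[2])
    rtoks <- strsplit(m[3], ",", fixed = TRUE)[[1]]
    ranges <- t(vapply(rtoks, function(tok) {
      mm <- regmatches(tok, regexec("^([0-9]+)(-([0-9]+))?$", tok))[[1]]
      if (!length(mm)) parse_error("polymer", sprintf("bad unit range '%s'", tok))
      a <- as.integer(mm[2]); b <- if (nzchar(mm[4])) as.integer(mm[4]) else a
      if (b < a) parse_error("polymer", sprintf("reversed unit range '%s'", tok))
      c(a, b)
    }, integer(2)))
    dimnames(ranges) <- list(NULL, c("lo", "hi"))
    caps <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("cap", "backbone")))
    if (!is.na(m[5]) && nzchar(m[5])) {
      ptoks <- strsplit(m[5], ",", fixed = TRUE)[[1]]
      caps <- t(vapply(ptoks, function(tok) {
        mm <- regmatches(tok, regexec("^([0-9]+)-([0-9]+)$", tok))[[1]]
        if (!length(mm)) parse_error("polymer", sprintf("bad cap attachment '%s'", tok))
        c(as.integer(mm[2]), as.integer(mm[3]))
      }, integer(2)))
      dimnames(caps) <- list(NULL, c("cap", "backbone"))
    }
    list(kind = kind, ranges = ranges, caps = caps)
  })
  if (!length(units)) parse_error("polymer", "empty polymer layer")
  structure(list(units = units), class = "polymer_layer")
}

serialize_polymer <- function(pl) {
  paste(vapply(pl$units, function(u) {
    rtxt <- paste(apply(u$ranges, 1, function(r) {
      if (r[1] == r[2]) as.character(r[1]) else paste0(r[1], "-", r[2])
    }), collapse = ",")
    ctxt <- if (nrow(u$caps)) {
      paste0("(", paste(apply(u$caps, 1, paste, collapse = "-"), collapse = ","), ")")
    } else ""
    paste0(u$kind, "-", rtxt, ctxt)
  }, character(1)), collapse = ";")
}

## ---- whole identifier ------------------------------------------------------

new_parsed_inchi <- function(dialect, formula, connections = NULL, hydrogens = NULL,
                             charge_q = NA_integer_, protons_p = NA_integer_,
                             stereo = NULL, isotope_raw = NA_character_,
                             polymer = NULL, unknown_layers = list()) {
  structure(list(version = 1L, dialect = dialect, formula = formula,
                 connections = connections, hydrogens = hydrogens,
                 charge_q = charge_q, protons_p = protons_p,
                 stereo = stereo, isotope_raw = isotope_raw,
                 polymer = polymer, unknown_layers = unknown_layers),
            class = "parsed_inchi")
}

#' Parse a layered chemical identifier string
#'
#' Whitespace (including typesetting artifacts inside the string) is stripped
#' before tokenizing. Recognized layers are decomposed into typed objects;
#' layer letters the package does not interpret are preserved verbatim and
#' re-emitted on serialization. Any malformed input is rejected with a classed
#' `minichi_parse_error` carrying a short code — arbitrary bytes never crash
#' the parser.
#'
#' @param text identifier text beginning with `"InChI="`.
#' @return a `parsed_inchi` object.
#' @examples
#' p <- parse_inchi("InChI=1S/C6H7N/c1-6-4-2-3-5-7-6/h2-5H,1H3")
#' p$dialect
#' hydrogen_total(p$hydrogens)
#' @seealso [serialize_inchi()]
#' @export
parse_inchi <- function(text) {
  tryCatch(parse_inchi_impl(text), error = function(e) {
    if (inherits(e, "minichi_error")) stop(e)
    parse_error("internal", conditionMessage(e))
  })
}

parse_inchi_impl <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text))
    parse_error("prefix", "identifier must be a single character string")
  s <- normalize_identifier_text(text)
  if (!startsWith(s, "InChI="))
    parse_error("prefix", "identifier must begin with 'InChI='")
  body <- substring(s, nchar("InChI=") + 1L)
  m <- regmatches(body, regexec("^1([SBM])/", body))[[1]]
  if (!length(m))
    parse_error("prefix", "expected version/dialect '1S', '1B' or '1M' followed by '/'")
  dialect <- m[2]
  segs <- strsplit(substring(body, 4L), "/", fixed = TRUE)[[1]]
  if (!length(segs) || !nzchar(segs[1]))
    parse_error("element", "missing formula layer")
  formula <- parse_formula(segs[1])

  connections <- NULL; hydrogens <- NULL
  charge_q <- NA_integer_; protons_p <- NA_integer_
  t_text <- NULL; m_text <- NULL; s_text <- NULL; b_text <- NULL
  isotope_raw <- NA_character_; polymer <- NULL
  unknown_layers <- list()
  last_rank <- 0L
  for (seg in segs[-1]) {
    if (!nzchar(seg)) parse_error("layer", "empty layer")
    letter <- substr(seg, 1, 1)
    rest <- substring(seg, 2L)
    if (letter %in% names(LAYER_ORDER)) {
      rank <- LAYER_ORDER[[letter]]
      if (rank <= last_rank)
        parse_error("layer-order", sprintf("layer '/%s' out of canonical order", letter))
      last_rank <- rank
      switch(letter,
        c = { connections <- parse_connections(rest) },
        h = { hydrogens <- parse_hydrogens(rest) },
        q = { charge_q <- parse_signed_int(rest, "charge") },
        p = { protons_p <- parse_signed_int(rest, "protons") },
        b = { b_text <- rest },
        t = { t_text <- rest },
        m = { m_text <- rest },
        s = { s_text <- rest },
        i = { isotope_raw <- rest },
        z = { polymer <- parse_polymer(rest) })
    } else if (grepl("^[a-z]$", letter)) {
      unknown_layers[[length(unknown_layers) + 1L]] <- c(letter, rest)
    } else {
      parse_error("layer", sprintf("unrecognized layer '%s'", seg))
    }
  }
  stereo <- parse_stereo(t_text, m_text, s_text, b_text)
  p <- new_parsed_inchi(dialect, formula, connections, hydrogens, charge_q,
                        protons_p, stereo, isotope_raw, polymer, unknown_layers)
  validate_cross_layer(p)
  p
}

parse_signed_int <- function(text, what) {
  if (!grepl("^[+-]?[0-9]+$", text))
    parse_error(what, sprintf("bad %s layer '%s'", what, text))
  as.integer(text)
}

# every atom index referenced in /h, /t, /z must fit the molecule
validate_cross_layer <- function(p) {
  n_heavy <- heavy_atom_count(p$formula)
  max_idx <- if (!is.null(p$connections) && length(p$connections$components) == 1L)
    max(p$connections$max_index, n_heavy) else n_heavy
  single <- length(p$formula$components) == 1L &&
    p$formula$components[[1]]$multiplier == 1L
  if (!single) return(invisible(p))   # per-component index bookkeeping not enforced
  check <- function(idx, layer) {
    if (length(idx) && any(idx > max_idx))
      parse_error("index", sprintf("atom index %d in /%s exceeds %d heavy atoms",
                                   max(idx), layer, max_idx))
  }
  if (!is.null(p$hydrogens) && length(p$hydrogens$components) == 1L) {
    comp <- p$hydrogens$components[[1]]
    check(names2int(comp$fixed), "h")
    for (gr in comp$mobile_groups) check(gr$atoms, "h")
  }
  if (!is.null(p$stereo)) check(p$stereo$t_entries$idx, "t")
  if (!is.null(p$polymer)) {
    zz_n <- sum(vapply(p$formula$components, function(comp) {
      comp$multiplier * sum(comp$counts[names(comp$counts) == "Zz"])
    }, numeric(1)))
    zz_lo <- n_heavy - zz_n + 1L
    for (u in p$polymer$units) {
      check(as.vector(u$ranges), "z")
      check(as.vector(u$caps), "z")
      if (nrow(u$caps)) {
        if (any(u$caps[, "cap"] < zz_lo))
          parse_error("polymer", "cap atoms must be Zz atoms")
        inside <- vapply(u$caps[, "backbone"], function(b)
          any(b >= u$ranges[, "lo"] & b <= u$ranges[, "hi"]), logical(1))
        if (!all(inside))
          parse_error("polymer", "cap attachment outside the unit atom range")
      }
    }
  }
  invisible(p)
}

#' Serialize a parsed identifier back to text
#'
#' Layers are emitted in the fixed canonical order (formula, `/c`, `/h`,
#' `/q`, `/p`, `/b`, `/t`, `/m`, `/s`, `/i`, `/z`, then preserved unknown
#' layers) with no whitespace, so `parse_inchi(serialize_inchi(p))` is
#' structurally equal to `p` and parsing-then-serializing a well-formed
#' identifier reproduces it after whitespace normalization.
#'
#' @param p a `parsed_inchi`.
#' @return a single identifier string.
#' @export
serialize_inchi <- function(p) {
  if (!inherits(p, "parsed_inchi")) serialize_error("type", "not a parsed_inchi")
  if (is.null(p$formula) || !length(p$formula$components) ||
      !length(p$formula$components[[1]]$counts))
    serialize_error("formula", "empty molecule: formula layer is required")
  validate_for_serialization(p)
  segs <- paste0("InChI=1", p$dialect, "/", serialize_formula(p$formula))
  add <- function(letter, txt) paste0(segs, "/", letter, txt)
  if (!is.null(p$connections)) {
    ctxt <- serialize_connections(p$connections)
    if (nzchar(gsub(";", "", ctxt))) segs <- add("c", ctxt)
  }
  if (!is.null(p$hydrogens)) {
    htxt <- serialize_hydrogens(p$hydrogens)
    if (nzchar(gsub(";", "", htxt))) segs <- add("h", htxt)
  }
  if (!is.na(p$charge_q) && p$charge_q != 0L) segs <- add("q", sprintf("%+d", p$charge_q))
  if (!is.na(p$protons_p) && p$protons_p != 0L) segs <- add("p", sprintf("%+d", p$protons_p))
  if (!is.null(p$stereo)) {
    st <- p$stereo
    if (!is.na(st$b_raw)) segs <- add("b", st$b_raw)
    if (nrow(st$t_entries))
      segs <- add("t", paste0(st$t_entries$idx, st$t_entries$parity, collapse = ","))
    if (!is.na(st$m_flag)) segs <- add("m", st$m_flag)
    if (!is.na(st$s_flag)) segs <- add("s", st$s_flag)
  }
  if (!is.na(p$isotope_raw)) segs <- add("i", p$isotope_raw)
  if (!is.null(p$polymer)) segs <- add("z", serialize_polymer(p$polymer))
  for (ul in p$unknown_layers) segs <- add(ul[1], ul[2])
  segs
}

validate_for_serialization <- function(p) {
  if (!is.null(p$stereo) && nrow(p$stereo$t_entries) &&
      is.unsorted(p$stereo$t_entries$idx, strictly = TRUE))
    serialize_error("t-order", "stereo entries must be strictly increasing")
  single <- length(p$formula$components) == 1L &&
    p$formula$components[[1]]$multiplier == 1L
  if (single && !is.null(p$hydrogens) && length(p$hydrogens$components) == 1L) {
    want <- formula_h_count(p$formula) - ifelse(is.na(p$protons_p), 0L, p$protons_p)
    got <- hydrogen_total(p$hydrogens)
    if (got != want)
      serialize_error("hydrogen",
                      sprintf("hydrogen layer total %d != formula total %d (after /p)", got, want))
  }
  tryCatch(validate_cross_layer(p), error = function(e)
    serialize_error(error_code(e), conditionMessage(e)))
  invisible(p)
}

#' @export
print.parsed_inchi <- function(x, ...) {
  cat(serialize_inchi(x), "\n")
  invisible(x)
}

#' @export
format.formula_layer <- function(x, ...) serialize_formula(x)

#' @export
print.formula_layer <- function(x, ...) {
  cat(serialize_formula(x), "\n")
  invisible(x)
}
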