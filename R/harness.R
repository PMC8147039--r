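#' @title Reliability-audit harness
#' @description
#' Machinery for auditing an identifier generator the way large chemical
#' databases are audited: re-number each molecule's atoms k times with seeded
#' random permutations and demand one identifier; classify observed
#' imperfections (generation failure, collision of two molecules onto one
#' string, numbering instability, version difference); and summarize layer
#' differences between engine versions over a cohort. The generator under
#' audit is pluggable — any `function(mol_graph) -> character` — so the same
#' harness can fuzz an external tool.
#' @name harness
NULL

#' Seeded random permutation (Fisher-Yates)
#'
#' @param n permutation size.
#' @param seed integer seed; the caller's RNG state is untouched.
#' @return an integer permutation of `1..n`.
#' @export
random_permutation <- function(n, seed) {
  with_seed(seed, sample.int(n))
}

# 32-bit FNV-1a over a string, carried in doubles (R integers are 32-bit
# signed); identifiers are digested after whitespace normalization
fnv1a <- function(s) {
  h <- 2166136261
  for (b in as.integer(charToRaw(s))) {
    h <- xor32(h, b)
    h <- mulmod32(h)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
xor32 <- function(a, b) {
  al <- a %% 65536; ah <- (a - al) / 65536
  bl <- b %% 65536; bh <- (b - bl) / 65536
  bitwXor(as.integer(ah), as.integer(bh)) * 65536 +
    bitwXor(as.integer(al), as.integer(bl))
}
mulmod32 <- function(a) {
  # a * 16777619 mod 2^32 without losing double precision
  al <- a %% 65536; ah <- (a - al) / 65536
  (al * 16777619 + ((ah * 16777619) %% 65536) * 65536) %% 4294967296
}

#' Digest of an identifier string
#' @param s identifier text.
#' @return 8-hex-digit digest of the whitespace-normalized text.
#' @export
identifier_digest <- function(s) {
  s <- normalize_identifier_text(s)
  fnv1a(s)
}

#' Renumbering-stability audit of one molecule
#'
#' Applies `n_perms` seeded random renumberings to the atoms, runs the
#' identifier generator on each copy, and reports how many distinct strings
#' came back. A canonical generator yields exactly one; a distinct count
#' above one is a numbering instability. A generator error on some
#' permutation is recorded as a generation failure for that permutation, not
#' a harness crash.
#'
#' @param g a `mol_graph`.
#' @param identifier_fn `function(mol_graph) -> character`; defaults to the
#'   package's own [identifier_string()].
#' @param n_perms number of renumberings (default 16).
#' @param seed base seed; permutation `k` uses `seed + k - 1`.
#' @param molecule_id label carried into the report.
#' @return a `stability_report`: molecule id, seeds used, per-seed digests,
#'   distinct identifier count, failure count, first divergent seed.
#' @export
renumbering_stability <- function(g, identifier_fn = identifier_string,
                                  n_perms = 16L, seed = 1L,
                                  molecule_id = "molecule") {
  n <- n_atoms(g)
  seeds <- seed + seq_len(n_perms) - 1L
  ids <- character(n_perms)
  failed <- logical(n_perms)
  for (k in seq_len(n_perms)) {
    perm <- random_permutation(n, seeds[k])
    ids[k] <- tryCatch(identifier_fn(permute(g, perm)),
                       error = function(e) {
                         # a time-limit expiry belongs to the caller's budget
                         # handling, not to this per-permutation record
                         if (grepl("time limit", conditionMessage(e)))
                           stop(e)
                         NA_character_
                       })
    failed[k] <- is.na(ids[k])
  }
  ok <- ids[!failed]
  distinct <- length(unique(ok))
  first_div <- NA_integer_
  if (distinct > 1L) {
    ref <- ok[1]
    first_div <- seeds[!failed][match(TRUE, ok != ref)]
  }
  structure(list(molecule_id = molecule_id, n_perms = n_perms, seeds = seeds,
                 identifiers = ids,
                 digests = ifelse(failed, NA_character_,
                                  vapply(ifelse(failed, "", ids), identifier_digest,
                                         character(1))),
                 n_fail = sum(failed),
                 distinct_count = distinct,
                 first_divergent_seed = first_div,
                 stable = distinct == 1L && !any(failed)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %s: %d renumberings, %d distinct, %d failed%s\n",
              x$molecule_id, x$n_perms, x$distinct_count, x$n_fail,
              if (!is.na(x$first_divergent_seed))
                sprintf(", first divergent seed %d", x$first_divergent_seed) else ""))
  invisible(x)
}

## ---- layer diffs -----------------------------------------------------------

layer_texts <- function(p) {
  st <- p$stereo
  c(formula = serialize_formula(p$formula),
    c = if (!is.null(p$connections)) serialize_connections(p$connections) else NA_character_,
    h = if (!is.null(p$hydrogens)) serialize_hydrogens(p$hydrogens) else NA_character_,
    q = if (!is.na(p$charge_q)) sprintf("%+d", p$charge_q) else NA_character_,
    p = if (!is.na(p$protons_p)) sprintf("%+d", p$protons_p) else NA_character_,
    b = if (!is.null(st)) st$b_raw else NA_character_,
    t = if (!is.null(st) && nrow(st$t_entries))
      paste0(st$t_entries$idx, st$t_entries$parity, collapse = ",") else NA_character_,
    m = if (!is.null(st) && !is.na(st$m_flag)) as.character(st$m_flag) else NA_character_,
    s = if (!is.null(st) && !is.na(st$s_flag)) as.character(st$s_flag) else NA_character_,
    i = p$isotope_raw,
    z = if (!is.null(p$polymer)) serialize_polymer(p$polymer) else NA_character_)
}

METAL_SYMBOLS <- c("Na", "Zn", "Ru", "K", "Fe", "Co", "Mn", "Ni")
HALOGEN_SYMBOLS <- c("F", "Cl", "Br", "I")

formula_elements <- function(f) {
  unique(unlist(lapply(f$components, function(comp) names(comp$counts))))
}

#' Layer-by-layer comparison of two identifiers
#'
#' Computes per-layer equality flags plus the diagnostic flags used in
#' version-difference cohorts: presence of `/p` and `/q` on each side, a
#' stereo-layer difference flag, and the charge-fold pattern in which side
#' `a` carries a `/q<0` plus `/p` pair that side `b` writes as the single
#' folded `/p` layer (the classic `"/q-1/p+2"` to `"/p+1"` rewrite).
#' Element flags (N, S, P, metals, halogens) describe the molecule and are
#' taken from side `a`'s formula.
#'
#' @param a,b `parsed_inchi` objects or identifier strings.
#' @return a `diff_report`.
#' @export
classify_pair <- function(a, b) {
  if (is.character(a)) a <- parse_inchi(a)
  if (is.character(b)) b <- parse_inchi(b)
  la <- layer_texts(a); lb <- layer_texts(b)
  equal <- mapply(function(x, y) (is.na(x) && is.na(y)) || identical(x, y), la, lb)
  qa <- ifelse(is.na(a$charge_q), 0L, a$charge_q)
  qb <- ifelse(is.na(b$charge_q), 0L, b$charge_q)
  pa <- ifelse(is.na(a$protons_p), 0L, a$protons_p)
  pb <- ifelse(is.na(b$protons_p), 0L, b$protons_p)
  els <- formula_elements(a$formula)
  structure(list(
    layer_equal = equal,
    identical_strings = all(equal),
    has_p_a = !is.na(a$protons_p), has_p_b = !is.na(b$protons_p),
    has_q_a = !is.na(a$charge_q), has_q_b = !is.na(b$charge_q),
    t_differs = !all(equal[c("b", "t", "m", "s")]),
    q1p2_pattern = qa < 0L && pa + qa >= 0L && qb == 0L && pb == pa + qa &&
      !is.na(a$charge_q) && !is.na(a$protons_p),
    contains_n = "N" %in% els, contains_s = "S" %in% els,
    contains_p_element = "P" %in% els,
    contains_metal = any(METAL_SYMBOLS %in% els),
    contains_halogen = any(HALOGEN_SYMBOLS %in% els),
    charge_sign_a = sign(qa), charge_sign_b = sign(qb)),
    class = "diff_report")
}

#' Summarize a cohort of identifier diffs
#'
#' The same breakdown the version-difference tables report in prose: how
#' many members carry `/p`, `/q`, both or neither (per side), how many show
#' the charge-fold rewrite or a stereo-layer difference, element-content
#' counts and net-charge sign counts.
#'
#' @param reports nonempty list of `diff_report` objects.
#' @return a one-row `data.frame` of counts.
#' @export
cohort_summary <- function(reports) {
  if (!length(reports)) argument_error("reports", "empty cohort")
  cnt <- function(f) sum(vapply(reports, f, logical(1)))
  data.frame(
    n = length(reports),
    has_p_a = cnt(function(r) r$has_p_a), has_p_b = cnt(function(r) r$has_p_b),
    has_q_a = cnt(function(r) r$has_q_a), has_q_b = cnt(function(r) r$has_q_b),
    both_a = cnt(function(r) r$has_p_a && r$has_q_a),
    both_b = cnt(function(r) r$has_p_b && r$has_q_b),
    neither_a = cnt(function(r) !r$has_p_a && !r$has_q_a),
    neither_b = cnt(function(r) !r$has_p_b && !r$has_q_b),
    q1p2 = cnt(function(r) r$q1p2_pattern),
    t_differs = cnt(function(r) r$t_differs),
    contains_n = cnt(function(r) r$contains_n),
    contains_s = cnt(function(r) r$contains_s),
    contains_p_element = cnt(function(r) r$contains_p_element),
    contains_metal = cnt(function(r) r$contains_metal),
    contains_halogen = cnt(function(r) r$contains_halogen),
    charge_pos_a = cnt(function(r) r$charge_sign_a > 0),
    charge_neg_a = cnt(function(r) r$charge_sign_a < 0),
    charge_zero_a = cnt(function(r) r$charge_sign_a == 0))
}

#' Classify a generation attempt into the imperfection taxonomy
#'
#' Categories, in priority order: `GEN_FAIL` (no identifier came back),
#' `INSTABILITY` (renumbering produced more than one string), `COLLISION`
#' (two non-isomorphic molecules share one string), `VERSION_DIFF` (two
#' engine versions disagree on one input); `"OK"` when none applies.
#'
#' @param attempt list with logical `success`, character `ids` (identifiers
#'   over renumberings), optional logical `collision`, optional
#'   `id_other_version`.
#' @return one of `"GEN_FAIL"`, `"INSTABILITY"`, `"COLLISION"`,
#'   `"VERSION_DIFF"`, `"OK"`.
#' @export
classify_outcome <- function(attempt) {
  ids <- attempt$ids[!is.na(attempt$ids)]
  if (!isTRUE(attempt$success) || !length(ids)) return("GEN_FAIL")
  if (length(unique(ids)) > 1L) return("INSTABILITY")
  if (isTRUE(attempt$collision)) return("COLLISION")
  if (!is.null(attempt$id_other_version) &&
      !is.na(attempt$id_other_version) &&
      !identical(attempt$id_other_version, ids[1])) return("VERSION_DIFF")
  "OK"
}

#' Audit a batch of molecules end to end
#'
#' Runs [renumbering_stability()] on every molecule, then scans the batch
#' for collisions: molecules that share an identifier are checked with the
#' brute-force isomorphism oracle where feasible (pairs equal up to
#' mobile-hydrogen metadata are legitimate proton-localization mates and are
#' exempt). A per-molecule time budget can be set; on expiry the molecule is
#' recorded as a generation failure with reason `"timeout"`.
#'
#' @param graphs list of `mol_graph` objects.
#' @param identifier_fn generator under audit.
#' @param n_perms renumberings per molecule.
#' @param seed base seed; molecule `m` uses `seed + 1000 * (m - 1)`.
#' @param timeout_ms per-molecule budget in milliseconds (default none).
#' @return an `audit` object: `table` (one row per molecule), `summary`
#'   (category counts), `reports` (the stability reports).
#' @export
audit_molecules <- function(graphs, identifier_fn = identifier_string,
                            n_perms = 16L, seed = 1L, timeout_ms = Inf) {
  if (!length(graphs)) argument_error("graphs", "empty batch")
  ids <- names(graphs)
  if (is.null(ids)) ids <- sprintf("mol%03d", seq_along(graphs))
  reports <- vector("list", length(graphs))
  reasons <- character(length(graphs))
  for (m in seq_along(graphs)) {
    mseed <- seed + 1000L * (m - 1L)
    rep_m <- tryCatch({
      if (is.finite(timeout_ms)) {
        setTimeLimit(elapsed = timeout_ms / 1000, transient = TRUE)
        on.exit(setTimeLimit(elapsed = Inf), add = TRUE)
      }
      renumbering_stability(graphs[[m]], identifier_fn, n_perms = n_perms,
                            seed = mseed, molecule_id = ids[m])
    }, error = function(e) NULL)
    setTimeLimit(elapsed = Inf)
    if (is.null(rep_m)) {
      reasons[m] <- "timeout"
      rep_m <- structure(list(molecule_id = ids[m], n_perms = n_perms,
                              seeds = mseed + seq_len(n_perms) - 1L,
                              identifiers = rep(NA_character_, n_perms),
                              digests = rep(NA_character_, n_perms),
                              n_fail = n_perms, distinct_count = 0L,
                              first_divergent_seed = NA_integer_,
                              stable = FALSE),
                         class = "stability_report")
    }
    reports[[m]] <- rep_m
  }
  baseline <- vapply(reports, function(r) {
    ok <- r$identifiers[!is.na(r$identifiers)]
    if (length(ok)) ok[1] else NA_character_
  }, character(1))
  collision <- logical(length(graphs))
  for (id in unique(baseline[!is.na(baseline)])) {
    members <- which(!is.na(baseline) & baseline == id)
    if (length(members) < 2L) next
    for (x in members[-1]) {
      ref <- members[1]
      same <- if (n_atoms(graphs[[ref]]) <= 12L && n_atoms(graphs[[x]]) <= 12L)
        graphs_isomorphic(graphs[[ref]], graphs[[x]])
      else NA
      if (isFALSE(same)) { collision[ref] <- TRUE; collision[x] <- TRUE }
    }
  }
  category <- vapply(seq_along(graphs), function(m) {
    r <- reports[[m]]
    classify_outcome(list(success = r$n_fail < n_perms, ids = r$identifiers,
                          collision = collision[m]))
  }, character(1))
  table <- data.frame(molecule_id = ids,
                      n_atoms = vapply(graphs, n_atoms, integer(1)),
                      n_perms = n_perms,
                      distinct = vapply(reports, `[[`, integer(1), "distinct_count"),
                      n_fail = vapply(reports, `[[`, integer(1), "n_fail"),
                      category = category,
                      reason = reasons,
                      identifier = baseline,
                      stringsAsFactors = FALSE)
  summary <- list(n = length(graphs),
                  gen_fail = sum(category == "GEN_FAIL"),
                  instability = sum(category == "INSTABILITY"),
                  collision = sum(category == "COLLISION"),
                  ok = sum(category == "OK"))
  structure(list(table = table, summary = summary, reports = reports,
                 seed = seed), class = "audit")
}

#' @export
print.audit <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<audit> %d molecules: %d ok, %d gen-fail, %d unstable, %d collisions\n",
              s$n, s$ok, s$gen_fail, s$instability, s$collision))
  invisible(x)
}

#' Write audit results to disk
#'
#' @param audit an `audit` object.
#' @param tsv_path path for the per-molecule TSV table.
#' @param json_path path for the JSON summary.
#' @return the audit, invisibly.
#' @export
write_audit <- function(audit, tsv_path, json_path = NULL) {
  utils::write.table(audit$table, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(audit$summary, json_path, auto_unbox = TRUE)
  invisible(audit)
}
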