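# minichi

Desk-scale canonical chemical identifiers, with the reliability machinery to
prove they are canonical.

Chemical databases link records by layered identifier strings of the InChI
family. The format's central promise is canonicality: one molecule, one
string, and the string must not depend on how the atoms were numbered in the
input — a molecule with *N* heavy atoms can arrive in about *N*! equivalent
Molfiles, and all of them must serialize identically. `minichi` is a
self-contained R implementation of that contract for people who study or
audit identifier systems:

* **Grammar** — a parser/serializer for the layered text format (standard
  `1S` and beta `1B` dialects): formula, `/c` connections, `/h` hydrogens
  with tautomeric mobile groups, `/q` `/p` charge and proton layers,
  `/b /t /m /s` stereo, `/z` polymer units with `Zz` pseudo-atoms. Unknown
  layers round-trip verbatim; malformed input of any kind is rejected with a
  classed error, never a crash.
* **Molecular graphs** — Molfile V2000 / SDF I/O, reconstruction of graphs
  from identifiers, Hill formulas, a valence model with implicit hydrogens,
  and a seeded generator of connected, valence-valid fixture molecules.
* **Canonical labeler** — equitable partition refinement plus exhaustive or
  individualization search, minimizing the serialized identifier itself as
  the certificate; an independent *n*!-enumeration oracle checks it on small
  graphs. Generated identifiers carry a distinct `1M` prefix so they cannot
  impersonate official standard strings.
* **Stereo** — tetrahedral parity bookkeeping that survives renumbering, and
  2D perception with near-collinearity rejection plus a large-ring
  relaxation (the loose tetrahedral-stereo check).
* **Polymers** — structural repeat units capped with `Zz`: enumeration of
  the cut/direction representations and selection of one canonical form with
  a `/z` layer.
* **Audit harness** — seeded random-renumbering stability tests (16 by
  default), an imperfection taxonomy (generation failure / collision /
  numbering instability / version difference), layer-diff classification of
  version pairs, and cohort summaries. The generator under audit is
  pluggable, so the same harness can fuzz an external tool.

## Worked example

```r
library(minichi)

# parse a published identifier (2-methylpyridine) and inspect its layers
p <- parse_inchi("InChI=1S/C6H7N/c1-6-4-2-3-5-7-6/h2-5H,1H3")
hydrogen_total(p$hydrogens)
#> [1] 7

# rebuild the molecular graph and assemble our own canonical identifier
g <- graph_from_inchi(p)
identifier_string(g)
#> [1] "InChI=1M/C6H7N/c1-6-3-4-5-2-7-6/h2-5H,1H3"

# the contract under attack: 16 seeded renumberings, one string expected
renumbering_stability(g, n_perms = 16, seed = 42, molecule_id = "picoline")
#> <stability_report> picoline: 16 renumberings, 1 distinct, 0 failed

# a polymer repeat unit (-O-CH2-CH(CH3)-): six equivalent capped drawings,
# one canonical identifier with a /z layer
unit <- mol_graph(c("O", "C", "C", "C"), bonds = cbind(c(1, 2, 3), c(2, 3, 4)))
reps <- enumerate_sru_representations(unit, c(1, 2, 3))
length(reps)
#> [1] 6
canonical_sru(reps)$identifier_string
#> [1] "InChI=1M/C3H6OZz2/c1-3(2-4-5)6/h3H,2H2,1H3/z101-1-4(5-4,6-3)"

# the v1.06 protonation rewrite: /q-1/p+2 folds to /p+1, q+p conserved
normalize_protonation(q = -1, p = 2, h_total = 10)
#> $q [1] 0   $p [1] 1   $h_total [1] 11   $flagged [1] FALSE
```

The `1M` string for picoline differs from the official `1S` string only in
its traversal rendering — both describe the same 7-atom graph; the package
deliberately never claims byte compatibility with the official numbering and
validates its output by renumbering invariance, oracle agreement and
discrimination instead (see the vignette in `vignettes/`).

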