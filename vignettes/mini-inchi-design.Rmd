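---
title: "Canonical identifiers at desk scale: model, algorithms, and audit design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canonical identifiers at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minichi)
```

## The problem

A layered chemical identifier promises a contract: one molecule maps to one
string, and the string does not depend on how the atoms happened to be
numbered in the input file. A molecule with $N$ heavy atoms can arrive in
roughly $N!$ equivalent connection tables, and all of them must serialize to
the same text. `minichi` implements that contract end to end at desk scale —
a grammar for the layered text format, a reference canonical labeler, polymer
repeat-unit handling with `Zz` pseudo-atoms, tetrahedral parity bookkeeping
with 2D perception rules, and a fuzzing harness that audits any identifier
generator by random atom renumbering.

The package does not claim byte compatibility with the official InChI
software's canonical numbering, whose ranking algorithm is far larger than
anything reproducible here. Printed official strings are used as *parsing*
golden data; identifiers the package generates carry their own `1M` dialect
prefix precisely so they cannot impersonate standard `1S` strings, mirroring
how beta features are fenced off under the `1B` prefix. Our canonical output
is validated by properties — renumbering invariance, oracle equivalence,
discrimination — rather than by string equality with the official tool.

## The grammar

An identifier is a `/`-separated stack of layers after a version/dialect
prefix: formula, `/c` connections, `/h` hydrogens, `/q` charge, `/p`
protons, `/b /t /m /s` stereo descriptors, `/i` isotopes, `/z` polymer
units. The parser strips all whitespace first (typeset copies of identifiers
routinely pick up stray spaces), preserves unrecognized layer letters
verbatim, and turns every malformed input into a classed parse error with a
short code — a fuzzing property in the test suite feeds it random byte
strings and asserts that nothing but `parsed_inchi` or
`minichi_parse_error` ever comes out. Re-serialization emits layers in a
fixed canonical order; the `/c` layer remembers its original depth-first
rendering so that parsing and re-serializing a well-formed identifier
reproduces it byte for byte.

The `/c` grammar is a depth-first traversal: `-` extends a chain, `(` … `)`
encloses leading branches with `,` separating siblings, and a token whose
index has already been seen closes a ring without re-opening that atom. The
`/h` grammar couples index lists to shared `H`/`H2`/`H3` suffixes and keeps
tautomeric hydrogens in `(Hn,a1,a2,…)` mobile groups. The `/z` polymer layer
is parsed structurally as `kind-ranges(cap-backbone,…)`; the only kind code
exhibited in published examples is 101, which is also what we emit — other
codes are carried through opaquely, and the general multi-unit syntax is
deliberately not guessed at.

## The canonical labeler

Atoms are first partitioned by an order-free invariant: element (carbon
first, heteroatoms alphabetically, `Zz` after every true element), degree,
attached hydrogen count, formal charge. The cell order of this partition
fixes which index block each kind of atom may occupy — the same convention
the grammar's reconstruction relies on (picoline's printed string numbers
its carbons 1–6 and the nitrogen 7). The partition is then refined to the
coarsest equitable partition: cells split until any two atoms in a cell see
identical multisets of neighbor cells, with split cells keeping their
parent's position and sub-ordering by neighbor signature.

The canonical labeling is defined as the labeling, *among all labelings
consistent with that ordered refined partition*, whose serialized identifier
text is lexicographically smallest. The certificate is the very string users
see — ties in the search are broken by the same object that is published.
Two details are worth recording:

* **Why admissibility is partition-consistency.** The serialized text does
  not encode per-index elements; they are implied by the block convention.
  An unrestricted minimization over all $N!$ labelings would happily pick a
  labeling whose string reconstructs a different molecule. Consistency with
  the ordered refined partition is the weakest constraint under which the
  certificate is a complete invariant (the `/c` layer pins the adjacency,
  `/h` pins hydrogen counts, and the block structure pins elements and
  charges).
* **Why the refined partition, not just element blocks.** Equitable
  refinement is not an optional speedup here; it is part of the definition.
  A worked pentane example shows why: with only element blocks constrained,
  a flat minimization puts the methylene chain in cycle order, while any
  refinement-ordered search must keep the two methyl carbons in the lower
  index block — the two definitions disagree. Making the refined partition
  part of admissibility puts the implementation and the exhaustive oracle on
  the same footing.

The search enumerates all consistent labelings outright whenever the product
of cell factorials is at most $8! = 40\,320$ — which covers every graph the
brute-force oracle accepts — and otherwise individualizes one atom from the
first smallest non-singleton cell, re-refines, and recurses. Both strategies
are isomorphism-invariant functions of the graph, so renumbering the input
cannot change the result; that is the property the audit harness then
attacks with random permutations rather than assumes. For large symmetric
cells the individualize-and-refine branch restricts the candidate set
further than flat enumeration would (a 7-cycle relabels its atoms by
distance from the individualized atom, not in cycle order), so its winner is
canonical but not necessarily the flat minimum; at or below 8 atoms the
exhaustive branch always runs, and the oracle comparison is exact by
construction.

One serialization choice falls out of the string order: the depth-first
rendering that starts at canonical label 1 is always the lexicographic
minimum over start atoms, because every other start opens with a larger
first token and `(`, `,`, `-` all sort before digits. The renderer therefore
starts at label 1 and expands branches toward ascending labels, emitting
ring closures at the latest-visited endpoint.

`brute_force_labeling` is the independent check: it generates all $n!$
permutation rows, filters them against the ordered refined partition's index
blocks, and minimizes the same certificate by flat enumeration — no search
tree, no individualization. The test suite compares the two on every
connected unlabeled graph with up to six vertices (deduplicated with
igraph's BLISS canonical form, an implementation wholly independent of this
package) and on 500 seeded mixed-element fixtures of up to eight atoms, and
additionally asserts discrimination: non-isomorphic sweep graphs receive
distinct certificates.

## Hydrogens, charges, tautomers

Implicit hydrogens follow a fixed valence model (C 4, N 3, O 2, S 2, P 3,
halogens 1, `Zz` 1), shifted by ±1 per unit of formal charge; atoms that
exceed it keep their bonds, get no implicit hydrogens, and trigger a loud
warning rather than an error — real archives contain metals and radicals,
and a reference tool should describe them rather than refuse them. Aromatic
Molfile bonds (order 4) are kekulized by a deterministic backtracking
matching before any hydrogen filling, because the identifier's connectivity
layer is order-free but valence bookkeeping needs integral bond orders.

A `/q` charge parsed from an identifier is carried as a delocalized
graph-level charge rather than being pinned to an arbitrary atom: the
identifier does not localize charge, and inventing a position would break
the idempotence property (assembling, parsing, and re-assembling must be a
fixed point). Mobile (tautomeric) hydrogen groups are likewise carried as
metadata: their hydrogens are placed on the lowest-indexed group members for
graph bookkeeping, flagged as mobile, and re-emitted as `(Hn,…)` groups.
No tautomer *perception* is attempted — mobile groups are parsed, never
derived.

`normalize_protonation` implements the charge-fold convention for acidic
hydroxy groups at cationic heteroatom centres: the historical
`/q-1/p+2`-style pair becomes a single `/p+1` layer with the extra hydrogen
counted in the formula. The fold applies whenever $q < 0 \le p + q$ and
conserves the bookkeeping quantity $q + p$; any other nonzero-charge pattern
is returned unchanged with a review flag, because the published record does
not define the rewrite beyond that case and guessing would silently alter
molecules.

## Stereo perception

Tetrahedral parity is stored per centre relative to the centre's neighbors
in ascending index order, with an implicit hydrogen in the last slot.
Relabeling maps the neighbors, re-sorts them, and flips the parity exactly
when the re-sort is odd — a pure permutation-sign computation that the
canonical assembler reuses, so `/t` layers survive renumbering unchanged.

2D perception starts from wedge bonds. A candidate centre is rejected
(parity `?`) when any two of its neighbor bonds lie within
`collinear_tol_deg` of collinear: a straight-line chain drawing simply does
not say which side the substituents are on. The exception is the loose
check: when enabled and the centre lies in a ring of at least
`min_loose_ring` atoms (smallest ring through the centre), the parity is
computed anyway — macrocycle depictions run their chains nearly straight
while the ring as a whole fixes the geometry. The published record
quantifies neither threshold ("how straight is too straight" is posed as an
open question there), so both are explicit knobs: 3° and ring size 8 by
default, chosen as a tight tolerance that still accepts hand-drawn 120°
sketches and the smallest ring size conventionally called "large"; they are
reported in results and explicitly not claimed to match the official tool.
Parities adjacent to `Zz` caps are suppressed unless explicitly enabled,
matching the default for pseudo-atom stereochemistry. The parity itself is
the sign of the signed volume of the ordered neighbor tetrahedron after
lifting wedged neighbors out of plane, with the implicit hydrogen placed
opposite the explicit neighbors; the suite checks invariance under rigid
motions and sign flip under mirror reflection and under odd neighbor
permutations.

## Polymers

A structural repeat unit is encoded by capping the two join positions with
`Zz` pseudo-atoms. The same polymer can be cut from the chain at any
backbone bond and read in either direction — a 3-atom backbone gives six
capped drawings, and capped graphs from different cuts are *not* mutually
isomorphic (the oxygen of a glycol unit has different neighbor environments
depending on where the cut falls). They agree only after folding the caps
into a ring-closure bond. The assembler therefore treats any graph with
exactly two univalent `Zz` caps on distinct atoms as a repeat unit: it
closes the cycle, enumerates every connectivity-preserving single-edge cut
of the closed unit, computes the capped identifier for each, and keeps the
lexicographically smallest. All cut/direction representations of one unit
thus yield one identifier — the property `canonical_sru` checks before
reporting, raising an instability error if it ever fails. The `/z` layer
emitted records kind code 101, the unit's atom range, and the cap
attachments under canonical numbering. Source-based polymer encodings
(block/random/alternating) are out of scope; only the structure-based SRU
form is implemented.

## The audit harness

`renumbering_stability` applies `n_perms` seeded Fisher–Yates permutations
(default 16, the standard protocol for this kind of audit; fresh seeds per
molecule, all seeds logged) and counts distinct identifier strings; a
canonical generator yields exactly one. `audit_molecules` runs this over a
batch, then scans for collisions — molecules sharing a string are verified
with a hand-written backtracking isomorphism oracle where feasible — and
classifies each molecule into the imperfection taxonomy: generation
failure, instability, collision, version difference, in that priority
order. A generator that throws is recorded as a failure for that
permutation, never as a harness crash, and a per-molecule millisecond
budget can convert runaway cases into failures with reason `"timeout"`.
`classify_pair` and `cohort_summary` reproduce the layer-difference
bookkeeping used when two engine versions disagree: `/p` and `/q`
presence, the charge-fold pattern, stereo-layer differences, and
element-content flags.

```{r audit-example}
g <- random_graph(12, seed = 7)
renumbering_stability(g, n_perms = 16, seed = 42, molecule_id = "fixture-12")
```

## What the generator emulates — and what it does not

`random_graph` grows a random tree over C/N/O/S/P/halogens with
organic-like element weights, adds about one ring-closing bond per six
atoms, optionally charges N/P (+1) or O/S (−1) at 5% probability, and fills
the remaining valence with hydrogens; everything is a deterministic function
of the seed. This emulates the *combinatorial* difficulty of real archives —
heteroatom variety, fused rings, charges, symmetry — at 5–30 heavy atoms.
It does not emulate their chemical pathologies: no metals, no radicals, no
tautomer-rich scaffolds, no pathological stereo drawings, and nothing near
the hundred-million-molecule scale on which the official software's failure
rates are measured in parts per million. A clean bill of health from this
suite therefore demonstrates the algorithmic contract (canonicality, oracle
agreement, discrimination) on the fixture distribution, not fitness for
archive-scale deployment.

## Numerical and procedural choices

* Problem sizes in the shipped tests: 200 fixtures × 16 renumberings for
  the stability property; the full ≤6-vertex sweep (143 connected graphs)
  plus 500 ≤8-atom fixtures for oracle equivalence; 100 random (q, p)
  pairs for the conservation property. These sizes exercise every code
  path (including the individualization branch, reached above the 8!
  enumeration budget) while keeping a laptop run comfortable.
* Ties everywhere are broken by fixed rules, never by input order: cells
  sort by invariant then by neighbor signature, branches by ascending
  label, mobile groups by member list, digests by whitespace-normalized
  text.
* Degenerate stereo geometry (zero signed volume after the collinearity
  gate, e.g. opposing wedges) falls back to `?` rather than an arbitrary
  sign.
* `1M`-dialect output never emits `/m`/`/s` flags or `/b` layers; they are
  parsed and preserved for foreign strings but their generation semantics
  (mirror-image bookkeeping, double-bond stereo) are out of scope.
* Multi-component identifiers (`;`-separated layers, formula multipliers)
  are parsed and re-serialized but not reconstructed into graphs; the
  assembler refuses disconnected input rather than silently concatenating
  components.

## Known limitations

Mobile-hydrogen placement is a bookkeeping convention, not a tautomer
model; identifiers that differ only in proton localization can legitimately
coincide, and the collision scanner exempts such pairs. The valence model
is a table, not a perception engine. Canonical labeling is worst-case
exponential — acceptable and intended at desk scale, with the 8!
enumeration budget and individualization keeping realistic molecules in
milliseconds. Explicit-hydrogen Molfiles lose wedges drawn on hydrogen
bonds (with a warning). V3000 connection tables, isotope semantics,
InChIKey hashing, and CIP naming are out of scope.
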