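---
title: "Substructure pooling for extended-connectivity fingerprints: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substructure pooling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind `ecfpPool`, the design
decisions taken where the problem was genuinely open, and what the
package's tests do and do not establish. No empirical claims are made
here beyond what the test suite and `scripts/acceptance.R` themselves
compute.

## The pooling model

A compound is first mapped to its set of circular-substructure
identifiers $\varphi(\mathcal{M}) = \{\mathcal{J}_1, \ldots,
\mathcal{J}_k\}$, 32-bit integers obtained by iterated
neighbourhood hashing (below). A *pooling operator* is any set
function $\Psi : P(\mathfrak{J}) \to \{0,1\}^L$; being a set function
it is automatically invariant to the order in which substructures are
listed. The four operators differ only in how they use the training
set $\mathfrak{T}$ and the labels:

| operator     | uses $\mathfrak{T}$ | uses labels | collision-free |
|--------------|--------------------|-------------|----------------|
| `folded`     | no                 | no          | no             |
| `sort_slice` | yes                | no          | yes            |
| `filtered`   | yes                | yes         | yes            |
| `mim`        | yes                | yes         | yes            |

All selection-based operators share one transform: position $s(\mathcal{J})$
is set iff the calibrated list contains $\mathcal{J}$ and the compound
does; identifiers outside the list — including substructures never
seen in training — map to the zero vector. The folded operator instead
hashes *any* identifier, seen or unseen, onto $1..L$. This asymmetry
is intentional: selection calibrates to a region of chemical space,
folding does not.

**Tie-breaking.** The frequency order puts higher support counts
first; at equal counts the *larger* identifier value takes the earlier
rank. The same direction is used in the $\chi^2$ order of filtering
(larger p-value, then smaller identifier, is removed first) and the
mutual-information order of MIM (smaller information, then smaller
identifier, removed first). One consistent convention in all three
places makes every calibration a deterministic function of
(training set, labels, seed); it is also what distinguishes Sort &
Slice from chunk-wise slicing schemes that cannot hit an exact target
length when many substructures share a count.

**Degenerate inputs.** $L \ge m_{\mathfrak{T}}$ keeps the whole
vocabulary and zero-pads fingerprints. A constant (binarised) label
makes the $\chi^2$ ranking meaningless, so `filtered` raises an error;
`mim` only warns and falls back to the identifier order, since a zero
mutual information is still well defined. Continuous labels are
binarised at the median with ties mapped down (`> median` is class 1).
A 2×2 table with a zero margin gets $p = 1$ and zero information: a
constant feature carries no signal, not infinite signal.

## Substructure enumeration

There is no RDKit for R, so the enumeration is native: OpenBabel (via
`ChemmineOB`/`ChemmineR`) parses SMILES, fixes one canonical atom
order and one Kekulé assignment, and reports the connection table;
the package then computes, for every heavy atom and radius $0..D/2$,
a 32-bit identifier by Horner-hashing the tuple (radius, previous
identifier, sorted list of (bond code, neighbour identifier) pairs).
Base-31 arithmetic modulo $2^{32}$ keeps every intermediate below
$2^{38}$, inside exact double precision, so identifiers are
platform-independent. Identifiers therefore live in the same space
and play the same role as native Morgan identifiers, but their
numerical values are this package's own; fingerprints are not
bit-compatible with other toolkits (see Limitations).

*Standard invariants* per atom: atomic number, heavy-neighbour count,
hydrogen count, formal charge, ring membership — and a tetrahedral
chirality tag (none/@/@@ as written in the canonical SMILES) when
`useChirality = TRUE`. *Pharmacophoric invariants* are six binary
flags — H-bond donor, acceptor, negatively ionizable, positively
ionizable, aromatic, halogen — computed by simple structural rules
(e.g. donor = N/O with a hydrogen; negatively ionizable = acidic OH
adjacent to a C/S/P that double-bonds another oxygen). These rules are
deliberately plain: they seed a hashing scheme, so internal
consistency matters more than pharmacological nuance.

Aromaticity is read off OpenBabel's canonical SMILES (lowercase
atoms), and ring bonds between two aromatic atoms get a dedicated
bond code, so symmetric aromatic systems (benzene, naphthalene)
collapse to the correct number of environment classes instead of
being split by an arbitrary Kekulé choice. Ring membership is
perceived graph-theoretically (an atom or bond is in a ring iff the
bond is not a bridge). Enumeration always canonicalises first, which
makes it invariant to the input atom numbering; the test suite checks
this on renumbered SMILES pairs.

Because enumeration produces sets, per-compound multiplicities are
discarded (binary fingerprints only), and two environments that
collide on one identifier inside a compound count once. Identifiers
are treated as opaque: rare intra-molecular hash collisions are
accepted, as they are in any hashed fingerprint scheme.

## Standardisation contract

`standardizeSmiles` pins one documented behaviour (dataset sizes
depend on it, so it must not drift): reject syntactically or
chemically unparseable strings; strip isotope annotations; split
multi-fragment records, drop carbon-free fragments (counterions,
water), deduplicate identical organic fragments; neutralise atoms
where a proton can be added or removed — skipping charge-separated
groups whose direct neighbour carries the opposite charge (nitro,
N-oxides) and hydrogen-free cations (quaternary N) — and return the
OpenBabel canonical SMILES. Tetrahedral stereo-annotations are
preserved throughout, because chirality is an enumeration invariant
downstream. A record whose organic part is still several distinct
fragments is a genuine mixture: standardisation reports it joined
with `.` and `cleanCompounds` drops it, whereas a salt stripped to a
single parent survives. Duplicate canonical SMILES are collapsed to
one record chosen uniformly at random under the cleaning seed; the
surviving count is seed-independent, only the surviving identity is
not. Labels of dropped duplicates are discarded, never averaged.

## Filtering details

The non-closed check (Step 2) reconstructs an identifier's atom
environment from the enumeration trace: all atoms within graph
distance $r$ of the centre plus every bond with at least one endpoint
strictly inside radius $r$ — boundary bonds included, which is the
convention this package fixes since the alternative (induced subgraph
on the atom ball) cannot distinguish an environment from its closure.
An identifier is non-closed if another identifier with exactly the
same support has an environment isomorphic to a proper subgraph of
its own; containment is decided by a radius-nesting fast path (same
compound, same centre atom, smaller radius) and otherwise by VF2
monomorphism with atom-invariant vertex colours and bond-order edge
colours. The $\chi^2$ statistic is Pearson's on the 2×2 table, one
degree of freedom, without continuity correction — the plain variant;
with a correction the ranking of strongly dependent features would be
compressed for no benefit at these sample sizes.

All random removals (singleton order in filtering Steps 1–2, pair
collapsing in MIM Step 1, duplicate survival in cleaning) consume a
dedicated seeded generator that is saved and restored around each
call, so calibrations are reproducible and never perturb the caller's
RNG state.

## The synthetic generator

`fixtureSpec`/`generateLibrary` compose molecules as linear chains of
self-contained SMILES fragments, each attachable at both ends, so
validity is guaranteed by construction rather than by a
reject-and-retry loop. The defaults emulate the one structural fact
the pooling analysis depends on: the heavy-tailed substructure
frequency distribution of real libraries. A small common pool with
geometrically decaying weights produces the high-frequency head; a
40-fragment rare pool (one decoration per compound with probability
0.7) and the combinatorial variety of chain junctions produce the
singleton-dominated tail. At the default size ($n = 100$, $D = 4$)
over half of all substructures are singletons and ~98% occur in fewer
than half the compounds — the qualitative shape reported for real
datasets, at roughly 1/20 of their vocabulary size.

The planted signal is a thiomethyl branch `C(SC)`: sulfur occurs
nowhere else in the grammar, and as a branch its atom environment is
identical wherever the fragment sits, so the planted substructure's
support is exactly the set of planted compounds. With noiseless
labels equal to planted presence, both supervised selectors at
$L = 1$ must recover a feature column identical to the presence
column; the acceptance suite checks this on ten seeds.

What the generator does *not* emulate: drug-likeness, realistic
functional-group co-occurrence, stereochemistry, tautomerism, or
activity cliffs. Passing tests on these libraries establishes the
operators' contracts and relative behaviour in the collision regime;
they do not certify predictive performance on real assay data.

## Benchmark harness

Repeated two-fold cross-validation (three seeds by default) over the
grid (method × $L$ × $D$ × invariants), with calibration strictly on
the training fold — the test fold never reaches the calibration, which
the suite verifies by comparing against calibrating on the training
compounds enumerated alone. Splits: seeded random; stratified
(per-class shuffle, classification only — regression uses plain
random); scaffold, which groups compounds by Bemis–Murcko framework
(iterative pruning of terminal atoms; acyclic molecules share the
empty scaffold), orders groups by descending size with seeded
shuffling among equal sizes, and assigns each group greedily to the
smaller fold. Greedy balanced assignment is this package's choice; it
is reproducible and keeps folds as even as the largest scaffold group
allows.

Models: random forests (`ranger`) with library defaults, except
regression `mtry = floor(sqrt(p))` (the square-root rule) to add
randomness; single-threaded and seeded for determinism. The
five-layer MLP configuration is documented in `fitPredict` but not
runnable — it needs a deep-learning backend, which is intentionally
not a dependency of this package; random forests are the desk-scale
default. Metrics: MAE for regression, AUROC (pairwise rank statistic,
ties half-weighted) for balanced classification, AUPRC (precision
accumulated over recall steps) for imbalanced classification; a fold
whose truth contains a single class raises an error rather than a
silent NA.

Problem sizes: the test suite works at $n = 40$–$200$ compounds and
$L = 32$–$512$; the acceptance script at $n = 200$ with 300-tree
forests. These sizes keep every calibration step exact (no
approximations are introduced at any scale) while exercising the
collision regime $m_{\mathfrak{T}} \gg L$ that drives the
folded-vs-sorted comparison.

## Known limitations

- Identifier values are specific to this package's hashing scheme.
  Vocabulary sizes and frequency percentages computed on the same
  external dataset by other toolkits will differ in detail (different
  invariant encodings and collision patterns), though the
  distributional shape and all pooling behaviour carry over.
- Aromaticity/chirality annotation relies on OpenBabel's canonical
  SMILES and on SDF atom order matching SMILES token order; the parse
  asserts this alignment per molecule and degrades to
  annotation-free invariants (never misassigned ones) if it fails.
- Pharmacophoric flags are rule-based approximations, not a curated
  SMARTS feature library.
- The scaffold is the pruned framework without the exocyclic
  double-bond refinements some toolkits apply.
- Tautomer canonicalisation, stereo enumeration and 3D structure are
  out of scope throughout.
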