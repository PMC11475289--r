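---
title: "Reaction-vector de novo design: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction-vector de novo design: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

A reaction vector is a difference fingerprint over atom-pair descriptors:

$$\mathrm{ReactionVector} = \Big[\sum \mathrm{ProductVectors}\Big] -
  \Big[\sum \mathrm{ReactantVectors}\Big]$$

Each reaction component is described by counted atom pairs of two kinds. An
**AP2** couples two bonded heavy atoms through the bond order
(`X1h1p1r1-1b-X2h2p2r2`, with `b` in 1–4 and 4 meaning aromatic); an **AP3**
couples two heavy atoms at topological distance exactly two and carries no
bond information (`X1h1p1r1-2-X2h2p2r2`). Each atom is typed by its element
`X`, heavy-atom degree `h` (bonds to non-hydrogen atoms), $\pi$-electron
count `p` and ring membership count `r`. The signed difference splits into a
**negative part** (pairs lost by the reaction) and a **positive part** (pairs
gained). A new reactant is a valid substrate for a vector when it contains
the negative pairs — wholly, or partially with the remainder supplied by a
second reagent — and applying the vector removes the negative pairs from the
reactant graph and assembles the product according to the positive pairs.

`rxnvec` implements this model end to end in R: descriptor enumeration,
reaction cleaning and balancing, vector derivation with stored
reaction-centre templates, validity testing, reagent completion, product
assembly, the inside-out design loop and the passive filter cascade.
Molecular primitives with established community implementations — SMILES
parsing and sanitisation, canonicalisation, SMARTS matching,
Morgan/FeatMorgan fingerprints, Lipinski descriptors, stereoisomer
enumeration — are delegated to RDKit through a bundled Python worker that the
package starts once per session and speaks to over a local socket.

# Descriptor conventions

The atom typing leaves two quantities under-determined, fixed here as
documented conventions:

* **$\pi$ electrons (`p`).** An aromatic atom contributes 1; each
  non-aromatic double bond contributes 1 to each end and each triple bond 2,
  so cumulated systems sum (an allene centre has `p = 2`, a nitrile carbon
  `p = 2`). This follows the classic Carhart atom-pair convention that the
  descriptor family descends from. An aromatic atom carrying an exocyclic
  double bond accumulates both contributions.
* **Ring count (`r`).** The number of SSSR (smallest set of smallest rings)
  rings an atom belongs to: deterministic and cheap. A fused-ring junction
  atom has `r = 2`.
* **Canonical pair order.** A pair is stored with its two serialized atom
  descriptors in lexicographic order, so `AP(a, b)` and `AP(b, a)` are the
  same key. AP3 multiplicity counts each unordered atom pair at distance two
  once, regardless of how many two-bond paths connect it.
* Hydrogens are implicit everywhere; descriptors never include them.

# Cleaning and balancing

A reaction must carry the same heavy atoms on both sides before subtraction
makes sense. `clean_reaction()` compares heavy-atom elemental formulas and,
when one side is deficient, appends **a single byproduct molecule whose
formula matches the deficit exactly** to that side (at most one addition per
side). The default byproduct list covers the condensation and substitution
chemistry of the shipped corpus: water, the hydrogen halides, methanol,
ethanol, CO₂ and N₂, plus the boron leaving group of aryl couplings on the
application side. Reactions whose imbalance no single byproduct closes are
rejected with the formula difference. Restricting completion to one molecule
per side keeps cleaning conservative: pairs of byproducts can close almost
any small imbalance and would silently "balance" genuinely corrupt records.

# Derivation and templates

`derive_vector()` computes the signed pair difference and extracts one mapped
**transformation template** that both application directions share:

* **Core atoms** are those incident to a changed bond (present on one side
  only, or with a different order) or whose `(X, h, p, r)` descriptor,
  charge or aromaticity changes.
* **Context** is one shell of mapped neighbours. One shell makes application
  site-specific without over-restricting; it is also exactly the radius that
  the negative AP2s constrain directly.
* Each template atom records its component assignment and local descriptors
  on *both* sides, and the template stores both bond sets. Forward
  application and retrosynthetic fragmentation (`reverse_vector()`) are the
  same graph edit with the sides swapped, which guarantees the two directions
  cannot drift apart.

Atom maps are required: template extraction is ill-posed without atom
correspondence. Unmapped input is first passed through a
maximum-common-substructure mapper (exact element and bond-order matching,
with the placement chosen to maximise unclaimed coverage); reactions where
under half of a principal reactant aligns are rejected as low-confidence
rather than guessed. Byproduct atoms are completed by element pairing.
Identity and stereochemistry-only reactions derive the zero vector and are
rejected — the formalism is constitution-level, and generated structures are
flat until `enumerate_stereoisomers()` expands them.

One principal (non-byproduct) product and at most two principal reactants
are supported, which covers the bimolecular chemistry of the corpus;
reactions outside these bounds are skipped with a logged reason when
building a database.

# Application and the exactness principle

`apply_vector()` embeds each reactant-side template component into its
reactant, requiring an **exact match of element, heavy degree, $\pi$ count,
ring count, charge and aromaticity on every template atom** (core and
context), with bond orders compatible (aromatic matches aromatic). This is
stricter than matching elements only, and it is deliberate: the post-hoc
conservation check — the pair vector of products plus byproducts minus
reactants must equal the signed vector *exactly* — fails for any
shell-descriptor mismatch, because shell atoms appear in the negative AP2/AP3
pairs of the vector. Exact embedding makes the post-application discard rate
near zero instead of using the conservation check as the primary filter. A
consequence worth understanding: a vector derived from an acetic-acid
esterification does not transfer to propanoic acid, because the methyl shell
carbon `(C,1,0,0)` differs from a methylene `(C,2,0,0)`; transfer happens
between substrates whose one-shell environments coincide (e.g. propanoic to
butanoic acid, or any pair of para-substituted aroyl substrates). This
environment specificity is intrinsic to the difference-vector formalism and
is the reason production systems derive vectors from very large reaction
corpora.

After bond edits, connected components are classified: fragments consisting
exactly of the leaving template atoms must sanitise to a molecule on the
byproduct allow-list, anything else discards the application; the remaining
atoms must form exactly the expected number of principal products. Every
emitted product passes sanitisation and the exact conservation check.
Symmetric sites that produce identical edits (automorphic embeddings) are
deduplicated by their edit signature; distinct sites are all applied — no
sampling, so output is deterministic.

# The design loop

`run_design()` is the inside-out workflow:

1. **Fragment** each reference with every database vector run in reverse;
   every fragment set is verified by reassembly before use (fragmenting and
   rebuilding must regenerate the reference). Depth > 1 recursively
   fragments the fragments and extends routes in forward-synthesis order.
2. **Retrieve building blocks** per fragment: full-scan ranking by Euclidean
   distance between count FeatMorgan fingerprints (feature-typed circular
   fingerprints, radius 2, folded to 1024 counts) of fragment and library
   members. Feature typing retrieves pharmacophoric (isosteric) rather than
   strictly topological neighbours. Ties break on canonical SMILES.
3. **Reassemble** reagent combinations (ordered by total distance, capped at
   the beam width) forward through the same vectors. A candidate only exists
   if its full route replays through `apply_vector()`.
4. **Score** with the active scorers and keep the beam. Shipped scorers:
   Tanimoto similarity to the reference (binary Morgan, radius 2, 1024
   bits) and a property-window scorer (MW and logP bands); any user model
   plugs in through the `new_scorer()` contract (named, direction-annotated,
   deterministic, order-preserving).
5. **Passive cascade** at the end: reactive-group conversion, re-detection,
   exclusion substructures, Lipinski.

**Aggregation.** Sequential scoring describes which objectives act at each
step, not how they combine into one ranking; the package uses a weighted sum
of min–max-normalised objective scores (equal weights by default) because it
yields the simplest reproducible total order. A Pareto non-domination mode is
available behind a config flag for users who prefer rank-based selection.
A constant objective normalises to 0.5 so it neither dominates nor vanishes.

**Fragment shuffling.** Fingerprint-ranked replacement can recombine
fragments into arrangements that permute the reference's substituent
topology. An optional attachment-consistency check (a replacement must embed
the template component of the fragment it replaces) mitigates this; it is
off by default so that the default behaviour reflects the plain workflow,
and because route replay already guarantees synthesisability, not topology.

**Determinism.** All loops are ordered and all ties break on canonical
SMILES; the only randomness is optional library subsampling under the
configured seed. Two runs with the same config and seed are byte-identical.
A wider beam's final set is a superset of a narrower beam's when caps do not
bind.

# Filters and calculators

* **Lipinski:** violations of MW > 500, logP > 5, donors > 5,
  acceptors > 10 are counted; candidates violating more than one rule are
  removed (threshold configurable).
* **Reactive-group conversion:** reactive SMARTS hits are routed through
  single-reactant functional-transformation vectors (hydrolyses, reductions)
  and re-checked; still-reactive structures are discarded, converted ones
  are flagged for re-scoring. The shipped SMARTS lists are a minimal curated
  set in editable YAML — published curation efforts (Hann, Brenk, PAINS,
  ZINC) are the intended sources for production lists, which users supply as
  files rather than the package vendoring them.
* **Stereo enumeration** assigns all unspecified stereocentres and double
  bond geometries up to a cap, leaving assigned centres untouched; the count
  never exceeds $2^k$ for $k$ unspecified centres.
* **Permeability.** The two-compartment PAMPA model gives
  $P_{app} = \frac{V_D V_A}{V_D + V_A}\cdot\frac{1}{At}\cdot(-\ln(1-r))$ in
  cm s⁻¹. Membrane retention is implemented exactly as conventionally
  printed, $\%MR = [r - (D + A)]/Eq \times 100$; note this form mixes the
  dimensionless ratio $r$ with concentration sums, so it is *not* invariant
  under a common rescaling of $D$, $A$ and $Eq$ — callers must supply inputs
  in one consistent unit system. The implementation follows the printed
  convention literally and documents the caveat rather than silently
  "fixing" it.

# The fixture generator

`make_toy_reactions()` instantiates four coupling templates — esterification,
amide coupling, benzylic N-alkylation and biaryl (Suzuki-type) coupling —
over seeded substituent alphabets, producing 44 balanced, atom-mapped
records by default, each with its recorded product. `make_toy_reagents()`
enumerates the matching acids, alcohols, amines, boronic acids, benzylic
chlorides and aryl bromides (plus aldehyde/ketone/aniline decoys that match
no coupling template), ~150 unique structures closed over every fixture
reactant. `make_transform_reactions()` supplies the single-reactant
functional transformations for the conversion filter. The same seed yields
byte-identical fixtures; changing it changes the substituents but not the
template structure.

The corpus emulates clean, single-product, fully mapped bimolecular
chemistry with monofunctional reagents and small substituent diversity. It
does **not** emulate: noisy or wrongly mapped patent records, multi-product
or low-yield reactions, protecting-group chemistry, reagents with competing
reactive sites, or the scale of real reaction corpora (tens of thousands of
vectors, hundreds of thousands of reagents). Tests passing on this corpus
therefore demonstrate correctness of the formalism and the engine, not
robustness to real-world reaction-data curation problems.

Reference inhibitors and designed candidates used in similarity checks are
vendored as SMILES constants transcribed once from their published IUPAC
names (recorded alongside the constants); there is no runtime
name-to-structure dependency.

# Numerical and size choices

* Pair counts are exact integers; no tolerance enters the formalism
  anywhere. Similarity values are compared after round-half-even rounding to
  two decimals where two-decimal reference values are involved.
* Template embedding uses backtracking over candidate lists ordered by
  constrainedness; templates have ≤ ~12 atoms and fixture molecules ≤ ~50,
  so exhaustive enumeration of embeddings is cheap and exact.
* The test suite runs the full 44-reaction round-trip, a 100-molecule AP3
  brute-force oracle comparison, and design runs with beams of 5–50 over the
  ~150-reagent library; the complete suite finishes in about a minute on one
  CPU. These sizes were chosen as the smallest that exercise every template
  family and both match kinds (full and partial).

# Known limitations

* Vectors do not account for reactive groups outside the reaction centre;
  the passive cascade flags and converts offenders after generation rather
  than preventing their formation.
* At most two principal reactant components per vector; reactions beyond
  that are skipped at derivation with a logged count.
* The auto-mapper is a deliberate heuristic for convenience on clean
  reactions; production use should supply atom-mapped input.
* The partial-match rule attributes missing negative pairs to exactly one
  absent component; overlapping negative-pair ownership between two absent
  components is out of scope.
* Retrosynthetic fragmentation only inverts reactions present in the vector
  database — it is reaction-precedent-driven, not a general retrosynthesis
  engine.
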