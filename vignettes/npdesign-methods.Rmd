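---
title: "Reaction-driven de novo design with npdesign: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction-driven de novo design with npdesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npdesign)
```

# The problem

Natural products such as Marinopyrrole A are potent bioactive molecules, but
their intricate, halogen-dense architectures make them painful to synthesize
and to optimize. One productive strategy is *scaffold hopping by forward
synthesis*: grow new molecules from purchasable building blocks through
reactions a bench chemist would actually run, keep only those that resemble
the natural-product template in pharmacophore space, and let the construction
process itself hand you a synthesis route. `npdesign` implements that whole
loop offline: a molecular core, a virtual reaction engine, a deterministic
breadth-first designer, CATS topological-pharmacophore ranking, Murcko
scaffold statistics, and a cascaded self-organizing-map (SOM) target
predictor with empirical p-values.

Everything below states what the package computes, which knobs matter, and
where a design decision was genuinely open — together with the choice made
and why.

# The molecular core

The whole toolkit runs on a purpose-built molecular data model (the R
ecosystem available to this package ships no cheminformatics toolkit, so
parsing, canonicalization and matching are implemented here from first
principles):

* **Structures** are read from a SMILES dialect: organic subset, bracket
  atoms with charge / hydrogen-count / atom-map, ring closures, branches,
  and bond symbols `- = # :`. Stereo marks are accepted and ignored — the
  design method is deliberately constitution-only (the template is used as
  a 2-D chemical graph, nothing else).
* **Aromaticity** uses one declared perception model everywhere: lowercase
  input atoms are aromatic; Kekulé 5- and 6-rings whose members are
  sp2-eligible and whose pi count is six are promoted. `C1=CC=CC=C1` and
  `c1ccccc1` therefore share one canonical key, which matters because CATS
  typing, substructure matching and scaffold identity all condition on
  aromatic flags.
* **Canonical keys** come from Weisfeiler–Lehman refinement of atom
  invariants (element, aromaticity, degree, H count, charge, ring
  membership), with residual ties broken by promoting each tied atom in
  turn and keeping the lexicographically smallest output string — an
  invariant procedure by construction, property-tested against random atom
  renumberings.
* **Hydrogens** are implicit, filled from standard valences (with the usual
  hypervalent states for P and S and charge-shifted targets for N/O/P/S/B).
  Explicit bracket counts are preserved; SD files carry non-default counts
  through the V2000 valence field.
* **Exact masses** use IUPAC monoisotopic masses of the most abundant
  isotopes to at least six decimals and subtract one electron mass
  (0.000549 Da) per unit of positive charge. This is what makes the
  `[M+H]+` values land on published high-resolution MS "calculated for"
  figures at four decimals; without the electron correction the last digit
  is wrong.

Deliberate non-goals: salt stripping, tautomer canonicalization (inputs are
taken as drawn), 3-D geometry, stereochemistry.

One format caveat: SD output writes aromatic bonds with order 4 rather than
a Kekulé assignment. The package reads its own files back losslessly;
third-party tools that insist on Kekulé SD blocks will complain.

# The reaction engine

A reaction scheme is a mapped substructure transform over one to three
reactant slots, written in a small SMIRKS-like dialect:

```
[C:1](=O)[C:2]=O.[CH1:3]=O>>[c:1]1[c:2][nH][c:3]n1
```

Mapped atoms carry their out-of-pattern substituents into the product;
unmapped reactant-pattern atoms are leaving atoms; unmapped product-pattern
atoms are introduced fresh (here the two ring nitrogens supplied by the
ammonia source of a Debus–Radziszewski imidazole condensation). Hydrogen
counts on product atoms are recomputed from the final valence unless stated
explicitly (`[nH]`). In query patterns, a bracket hydrogen count is an exact
requirement (`[CH1]=O` hits aldehydes, not ketones) and an unwritten one is
unconstrained.

Design choices worth knowing:

* The ammonia source of the imidazole condensation is modeled as implicit —
  it is a fixed reagent, not a combinatorial slot, so the scheme has arity
  two (diketone + aldehyde).
* Esterification is modeled from the carboxylic acid and the phenol, the
  chemistry actually run at the bench (carbodiimide coupling); an
  acyl-halide writing of the same strategic bond is equivalent from the
  graph-rewrite point of view.
* Protecting-group logistics (silyl protection / fluoride deprotection used
  for the glycolate ester) are not modeled: virtual chemistry tracks the
  strategic bond only.
* Every bundled scheme carries a worked example and is self-tested at load:
  a registry that cannot reproduce its own example refuses to load, naming
  the scheme. The registry is a plain TSV and user-extensible.

# The designer

`run_design()` performs a deterministic breadth-first construction bounded
at **three linear steps**: at each depth, every surviving intermediate is
combined — under every scheme slot it can fill — with every applicable
building block in the remaining slots. Products are deduplicated by
canonical key; the top `beam_width` by fitness seed the next depth; products
of *all* depths are candidates (a one-step product can be a final design).
Tie-breaking is total everywhere (fitness, then route length, then canonical
key), so a configuration plus seed reproduces the identical run; the seeded
sampling of `n_start` start fragments is the only stochastic element.

* **Fitness.** The upstream method used a molecular graph-similarity kernel
  whose exact form lives in cited prior software and is not recoverable
  from the text. The default here is `1 / (1 + d_CATS)` — monotone in the
  same pharmacophore distance used for final ranking, so construction and
  ranking optimize one coherent objective — with a pluggable
  `kernel` argument for any alternative symmetric similarity.
* **Beam width** defaults to 50 per depth; the original's pruning schedule
  is unstated. `beam_width = Inf` disables pruning, and in that mode the
  search is property-tested for set equality against an independent
  exhaustive enumerator on toy libraries.
* `n_start` defaults to 200, the published number of randomly selected
  start fragments; it is capped at the library size, which matters for the
  bundled desk-scale fixtures (tens of blocks, standing in for a 25,563
  block commercial catalog that is not redistributable).

# CATS ranking

The CATS descriptor counts pairs of potential pharmacophore points (donor,
acceptor, positively/negatively ionizable, lipophilic) binned by
shortest-path topological distance 0–9: 15 unordered type pairs × 10 bins =
150 dimensions. The typing rule table is explicit, versioned and dumpable
(`cats_rule_table()`); an atom may carry several types (a phenol oxygen is
donor *and* acceptor). Same-atom pairs count once per unordered type pair at
distance zero; pairs farther than nine bonds are discarded.

Three scaling variants are implemented — `raw` counts, `occurrence` scaling
(each pair-type block divided by the summed incidence of its two types,
0/0 → 0), and `size` normalization (division by heavy-atom count) — with
Euclidean (default) or Manhattan distance. Mixed scalings refuse to compare.

**Calibration status, stated plainly.** The published workflow reports
template–design distances of 1.45 and 1.70 and a top-100 threshold of
"< 1.8" from its own CATS implementation, whose exact scaling/metric
parameterization is in cited software rather than in the text. None of the
six documented variants here reproduces those printed values; the default
(occurrence + Euclidean) yields 1.08 and 1.09 for the same two pairs — the
right order of magnitude and the same ordering (design 2 closer than design
3), but not the printed figures, and the acceptance suite reports exactly
that sweep rather than forcing agreement. Distances from this package are
internally consistent and rank-meaningful; absolute values are not
comparable to the published ones.

# Scaffold analysis

`murcko_scaffold()` uses the Bemis–Murcko convention: iteratively peel
terminal atoms to leave ring systems plus inter-ring linkers, then re-attach
atoms held by a double or triple bond (an exocyclic carbonyl is part of the
scaffold; a dangling vinyl side chain is not). A pyrrole-type aromatic N–H
keeps its hydrogen — it was never part of a side chain — while hydrogens at
pruning cut points are recomputed. Acyclic molecules map to the empty
scaffold. The **generic framework** additionally abstracts every atom to
carbon and every bond to single. Both keys are reported, because published
"unique scaffold" counts are ambiguous between the two conventions; either
grouping is reproducible from `scaffold_stats()`, which also exposes both
unique counts as attributes.

# Target prediction

The predictor emulates a cascade of two SOMs over complementary descriptor
spaces, trained on an annotated reference library:

* **Physicochemical space** (8 properties: monoisotopic mass, additive logP
  estimate, donor/acceptor counts, ring count, rotatable bonds, additive
  polar-surface estimate, heavy atoms), z-scaled against the reference
  library. The logP and TPSA contributions are crude declared
  atom-additive estimates — adequate for similarity *mapping*, not property
  prediction; the proprietary descriptor sets of the original software are
  not reproducible and are not imitated beyond this.
* **Pharmacophore space**: this package's 150-dimensional CATS vectors,
  z-scaled.

Both grids are classical online SOMs (seeded initialization from data rows,
per-sample best-matching-unit updates, exponentially decaying learning rate
and Gaussian lattice neighborhood). Defaults: 8×8 lattice, 50 epochs,
`alpha0 = 0.5` — grid sizes and schedules for the original tool are
unpublished, so these are this package's documented choices, exposed as
configuration.

A query maps to its best-matching unit plus the 8-connected lattice
neighborhood (radius is a knob) in each grid; each target is scored by its
frequency among co-located reference compounds, and the consensus is the
arithmetic mean of the two per-grid frequencies — symmetric, so the cascade
is order-invariant. Significance is empirical: `n_background` reference
compounds are resampled with a seed and
`p = (1 + #{background >= observed}) / (1 + n_background)`, the add-one
permutation estimator, so `p > 0` always and the p-values are valid
(conservative) under resampling from the reference population. Predictions
with `p <= 0.05` are reported by default; the filter can be disabled.

# What the synthetic fixtures emulate — and what they do not

`generate_blocks()` emits a seeded library that always contains the six
literature building blocks behind the published routes (the
bis(2-chlorophenyl) diketone, the two salicyl/vanillin-type aldehydes, and
the three ester acids) plus decoys in five categories (diketones,
aldehydes, acids, phenols, inert) allocated to requested fractions by
largest remainder. It stands in for a commercial catalog in *kind* —
functional-group composition and reactivity under the bundled schemes — but
not in scale or diversity: published endpoint counts (802 designs, 334
scaffolds, the 34% lophine share) arise from the 25,563-block catalog and
58-scheme set and are explicitly not reproducible at desk scale. A green
design test here establishes the method's contracts (route bound,
determinism, oracle equivalence, recovery of the published routes), not the
published census numbers.

`generate_reference_library()` plants `n_reference_targets` classes of
compounds assembled on a carbon backbone, each class shifted along one
substituent axis (methoxy, hydroxyl, chloro, phenyl, dimethylamino) by the
`separation` effect size, with chain length as a shared noise dimension and
substituent-count noise of sd 0.25 (so at separation 2.0 an off-axis
impurity is rare and an on-axis signal is essentially never absent). At
separation 2.0 held-out compounds recover their planted target as top
prediction in over 90% of cases; at separation 0 the classes are
exchangeable by construction and recovery collapses to near the 20% chance
level. The generator provides identifiability, not biology: real
target-annotated libraries are noisier in every respect, and the published
prediction counts for specific compounds depend on proprietary reference
data this package does not imitate.

# Numerical and degenerate-input choices

* Distances beyond nine bonds fall outside the CATS histogram by
  definition; disconnected inputs are rejected at parse time.
* A single heavy atom yields a CATS vector with exactly one non-zero entry
  (its same-atom pair at distance 0); occurrence scaling's 0/0 blocks are 0.
* `select_top()` applies a *strict* `<` cutoff, matching "distances below
  threshold" semantics; ties anywhere are resolved by canonical key.
* Route comparison prefers higher fitness, then fewer steps.
* The empirical-p estimator never returns 0 or values above 1.
* Floating-point fitness ties use a 1e-12 tolerance before falling through
  to the route-length and key tie-breaks.

# Known limitations

* Canonicalization cost is worst-case exponential in symmetry-class size;
  for drug-sized molecules it is milliseconds, but adversarial highly
  symmetric graphs (large fullerene-like cages) would be slow.
* Aromaticity perception covers benzenoid and common five/six-membered
  heteroaromatic rings; exotic systems (azulenes, mesoionics) are taken as
  drawn in Kekulé form.
* The SMIRKS-like engine supports the slot arity (1–3) and rewrite
  semantics the bundled chemistry needs; it is not a general reaction
  language (no recursive SMARTS, no logical atom queries beyond element /
  aromaticity / charge / exact-H).
* CATS absolute distances are implementation-specific (see the calibration
  note above); use them to rank, not to compare across toolkits.
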