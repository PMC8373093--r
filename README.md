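# npdesign

Reaction-driven de novo design of natural-product-inspired small molecules,
as an offline, fully tested R toolkit.

Complex natural products (the working example throughout is **Marinopyrrole
A**, a densely chlorinated bipyrrole) are attractive bioactivity templates
but poor synthetic starting points. `npdesign` implements the
*forward-synthetic* answer: grow candidate molecules from purchasable
building blocks through virtual reaction schemes, so that every design is
born with a synthesis route, then rank the candidates by topological
pharmacophore similarity to the template, summarise their scaffolds, and
annotate them with putative macromolecular targets.

The package provides:

* a **molecular core** — SMILES parsing, a single declared aromaticity
  model, canonical keys (Weisfeiler–Lehman refinement with invariant
  tie-breaking), implicit hydrogens, molecular formulas, monoisotopic
  masses (`mass = Σ count·m_isotope − charge·m_e`, matching printed HRMS
  "calculated for" values at 4 decimals), TSV and SD file I/O;
* a **reaction engine** — schemes as mapped substructure transforms
  (`[C:1](=O)[C:2]=O.[CH1:3]=O>>[c:1]1[c:2][nH][c:3]n1` is the bundled
  Debus–Radziszewski imidazole condensation), each registry entry
  self-tested at load against its own worked example;
* a **designer** — deterministic breadth-first construction bounded at
  three linear steps, seeded start-fragment sampling, beam pruning with
  total tie-breaking, exhaustive mode for oracle testing;
* **CATS ranking** — 150-dimensional pharmacophore correlation vectors
  (5 point types, 15 unordered pairs × topological distance bins 0–9),
  three documented scaling variants, Euclidean/Manhattan distance

  `entry(pair, d) = #{(i,j) : types match, shortest-path(i,j) = d}`, then scaling;

* **scaffold analysis** — Bemis–Murcko scaffolds and generic carbon
  frameworks, frequency tables, substructure counting;
* **target prediction** — a cascade of two self-organizing maps
  (physicochemical and pharmacophore descriptor spaces), neighborhood
  consensus scoring and empirical p-values
  `p = (1 + #{background ≥ observed}) / (1 + n_background)`, reported at
  `p ≤ 0.05`;
* **seeded fixture generators** and an end-to-end `pipeline()` with a
  reproducibility manifest, so everything runs and is tested offline.

## Worked example

Rebuild the published two-step route to the best-ranking design — imidazole
condensation of the bis(2-chlorophenyl) diketone with the allyl
salicylaldehyde, then esterification of the phenol with glycolic acid — and
rank the products against the template:

```r
library(npdesign)

cpds    <- marinopyrrole_compounds()          # bundled structures
tpl     <- cpds$mol[[which(cpds$id == "marinopyrrole_A")]]
blocks  <- cpds[grepl("block_|acid", cpds$id), ]
schemes <- load_scheme_registry()

cfg <- design_config(tpl, blocks, schemes,
                     n_start = 6, beam_width = Inf, seed = 1)
res <- run_design(cfg)
tidy(res)
```

```
#> # A tibble: 14 x 6
#>     rank canonical_key               fitness cats_distance n_steps route_schemes
#>    <int> <chr>                         <dbl>         <dbl>   <int> <chr>
#>  1     1 CCOc1cc(ccc1OC(CO)=O)-c2nc~   0.493          1.03       2 dr>ester
#>  2     2 C=CCc1cccc(-c2nc(-c3ccccc3~   0.481          1.08       2 dr>ester
#>  3     3 CCOc1cc(ccc1OC(COC)=O)-c2n~   0.479          1.09       2 dr>ester
#>  4     4 CCOc1cc(ccc1O)-c2nc(-c3ccc~   0.478          1.09       1 dr
#>  ...
```

Row 2 is the published glycolate ester design (CATS distance 1.08 to the
template under this package's default parameterization, reached by
`dr > ester`, i.e. imidazole condensation then esterification); row 4 is its
one-step companion from the vanillin-type aldehyde. Exact masses confirm
identities against printed HRMS values:

```r
d2 <- res$mol[[2]]
format(molecular_formula(d2, protonate = 1))
#> [1] "C26H21Cl2N2O3+"
round(monoisotopic_mass(molecular_formula(d2, protonate = 1)), 4)
#> [1] 479.0924
```

Scaffold statistics show the design set collapsing onto the
2,4,5-triphenylimidazole (lophine) family:

```r
scaffold_stats(res)
#> # A tibble: 2 x 4
#>   scaffold_key                                framework_key           n fraction
#> 1 c1ccc(cc1)-c2c(-c3ccccc3)[nH]c(-c4ccccc4)n2 C1CCC(CC1)C2CC(C3C~     8    0.571
#> 2 c1ccccc1                                    C1CCCCC1                6    0.429
```

An end-to-end demonstration (fixture generation, design, ranking, scaffold
table, target prediction, manifest) is one call:

```r
npdesign_demo("demo_run", seed = 7)
```

or from a shell: `Rscript scripts/npdesign.R demo --out-dir demo_run`.
`scripts/npdesign.R` also exposes `run`, `rank`, `react`, `scaffolds`,
`subsearch`, `predict` and `fixtures` subcommands over the same functions.

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline quantities from
scratch — it rebuilds the two selected designs through the reaction engine
(condensation, then esterification) and measures their CATS pharmacophore
distances to the Marinopyrrole A template under the documented default
parameterization (occurrence scaling, Euclidean metric):

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The CATS parameterization used by the original workflow is not restated in
its text; the methods vignette documents the variant sweep and why absolute
distances from different CATS implementations are not interchangeable.

## Package layout

* `R/` — implementation; `inst/schemes/` — the transform registry;
  `inst/extdata/` — bundled structures (template, designs, building blocks).
* `tests/testthat/` — unit, property and acceptance suites with independent
  oracles (Floyd–Warshall pair counting, exhaustive route enumeration).
* `vignettes/npdesign-methods.Rmd` — the models, every tunable parameter
  with its default and rationale, what the synthetic fixtures do and do not
  establish, numerical choices, known limitations.
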