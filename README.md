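# rxnvec

Reaction-vector-based de novo molecular design in R.

`rxnvec` is for computational and medicinal chemists who want generated
molecules to come with synthetic precedent. Instead of hand-coded
transformation rules or free-form generative models, structural changes are
driven by **reaction vectors** derived automatically from known reactions:
each reaction is encoded as the signed difference of atom-pair descriptor
counts between its product and reactant sides,

```
ReactionVector = [ Σ ProductVectors ] − [ Σ ReactantVectors ]
```

Two descriptor kinds enter the vectors: **AP2** (`X1h1p1r1-1b-X2h2p2r2`, two
bonded heavy atoms with the bond order `b`, 4 = aromatic) and **AP3**
(`X1h1p1r1-2-X2h2p2r2`, two atoms at topological distance two, no bond
information), each atom typed by element, heavy-atom degree, π-electron
count and ring membership. Pairs with negative counts are what the reaction
*loses*; positive counts are what it *gains*. A vector applies to a new
reactant if the reactant contains the negative pairs (wholly, or partially
with a second reagent supplying the rest); application fragments the
reactant along the stored reaction-centre template and assembles the product
according to the positive pairs, and every emitted product must reproduce
the signed difference exactly.

On top of the structure generator sits an **inside-out design loop**:
reference ligands are fragmented retrosynthetically with the same vectors
run in reverse, similar building blocks are retrieved for each fragment
(count FeatMorgan fingerprints, radius 2, 1024 counts, Euclidean distance),
and candidates are reassembled forward under multi-objective scoring,
finishing with a passive cascade of reactive-group conversion, substructure
exclusion and Lipinski filters. Every candidate carries a synthetic route
that replays step by step through the generator.

The package also ships Morgan-fingerprint Tanimoto similarity, stereoisomer
enumeration for the flat generated structures, and PAMPA apparent
permeability / membrane retention calculators.

## Requirements and installation

R (≥ 4.1) with the tidyverse core packages, plus a `python` on the PATH that
can `import rdkit` — molecular primitives (SMILES parsing, SMARTS, Morgan
fingerprints, descriptors) run through a bundled RDKit worker started once
per session. All reaction-vector logic is implemented in R.

```sh
R CMD INSTALL .
# test
Rscript -e 'testthat::test_dir("tests/testthat", package = "rxnvec", load_package = "installed")'
```

## Worked example

Derive a vector from one mapped esterification and apply it:

```r
library(rxnvec)

rxn <- "[CH3:6][C:1](=[O:2])[OH:3].[OH:4][CH3:5]>>[CH3:6][C:1](=[O:2])[O:4][CH3:5].[OH2:3]"
rv <- derive_vector(parse_reaction(rxn, id = "esterification"))
rv
#> <rxn_vector> esterification
#>   negative pairs: 4 (4 distinct)
#>   positive pairs: 5 (5 distinct)
#>   reactant components: 2

as.data.frame(rv$negative)
#>           pair count
#> 1 C100-11-O100     1      # the alcohol C–O bond pair, lost
#> 2  C100-2-O100     1
#> 3 C310-11-O100     1      # the acid C–OH bond pair, lost
#> 4  O100-2-O110     1

apply_vector(rv, list("CC(=O)O", "CO"))
#> # A tibble: 1 × 5
#>   product  byproducts vector_id      reactants site
#> 1 COC(C)=O <chr [1]>  esterification <chr [2]> add:2_6:1;del:2_4
```

The product is methyl acetate with water as the recognised leaving
fragment, and the emitted row has already passed the exact signed-pair
conservation check.

Run the inside-out design loop on the bundled toy corpus (44 balanced,
atom-mapped reactions over four coupling templates and a ~150-reagent
library):

```r
rxns <- make_toy_reactions()
db   <- build_vector_db(setNames(rxns$reaction, rxns$id))
lib  <- make_toy_reagents()

ref <- rxns$product[rxns$template == "amide_coupling"][2]   # "O=C(CC1CC1)NCc1ccc(F)cc1"
des <- run_design(c(parp_like = ref), db, lib,
                  config = design_config(beam_width = 25, k_building_blocks = 6,
                                         max_final_products = 10))
des
#> <rxn_design> 6 candidates from 1 reference(s)
#>   reference stage               n
#> 1 parp_like fragment_sets       3
#> 2 parp_like generated           6
#> ...
#> 7 parp_like emitted             6

head(tidy(des)[, c("structure", "score_similarity", "total")], 5)
#>   structure                score_similarity total
#> 1 O=C(CC1CC1)NCc1ccc(F)cc1            1     1      # the reference, rebuilt from library reagents
#> 2 CC(C)CC(=O)NCc1ccc(F)cc1            0.553 0.553
#> 3 CCCCC(=O)NCc1ccc(F)cc1              0.538 0.538
#> 4 CCCCCC(=O)NCc1ccc(F)cc1             0.525 0.525
#> 5 COCCCC(=O)NCc1ccc(F)cc1             0.5   0.5
```

The attrition table reports how many structures each stage kept; `tidy()`
returns the candidate tibble, `glance()` a one-row summary, `autoplot()`
per-objective score distributions, and `export_routes()` the step-by-step
synthetic routes, each of which replays to its candidate via
`replay_route()`.

Similarity and permeability utilities:

```r
tanimoto_similarity("CCO", "CCN")         # binary Morgan r2/1024: 0.3333
papp(v_d = 0.15, v_a = 0.3, area = 0.3,
     time = 18000, r = 0.5)               # 1.284e-05 cm/s
```

A thin command-line front end is installed under `inst/scripts/rxnvec`
(`build-vectors`, `design`, `filter`, `similarity`, `fixtures`).

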