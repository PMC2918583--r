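# compartnet

Compartmentalization of genome-scale metabolic networks in R.

A literature-based metabolic reconstruction typically links reactions to
enzymes but says nothing about *where* in the cell each reaction happens.
`compartnet` turns such a network into a compartmentalized model across
eight sub-cellular locations — extracellular (E), nucleus (N), cytosol (C),
endoplasmic reticulum (ER), Golgi apparatus (GA), peroxisome (X), lysosome
(L) and mitochondrion (M) — plus an `U` ("uncertain") placeholder, and then
repairs the inevitably patchy result by network-structure analysis. It is
aimed at systems biologists building or refining compartmentalized
genome-scale models.

## What it does

1. **Protein localization.** Cellular-component ontology annotations are
   backtracked along `is_a`/`part_of` edges to the eight top-level
   locations (plasma-membrane annotations map to the cytosol); keyword
   annotations complement them. A protein with conflicting sources keeps
   *all* locations; an unresolvable protein gets `{U}`.
2. **Reaction localization and relationship typing.** A reaction's
   location set is the union of its enzymes' locations. Each
   protein–reaction–location relationship is typed: `a` single enzyme,
   `b` several enzymes in identical locations, `c` enzymes in disjoint
   locations ("complementary proteins"), `d` overlapping-but-unequal.
   Type-`c` groups can be resolved against a curated verdict, deactivating
   the wrong links.
3. **Gap and IRLR analysis.** For every (pathway, compartment) the
   reactions located there form a graph linked by shared *main*
   metabolites (currency metabolites such as ATP or H2O are ignored; an
   edge requires that the metabolite can flow from one reaction to the
   other). A *gap* is a reaction outside the compartment whose main
   metabolites touch two separate connected components — an auto-fillable
   missing reaction–location relationship when the reaction is uncertain,
   an evidence-gated one otherwise. An *IRLR* (isolated reaction–location
   relationship) is a one-node component; a rule cascade decides whether
   it is kept (curated evidence, or a single-location single-reaction
   enzyme) or removed.
4. **Curation edits.** Literature-derived revisions are applied as
   declarative, citation-bearing edit records with a full audit trail.
5. **Transport inference.** Remaining `{U}` reactions move to the cytosol;
   transports are imported from a confidence-scored reference list
   (score 3 = direct evidence, accepted if the metabolite exists; score 2
   accepted only if the metabolite occurs in both compartments; lower
   scores ignored) and inferred for *dead-end* metabolites (only produced,
   only consumed, or sole participants in a compartment) with the cytosol
   as bridging compartment.
6. **Validation.** `find_path()` searches shortest cross-compartment
   routes (conversions within a compartment, transports between them) to
   check that key syntheses are feasible in the finished model.

A synthetic-network generator (`simulate_network()`) plants gaps, IRLRs
and dead ends with a verified ground truth, so the whole pipeline is
testable without any external database.

## Worked example

```r
library(compartnet)

net <- demo_gap_network()    # 7-reaction chain, R6's enzyme unannotated
build_pathway_graph(net, "demo", "M")
#> <pathway_graph> demo @ M: 6 reactions, 4 edges, 2 components

gaps <- identify_gaps(net)
gaps[, c("reaction", "compartment", "component_a", "component_b", "current_locations")]
#>   reaction compartment component_a component_b current_locations
#> 1       R6           M          R1          R7                 U
```

The mitochondrial graph of the `demo` pathway falls apart into two
components (`R1`–`R5` and `R7`) because `R6`, whose enzyme has no location
annotation, dropped out. `R6`'s metabolites touch both components, so it
is reported as the single gap `(R6, M)`. Filling it restores connectivity:

```r
filled <- fill_gaps(net, gaps)
filled$counts
#>    auto-filled evidence-filled        unfilled
#>              1               0               0
build_pathway_graph(filled$network, "demo", "M")
#> <pathway_graph> demo @ M: 7 reactions, 6 edges, 1 components
```

Relationship typing on the worked-example network (cytosolic/mitochondrial
malate dehydrogenase isoenzymes are type `c`, the two mitochondrial
glutaminases type `b`, the Golgi glycosyltransferase trio with one
secreted member type `d`):

```r
classify_reactions(demo_relationship_network())
#>    reaction type
#> 1    R00256    b
#> 2    R00342    c
#> ...
#> 7    R05987    d
```

An end-to-end run on a simulated input set:

```r
sim <- simulate_network(sim_config(seed = 7, n_gaps = 4, n_irlrs = 3,
                                   n_dead_ends = 3, n_pathways = 8))
res <- run_pipeline(sim$network, sim$assoc, sim$keywords, sim$ontology,
                    currency = sim$currency)
res$stage_matrix     # compartment x stage counts of reaction-location pairs
res$summary          # gaps found/filled, IRLRs, dead ends, transports
write_outputs(res, "out")   # TSV reports + SBML Level 3 export
```

A thin command-line wrapper with the same functionality is installed at
`system.file("cli", "compartnet", package = "compartnet")`
(subcommands `simulate`, `run`, `gaps`, `irlr`, `transport`, `classify`,
`report`, `path`).

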