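---
title: "Compartmentalizing a metabolic network: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmentalizing a metabolic network: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compartnet)
```

This vignette explains the model behind `compartnet`, the assumptions each
stage makes, the parameters worth tuning, and the design decisions taken
where the procedure was genuinely open. It states no empirical result that
the test suite and `scripts/acceptance.R` do not themselves compute.

## The model

A network is a set of reactions (substrates, products, reversibility,
pathway memberships), proteins, and protein–reaction links. Location is a
*relationship*, not a property: a reaction may legitimately occur in
several compartments, and every analysis below operates on (reaction,
compartment) pairs. Eight real compartments are used — extracellular,
nucleus, cytosol, ER, Golgi, peroxisome, lysosome, mitochondrion — plus a
placeholder `U` for "uncertain". `U` is never an analysis target: it exists
so that "we don't know" is representable without being mistaken for
knowledge.

Every location row carries a provenance tag (`protein`,
`default-uncertain`, `gap-filled`, `curated`, `cytosol-default`), so the
final model is auditable stage by stage, and link deletions are soft (an
`active` flag), preserving the trail of corrected protein–reaction
relationships. Stoichiometry is stored but unused by the analyses: all of
them are purely topological, which is the central simplification of the
whole approach — no mass balancing, no flux feasibility.

### Protein localization

Ontology annotations are resolved by ascending `is_a` and `part_of` edges
from the annotated term until a target term is reached; the term itself
counts (annotating the nucleus term itself resolves to N). `part_of` must
be followed because membranes are *part of* their organelle, not
subclasses of it; other relations (`regulates`, `occurs_in`) do not carry
compartment membership and are ignored. Obsolete terms neither match nor
let traversal pass through. The plasma-membrane remap (membrane proteins
are treated as cytosolic, since their catalytic sites mostly face the
cytosol) is implemented as a ninth entry in the target map rather than a
special case, so the traversal stays generic for synthetic ontologies.

Two policies are worth calling out:

* **Conflicts mean multi-location.** If ontology and keyword sources
  disagree, the protein keeps all locations. Sub-cellular multi-residency
  is real; choosing a winner would discard information.
* **`U` is a fallback, not a location.** A term that reaches a target and
  also reaches only-above-target ancestors resolves to the target alone.
  `U` appears only when nothing resolves.

Annotation evidence codes are not filtered; the association-table reader
keeps only the two columns it needs. If evidence-based filtering is
wanted, filter the table before passing it in.

### Reaction localization and relationship types

A reaction's locations are the union of its active enzymes' locations
(with `U` dropped as soon as a real location is present); enzyme-less
reactions and reactions whose enzymes are all uncertain default to `{U}`.
Relationship types follow the location-set shapes: equal sets are `b`,
pairwise disjoint partitions are `c`, and anything overlapping but
unequal — including mixtures where two enzymes are disjoint and a third
overlaps both — is `d`. `d` is deliberately the residual class: it
triggers no automatic action, so misclassifying an ambiguous case into
`d` is safe, while `c` (which drives link deletion) requires strict
disjointness. Proteins whose set is `{U}` are excluded from the
comparison: they carry no evidence either way.

Resolving a type-`c` group requires a verdict — which compartment the
reaction truly occurs in — supplied as curation data with a citation.
Inferring the verdict automatically is out of scope by design: the
evidence is biological, not topological.

### Pathway graphs, gaps, IRLRs

For each pathway and compartment, the reactions located there are nodes;
an edge joins two reactions sharing a main metabolite *that can flow
between them* — produced by one and consumed by the other under some
permitted direction (reversible reactions permit both). This
producer/consumer-aware rule is the single most consequential design
choice in the package: mere co-occurrence linking would join parallel
consumers of one substrate and inflate connectivity, hiding gaps. The
co-occurrence variant remains available (`edge_rule = "cooccurrence"`)
for sensitivity analysis. Currency metabolites (default: ATP, ADP, AMP,
NAD(H), NADP(H), FAD(H2), CoA, H2O, CO2, O2, NH3, phosphate,
pyrophosphate, H+) never link reactions; the set is configurable and
applied uniformly per run.

A **gap** is a (reaction, compartment) pair where the reaction is *not*
located in the compartment but its main metabolites intersect the
metabolite lists of two distinct connected components there. Records are
per component pair — a reaction bridging three components yields three
records but one fill — which keeps "number of gaps" and "number of gap
reactions" distinct, as they should be. Gaps from `{U}` reactions are
auto-filled (the placeholder yields to structural evidence, and a
reaction may accumulate fills in several compartments); gaps from
reactions with real locations are filled only when an evidence row backs
them, optionally adding newly identified enzymes.

An **IRLR** is a (reaction, compartment) pair forming a one-node
component. IRLR detection runs *after* gap filling on re-derived graphs,
since filling may connect previously isolated reactions. By default a
pair is reported only when the reaction is a singleton in *every* pathway
containing it for that compartment: a reaction connected in any pathway
context is evidently functional there, and the conservative variant
avoids deleting supported locations (`scope = "any"` gives the
per-pathway behaviour). The decision cascade is: curated keep; curated
bad-link (deactivate and recompute); keep when some catalyzing enzyme has
this compartment as its only location *and* catalyzes no other reaction
network-wide (removing it would leave the enzyme functionless); otherwise
remove. Removal never zeroes a location set — the reaction reverts to
`{U}`.

The pathway literally named `"isolated"` is excluded from every
structural analysis; it is the conventional dump for reactions without
pathway context, where connectivity arguments are meaningless.

### Transports and dead ends

Before transport addition, `{U}`-only reactions move to the cytosol
(`cytosol-default`), the usual convention in compartmentalized
reconstructions — a transport involving "uncertain" would be meaningless.
Reference transports are accepted by evidence grade: score 3 (direct
biochemical/genetic evidence) and transporter-annotation rows need only
the metabolite to exist; score 2 (physiological or non-human evidence)
additionally requires the metabolite to occur in located metabolic
reactions in both compartments — the presence test deliberately ignores
transports already added, so acceptance does not depend on import order;
scores below 2 (purely in-silico) are ignored.

A **dead end** is a metabolite that, within a compartment, is only
produced, only consumed, or — optionally — participates in exactly one
reaction. The `sole-participant` mode extends the classic
only-produced/only-consumed definition: a metabolite in one reversible
reaction is formally both produced and consumed yet functionally
disconnected, and flagging it serves the stated goal of a connected
network (`sole_participant = FALSE` restores the strict definition).
Three scoping choices matter:

* Candidacy requires at least one located *metabolic* reaction in the
  compartment. Transports contribute producer/consumer roles, but a
  transport endpoint alone is not a candidate — transports are bridges,
  not pathway membership. Without this rule every inferred transport
  would mint a fresh dead end at its far side and inference would never
  terminate.
* Currency metabolites are exempt; they are ubiquitous by definition.
* Tallies are network-wide per compartment by default; a per-pathway mode
  (`mode = "pathway"`) exists but double-counts metabolites shared
  between pathways, so it is not the default.

Inference uses the cytosol as bridge: a dead end at L gets a reversible
transport L↔C; a cytosolic dead end gets C↔L′ for every other compartment
holding the metabolite. Inferred transports are reversible because the
analysis carries no directional evidence. Deduplication keeps one
transport per (metabolite, unordered pair), preferring the
better-evidenced source. Transport ids are deterministic functions of the
pair, which is part of the package's byte-identical reproducibility
contract.

### Path search

`find_path()` works on states (metabolite, compartment): a metabolic step
consumes one main metabolite and produces another within a compartment; a
transport changes compartment only. Currency metabolites cannot carry a
step — a "path" through ATP would connect everything to everything.
Shortest means fewest reactions; ties are broken deterministically by the
underlying graph library's first-found shortest path.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `currency` | 17 common cofactors/carriers | canonical connectivity-analysis list; adjust per naming scheme |
| `edge_rule` | `"flow"` | see above; `"cooccurrence"` for sensitivity |
| `irlr_scope` | `"all"` | conservative: do not delete locations supported by any pathway context |
| `dead_end_mode` | `"network"` | per-pathway double-counts shared metabolites |
| `sole_participant` | `TRUE` | reversible singletons are functionally disconnected |
| `strict` (curation) | `FALSE` | continue past bad edit rows, logging them |

## The synthetic generator

`simulate_network()` emulates what the pipeline needs from real inputs:
pathway-structured reaction chains with one enzyme per reaction, partial
and uncertain annotation split between an ontology source and a keyword
source, currency cofactors, and planted structure — an auto-fillable gap
(a chain's middle enzyme unannotated), an IRLR (a branch reaction whose
enzyme carries a second compartment), and a dead end (a terminal
metabolite that circulates inside a second pathway elsewhere). Chain
boundary metabolites are currency, so chain ends do not masquerade as
dead ends; surplus unannotated enzymes beyond the planted gaps live in
the `"isolated"` pathway, outside all analyses. Planted counts are exact:
generation is verified post hoc against the package's brute-force oracles
(matrix-reachability components, exhaustive gap enumeration, direct role
tallies) — never against the production detectors, to avoid circular
validation. The verification replays the pipeline's stage order, because
planted IRLRs are only visible after gaps are filled and planted dead
ends only after IRLR removal.

What the generator does *not* emulate: realistic biochemistry (no mass
balance, no meaningful compound identity), annotation noise (wrong rather
than missing locations), reaction sharing between pathways, and
EHMN-scale size. Green tests therefore demonstrate algorithmic
correctness on known structure, not robustness to noisy annotation — on
real data the quality of the output is bounded by the quality of the
location sources.

## Numerical and determinism choices

All orderings are canonical: components sorted by smallest member,
records by (pathway, compartment, reaction), transports by id. Repeated
runs from the same seed are byte-identical, and the test suite asserts
this on whole output directories. Degenerate inputs are defined rather
than rejected: empty pathways produce empty graphs, one-component graphs
produce no gaps, a removal that would empty a location set reverts to
`{U}`, and an empty edit list is a no-op with an empty audit log.

Test problem sizes — 500 random graphs of up to 50 nodes for the
component oracle, 100 planted networks for the gap oracle, 200 random
DAGs for backtracking, 20 seeded configurations with up to 10 planted
findings each for end-to-end recovery — were chosen as the smallest sizes
at which every code path (multi-component graphs, multi-gap reactions,
overlapping plantings) is exercised across many random topologies.

## Known limitations

* All analyses are topological; a "filled" gap is structurally, not
  thermodynamically, justified.
* The IRLR keep-rule depends on link completeness: a protein that seems
  single-reaction merely because the network is incomplete will wrongly
  anchor its location.
* Keyword locations cover only the six organelles shared with the
  ontology targets; extracellular/cytosol keyword evidence is not used,
  and whether plasma-membrane keywords should remap to the cytosol (as
  the ontology terms do) is left to the keyword map supplied by the user.
* Transport inference guarantees connectivity, not correctness: dead-end
  derived transports are hypotheses with the weakest evidence class, and
  are labelled as such in the output.
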