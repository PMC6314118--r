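---
title: "Methods: group-consensus candidate scanning, shell analysis and phenotype metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group-consensus candidate scanning, shell analysis and phenotype metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fadscan)
```

## The problem

Membrane-bound fatty acid desaturases share a conserved fold — four
transmembrane helices, a cytosolic catalytic domain, and a di-iron centre
ligated by histidines arranged in three conserved boxes — yet differ sharply
in regioselectivity. Delta-12 enzymes (FAD2-like) insert a double bond
twelve carbons from the carboxyl end of an oleoyl chain; omega-3 enzymes
(FAD3-like) count three carbons from the methyl end of a linoleoyl chain.
Bifunctional fungal enzymes such as Fm1 of *Fusarium verticillioides*
perform both reactions with a single active site. Because overall sequence
identity between the two monofunctional families is low (~40%), positions
that *are* conserved within one family but not the other are the natural
candidates for specificity determination. fadscan implements this
comparative workflow end to end, together with the structural filter
(residues near the catalytic irons), rule-based mutagenesis planning, and
the GC-FAME phenotype metrics used to score the resulting variants.

## The column-classification model

Given a multiple sequence alignment whose rows are labelled `delta12`,
`omega3`, `query` (the bifunctional enzyme) or `other`, each column is
summarized by two group consensuses. A residue is the consensus of a group
at a column when its frequency among the group's non-gap residues reaches
the threshold `t`; the default `t = 1` is strict unanimity. The published
analyses that motivated this package describe columns simply as "conserved"
without quantifying the criterion, and were produced with a
conserved-property tool plus manual curation; unanimity is the strictest
reproducible reading and is therefore the default, with two documented
relaxations:

* a frequency threshold `t` in (0.5, 1] — the lower bound guarantees at
  most one consensus residue per column;
* a property mode in which consensus is evaluated over physico-chemical
  classes (hydrophobic `AVLIM`, aromatic `FWY`, polar `STNQ`, positive
  `KRH`, negative `DE`, special `GPC`), mirroring conserved-property-style
  analyses. Query-versus-consensus comparison stays identity-based even in
  property mode, because downstream substitution experiments are
  identity-based.

A column is a **candidate** only when the two groups genuinely differ: at
least one group has a consensus and the other group's consensus is absent
or different. Candidates are classified per group side:

| category | predicate |
|---|---|
| 1 | delta12 conserved, query matches its consensus |
| 2 | delta12 conserved, query differs |
| 3 | omega3 conserved, query matches its consensus |
| 4 | omega3 conserved, query differs |

The two sides are evaluated independently, so a column where both groups
are conserved at different residues carries two flags (for example `2,3`
when the query follows the omega-3 group). This matches how the published
Fm1 lists use the categories — their omega-3 listing subsumes the
query-shared subset, and two positions appear under both delta-12
categories — and those lists are shipped verbatim in
`fm1_candidate_sets()`, overlaps included; `merge_category_lists()`
resolves them to the 44 unique candidate positions. The published lists'
internal inconsistencies (position 318 under the shared category only)
stem from the original manual curation and are reproduced, not repaired.

**Gap handling.** Gaps are excluded from the consensus denominator when
they make up at most `max_gap_frac` (default 25%) of the group column;
gappier columns return no consensus, because a consensus supported by a
minority of the group is not evidence of family-wide conservation.
Columns where the query itself has a gap are skipped with a notice —
there is no query residue to mutate. All positions are reported in the
query's own ungapped 1-based numbering via an explicit column map, so a
site named `F157H` always refers to the 157th residue of the query.

The paralog-divergence scan (`divergent_sites()`) is the complementary
filter: positions where two bifunctional paralogs differ from *each other*
while *neither* functional group is conserved — positions free to drift,
hence candidates for the paralogs' differing product preferences.

## Structural shell filter

`find_his_boxes()` locates `HxxxH` and `HxxHH` motifs; interior positions
are required to be non-His so the two motif classes stay disjoint and an
`HxxHH` box is never double-counted as `HxxxH`. `shell_residues()` reports
every residue of a PDB-format model with at least one atom within `radius`
(default 5 Å) of any selected metal atom (elements FE/ZN/MN/CU by
default). Distance is computed to *any* atom of the residue — the
inclusive reading of a "within 5 Å" criterion; a side-chain-only variant
can be had by filtering the atom table before construction. Alternate
conformations keep the highest-occupancy copy; insertion codes are part of
the residue key. Homology-model *construction* is out of scope: the
package consumes models built elsewhere and ships a toy-structure
generator for testing.

## Mutagenesis planning

`plan_substitution()` implements the comparison rule: for categories 2 and
4 the query is mutated to the differing group's consensus; for categories
1 and 3 (consensus shared with the query) it is mutated to the equivalent
residue of a single named representative of the *other* group (the
delta-12 and omega-3 donors, e.g. AtFAD2 and AtFAD3), not that group's
consensus — representatives are what substitution experiments actually
copy from. When a site carries two flags the consensus rules (4, then 2)
take precedence over the representative rules; an explicit `category`
argument overrides. A donor gap at the column is a reported planning
error, never a silent skip. Structure-motivated substitutions that follow
no category rule (e.g. copying a template structure's residue) enter
through `mutation()` directly.

`merge_adjacent()` groups candidate positions within a 3-residue window
(default) into single mutagenesis units, reflecting the practice of
mutating sequence-adjacent candidates as one construct; the window is
configurable because the practice is a judgement call, not a published
constant. Variant names are canonical — mutations sorted by position and
joined with `/`, as in `K36R/L153R/F157H` — and `parse_variant()` inverts
`variant_name()` exactly.

## Phenotype metrics

`quantify()` converts a GC-FAME peak table to yields via internal-standard
normalization:

yield(species) = area(species) / area(17:0 standard) x standard mass (5 µg)
/ A600,

in µg fatty acid per A600 unit of cells. Response factors are assumed
equal across FAME species unless a per-species table is supplied; only the
normalization itself is published for the assays this models. **Product
activity** sums yields of species with ≥ 2 double bonds — everything
downstream of the enzyme's first desaturation, which also covers C16
feeding experiments; species-level flags can override. The **product
ratio** ALA/(ALA+LA) measures the second desaturation relative to the
first (all trienoic product derives from a second desaturation of the
dienoic one); when both yields are zero the ratio is undefined (`NA`),
deliberately distinct from 0. Variant classification uses three
thresholds: increased activity above 125% of the reference (the published
highlight criterion), loss of function below 1% of reference activity (the
published figures mark complete loss without a numeric floor; 1% is this
package's documented default), and a ratio shift larger than 0.15 absolute
(the published shifts, 0.86 → 0.55/0.5/0.4, are narrated without a cutoff;
0.15 separates them cleanly from replicate noise at the 5% level).

**Regiochemistry.** `predict_product()` encodes the two counting rules —
v+3 (three carbons methyl-ward of the last existing bond) and omega-3
(delta position `chain − 3`) — and `infer_rule()` inverts them. On an
18-carbon dienoate (Δ9,12) both rules predict Δ15, so the observation is
*ambiguous*; ambiguity occurs exactly when the last existing bond sits at
`chain − 6`. This is why a C16 substrate, where v+3 predicts Δ15 but
omega-3 predicts Δ13, is the discriminating experiment; the package's
worked example reproduces that inference from the assigned double-bond
positions alone (mass-spectral interpretation is out of scope).

## What the simulators emulate — and what they do not

`simulate_family()` builds alignments whose background columns draw each
group's residues from disjoint two-residue pools, cycled so every group
shows at least two distinct residues. The maximum within-group background
frequency is therefore 0.5 — below any valid threshold — making the
precision-1 assertions valid *by construction*, not empirically. Planted
columns are unanimous in their conserved group per their category
definition. Default dimensions (two groups of four sequences, 400
columns, twelve planted sites, a 2% indel rate and ten query-gap columns)
mirror the scale of the real nine-enzyme comparison. What the simulator
deliberately does **not** model: phylogenetic correlation between rows,
covarying columns, alignment errors, or partial conservation — precisely
the features that make real candidate lists aligner- and
curation-dependent. Passing the planted-recovery tests therefore shows the
classifier implements its definition exactly; it does not show that a real
alignment yields the published 44 positions, which additionally depends on
the structure-informed aligner and the manual curation of the original
analysis (the published lists are shipped as data for that comparison).

`simulate_structure()` places one C-alpha per residue at an exact distance
from a single iron at the origin — sufficient to validate shell geometry
exactly, silent about real side-chain atom clouds. `simulate_peaks()`
inverts the quantification formula with lognormal multiplicative noise
(σ = 5%, three replicates by default, matching routine GC-FAME replicate
scatter); the demo dataset `fm1_demo()` parameterizes variants at the
reported phenotypes (reference ratio 0.86, a 2.5x-activity variant, a
0.4-ratio variant, a 0.06-ratio triple, an empty-vector control) so the
tutorial reproduces the narrative classifications without claiming to
reproduce wet-lab measurements.

## Numerical and design notes

* All randomness flows through explicit `seed` arguments; generators
  restore the global RNG state, and identical seeds give byte-identical
  output.
* Consensus ties cannot occur at thresholds above 0.5; in property mode
  the representative residue of a tied class is the alphabetically first
  among the most frequent — a documented, deterministic tie-break.
* Shell distances are exact Euclidean minima; the brute-force oracle in
  the test suite agrees to 1e-9 Å, and rigid-motion invariance holds to
  1e-6 Å (floating-point rotation error).
* PDB coordinates round-trip at the format's 3-decimal precision.
* Degenerate inputs fail loudly: ragged alignments name the offending
  row, unknown group labels and ambiguity codes other than X are
  rejected, an all-gap row is an error, a zero internal-standard area is
  a quantification error, and `0/0` product ratios are `NA`, never 0.
* Problem sizes in the shipped tests (400-column families, 100 random
  toy structures, three-replicate peak tables) are the package's chosen
  verification scale: large enough to exercise every code path and
  invariant, small enough to run anywhere in seconds.

## Known limitations

* The conservation criterion of the original curated analysis is not
  fully recoverable; with a different aligner or threshold the candidate
  set will shift. The scan is deterministic given its inputs — the inputs
  themselves are the irreproducible part.
* No statistical scoring of conservation (entropy, mutual information):
  the implemented rule is consensus-based by design.
* Sequence fetching, alignment computation and homology-model building
  are external steps; documented hooks consume their outputs.
* Heterodimer effects, substrate channeling and headgroup specificity are
  outside the model; the phenotype metrics treat each enzyme variant
  independently.
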