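# fadscan

Specificity-determining position analysis for membrane-bound fatty acid
desaturases.

## What problem this solves

Delta-12 desaturases (FAD2-like) and omega-3 desaturases (FAD3-like) share
a fold and a histidine-ligated di-iron centre but only ~40% sequence
identity, and a handful of bifunctional fungal enzymes (Fm1 of *Fusarium
verticillioides* being the best studied) perform both reactions with one
active site. Dissecting which residues set activity and which set
regioselectivity is a comparative-sequence problem: positions conserved
within one functional group but not the other are candidate
specificity-determining positions (SDPs). fadscan implements that
workflow for enzyme engineers and molecular evolution researchers:

* **Candidate scanning** — per-column group consensus at threshold *t*
  (default: unanimity) and a four-category Venn classification of each
  alignment column: conserved in the delta-12 group and shared / not
  shared with the query enzyme (categories 1/2), conserved in the
  omega-3 group and shared / not shared (3/4). Sites are reported in the
  query's ungapped numbering.
* **Paralog divergence** — positions where two bifunctional paralogs
  differ while neither functional group is conserved.
* **Structure filter** — His-box motif detection (`HxxxH`, `HxxHH`) and
  the residues within a 5 Å shell of the catalytic iron atoms of a
  PDB-format model, with exact minimum distances.
* **Mutagenesis planning** — the comparison rule (mutate to the other
  group's consensus, or to a named representative's residue when
  conservation is shared), merging of sequence-adjacent sites into single
  constructs, and canonical `K36R/L153R/F157H` variant naming.
* **Phenotype analysis** — GC-FAME quantification against a 17:0 internal
  standard (µg fatty acid per A600), the product ratio ALA/(ALA+LA), and
  variant classification (increased activity > 125% of reference, loss of
  function, ratio shift).
* **Regiochemistry inference** — v+3 versus omega-3 double-bond counting:
  a v+3 enzyme desaturates three carbons methyl-ward of the last existing
  bond, an omega-3 enzyme at chain − 3. On 18:2Δ9,12 both predict Δ15
  (ambiguous); on 16:2Δ9,12 they diverge (Δ15 vs Δ13), which is how the
  processive v+3 mechanism of Fm1-type enzymes is established.
* **Synthetic data** — seeded simulators for grouped alignments with
  planted signal columns, toy metal-site structures, and peak tables, so
  the whole pipeline runs and is tested fully offline.

## Worked example

```r
library(fadscan)

# a simulated 9-sequence family: 4 delta-12, 4 omega-3, 1 bifunctional
# query, 400 columns, 12 planted signal sites
sim <- simulate_family(seed = 42)
cand <- scan_candidates(sim$alignment, threshold = 1)
head(cand, 4)
#>   ref_position column categories query_residue delta12_consensus omega3_consensus
#> 1           24     24          1             E                 E             <NA>
#> 2           49     49          2             M                 R             <NA>
#> 3           71     74          3             G              <NA>                G
#> 4          118    122          4             K              <NA>                M
```

Each row is one candidate: at query position 49 the delta-12 group is
unanimously R while the query has M (category 2); at position 71 the
omega-3 group and the query share G (category 3). Planning substitutions
with the first sequence of each group as donor:

```r
plans <- plan_candidates(cand, sim$alignment,
                         donor_delta12 = "d1", donor_omega3 = "w1")
head(plans, 4)
#>   ref_position wild_type substitute  name category_used unit note
#> 1           24         E          F  E24F             1    1
#> 2           49         M          R  M49R             2    2
#> 3           71         G          C  G71C             3    3
#> 4          118         K          M K118M             4    4
```

Category-2/4 sites get the differing group's consensus (M49R); category-1/3
sites get the opposite group's representative residue (E24F copies donor
w1). Phenotypes from the demo GC-FAME dataset:

```r
demo <- fm1_demo(seed = 42)
res <- lapply(split(demo$tables, sub("_rep[0-9]+$", "", names(demo$tables))),
              quantify_replicates)
res[["Fm1"]]
#> phenotype_result [Fm1]
#>   product activity: 10.3 ug/A600
#>   ALA/(ALA+LA): 0.867
classify_variant(res[["F157H"]], res[["Fm1"]])
#> [1] "increased_activity"
infer_rule("18:2Δ9,12", "18:3Δ9,12,15"); infer_rule("16:2Δ9,12", "16:3Δ9,12,15")
#> [1] "ambiguous"
#> [1] "v_plus_3"
```

The reference enzyme converts most LA to ALA (ratio 0.87); the F157H
variant exceeds the 125% activity criterion. The C18 product is ambiguous
between the two counting mechanisms, while the C16 product is explained
only by v+3 counting.

The published candidate lists for Fm1 itself ship with the package:

```r
length(merge_category_lists(fm1_candidate_sets()))
#> [1] 44
```

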