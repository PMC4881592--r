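---
title: "Selecting high-confidence miRNA cancer biomarkers from target groups and a stem-loop phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting high-confidence miRNA cancer biomarkers from target groups and a stem-loop phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirphylomark)
```

## The problem and the method

Microarray screens of tumour versus normal tissue yield lists of candidate
miRNA biomarkers per cancer, but such lists are noisy. The rationale of
this package is that miRNAs with similar stem-loop (precursor) sequences
tend to be evolutionarily related and are more likely to regulate the same
disease processes, so sequence similarity can be used as an independent
filter on expression-derived candidates. The method intersects two
clusterings of the same candidate panel:

1. **Target groups.** Each candidate miRNA carries a binary vector over
   the studied cancers (1 where it was flagged by the expression screen).
   miRNAs with *identical* vectors form a target group. The groups are
   visualized with a UPGMA dendrogram over Euclidean distances between the
   binary vectors; with 0/1 vectors the Euclidean distance is simply the
   square root of the number of cancers on which two miRNAs disagree, and
   identical vectors tie at height zero, so the zero-height partition of
   the dendrogram coincides with the group partition.

2. **Stem-loop phylogeny.** Pairwise Jukes–Cantor distances between the
   miRNAs' precursor stem-loop sequences,
   $d = -\tfrac{3}{4}\,\ln\!\left(1 - \tfrac{4}{3}\,p\right)$,
   where $p$ is the proportion of differing sites among gap-free aligned
   columns, followed by single-linkage (nearest-distance) agglomeration
   into a rooted binary tree.

3. **Selection.** A *biomarker set* is a maximal clade of the phylogeny
   whose leaves all belong to one target group. Every such set is
   simultaneously a unit of shared evolutionary structure and a unit of
   shared predicted cancer targets, which is what makes it
   "high-confidence". A group whose members sit in several branches of
   the tree yields several disjoint sets — one per branch — rather than
   one pooled set.

4. **Evaluation.** A selection is scored per cancer against a table of
   experiment-supported miRNA–disease associations (an HMDD-style
   validation set) through four counts: A candidates, B candidates
   confirmed, C selected, D selected-and-confirmed. Sensitivity is
   $D/B$ — among confirmed candidates, the fraction the screen retains.
   The reported specificity is $(C-D)/(A-B)$, among *unconfirmed*
   candidates the fraction retained. Note this published formula is not
   the standard true-negative rate; `specificity(..., standard = TRUE)`
   returns its complement $1-(C-D)/(A-B)$ for users who want the
   conventional quantity. Relative improvement over a baseline method is
   reported as the increase rate $(\text{new}-\text{old})/\text{old}$.

### Assumptions

* The candidate table is trusted as given; the package does not
  re-derive it from expression data (that upstream regression screen is
  out of scope, its output is the input here).
* Phylogenetic similarity of precursors is a proxy for shared function.
  This is a biological hypothesis, not a theorem; the evaluation module
  exists precisely to quantify how much the phylogenetic filter helps.
* The Jukes–Cantor model assumes equal substitution rates among the four
  nucleotides and across sites. It is the simplest correction of raw
  mismatch proportions for multiple hits; no rate heterogeneity or more
  general substitution models are offered.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `match`, `mismatch`, `gap` | +5 / −4 / −8 | Needleman–Wunsch global alignment scoring (linear gap penalty per position), NUC44-style. Stem-loop entries differ in length, so every pair is globally aligned before $p$ is computed; gap columns are excluded from $p$. |
| `saturation_cap` | 5 substitutions/site | distance substituted when $p \ge 0.75$ leaves the Jukes–Cantor formula undefined. Clustering needs finite entries; 5 is far beyond any realistic stem-loop divergence, so saturated pairs always join last. Saturated pairs are additionally recorded and logged. |
| `min_set_size` | 2 | a reported set must be a clade of at least two leaves, i.e. show genuinely *shared* phylogenetic structure. `min_set_size = 1` also emits single leaves whose maximal in-group clade is themselves. |
| `include_singleton_groups` | `FALSE` | separately emits the lone member of a one-miRNA group. Reference selections contain some singleton sets that the clade rule alone cannot produce, while omitting others; since no parameterization of the stated rule reproduces that asymmetry, both behaviours are exposed and neither is asserted as ground truth. |

Alphabet: sequences are normalized internally (default RNA; `U`/`T`
unified, case folded). `N` aligns but never matches anything, itself
included, so ambiguity always counts as a difference — a deterministic,
conservative choice.

## Numerical and structural conventions

* **Heights.** UPGMA node heights follow the ultrametric convention
  (merge at inter-cluster distance $d$ sits at height $d/2$; all leaves
  equidistant from the root). Single-linkage node heights are the raw
  minimum inter-cluster distances; sorted, they equal the minimum
  spanning tree edge weights of the distance graph, a classical
  equivalence the test suite checks against an independent Prim oracle.
* **Tie-breaking.** Agglomeration order under exactly tied distances is
  resolved lexicographically: among candidate merges at the minimum
  distance, the pair whose smallest leaf label sorts first wins (then the
  partner cluster's smallest label). Binary 0/1 target vectors tie
  constantly, so a deterministic rule is essential for reproducible trees
  across platforms; published linkage implementations leave this order
  unspecified.
* **Serialization.** Newick branch lengths are height differences
  (child branch = parent height − child height; leaves at height 0), so
  trees round-trip through standard Newick parsers with node heights
  preserved to well below 1e−9. The earlier-created cluster is always the
  left child.
* **Rounding for display.** Three decimals, half away from zero,
  trailing zeros trimmed — matching how the reference tables print values
  such as 0.64 and 0.5. Comparisons against printed values in the tests
  are made at each value's printed precision.
* **Degenerate inputs.** All-zero association rows, duplicate miRNA or
  disease names, unknown cell tokens, empty sequences and duplicate FASTA
  headers are load-time errors naming the offender. Undefined metrics
  (B = 0 or A = B) are reported as missing, never silently 0.

## The synthetic-data generators

`simulate_sequences()` emulates the panel structure the method assumes:
a few divergent families (inter-root site-difference proportion at least
0.5 by rejection sampling, i.e. roughly the divergence of unrelated
sequences) whose members differ from the family root by i.i.d.
substitutions at a small rate, at the ~90 nt scale of precursor
hairpins. Substituted bases are drawn uniformly from the three
alternatives, consistent with the Jukes–Cantor model used downstream.
Optional single-base indels (off by default) exercise the alignment
step. What it does **not** emulate: hairpin secondary structure,
site-rate heterogeneity, base-composition bias, or the gradual overlap
between real miRNA families. Passing family-recovery tests therefore
show the pipeline is correct in the regime where families are
well-separated and members closely related — the regime in which the
selection rule is well-posed — not that real miRBase panels will cluster
as cleanly.

`simulate_associations()` draws a requested number of distinct non-zero
binary disease patterns and assigns miRNAs to them, with optional
independent bit-flip noise; at zero noise the generating partition is
recovered exactly by `extract_groups()`, which is the identity the tests
assert, and with 90 miRNAs, 7 diseases and 41 patterns it mirrors the
reference panel's shape.

## Open design choices, and how they were settled

* **What is a "group"?** Defined as an equivalence class of identical
  target vectors. On the packaged reference panel the printed group
  numbering coincides exactly with this partition (90 miRNAs, 41
  groups), which the tests verify; the dendrogram is treated as a
  visualization, not as the definition. Cutting the dendrogram at a
  height threshold would coincide on this panel but could differ on data
  where distinct patterns tie at low heights.
* **What is "the same clade"?** A clade wholly inside one group, taken
  maximal among nested such clades. This reproduces the reference
  behaviour in which one bladder-only group splits into three sets
  because its members occupy three branches, and it makes the emitted
  sets within a group provably disjoint (clades are laminar).
* **Alignment before distance.** The reference analysis used a toolbox
  routine whose pairwise-alignment parameters are not printed, so exact
  tree topology on real miRBase sequences is not bit-reproducible from
  the description alone. The package makes the alignment explicit
  (global, +5/−4/−8) and configurable, and treats topology-dependent
  reference outputs as integration-level expectations rather than unit
  oracles.
* **Recomputed versus printed arithmetic.** All per-cancer
  sensitivity/specificity values recompute exactly from the packaged
  counts at printed precision, and three of the four packaged increase
  rates match their own formula; recomputing the colon sensitivity
  increase from the packaged metrics (0.405 → 0.476) gives 17.53%,
  whereas the packaged reference value prints 17.28%. The package always
  reports its own computed arithmetic; the fixture preserves the printed
  value, and the corresponding check documents the discrepancy by
  failing rather than hard-coding either number.
* **Name resolution.** Display names in association tables and stem-loop
  identifiers in FASTA headers differ (e.g. miR-92 resolves to the
  hsa-mir-92a-1 precursor); a small packaged name map plus the
  `name_map` argument of `phylomark()` handle this explicitly, and group
  members with no sequence are excluded with a logged message rather
  than silently dropped.

## Problem sizes used by the test suite

The suite is built on small, fast instances chosen to make every
property checkable against an independent oracle: exhaustive
subset-scan selection oracles on random trees of 5–12 leaves (200
trials), Prim MST comparisons at up to 10 leaves, exhaustive
global-alignment enumeration on strings of length ≤ 8, Jukes–Cantor
closed form versus numerical inversion on a grid of ~370 points, and
family-recovery runs of 3 families × 4 members × 90 nt across 20 seeds.
The packaged 90 × 7 reference panel is processed in full.

## Known limitations

* Jukes–Cantor only; no Kimura or GTR-class models, no rate
  heterogeneity, no bootstrap support.
* Pairwise alignment, not multiple sequence alignment: distances are not
  guaranteed mutually consistent the way an MSA-derived matrix would be.
* Single linkage chains: two families bridged by one intermediate
  sequence can fuse into one clade, which directly affects selection;
  the family-recovery tests quantify this only in the well-separated
  regime.
* The evaluation depends entirely on the completeness of the validation
  table; absent associations are treated as unconfirmed, not as false.

## A minimal end-to-end run

```{r example, eval = FALSE}
assoc <- load_fixture("table3")               # 90 x 7 candidate panel
length(extract_groups(assoc)$members)         # 41 target groups

# simulated demonstration: 3 sequence families, 3 matching target patterns
sim_s <- simulate_sequences(3, 4, seed = 7)
sim_a <- simulate_associations(12, 7, 3,
                               pattern_assignment = rep(1:3, each = 4),
                               seed = 7)
rownames(sim_a$assoc) <- names(sim_s$sequences)
fit <- phylomark(sim_a$assoc, sim_s$sequences)
summary(fit)
```

For file-based runs, `run_pipeline()` (or the `inst/cli/mirphylomark.R`
script) writes `groups.tsv`, both trees as Newick, the distance matrix,
`selection.tsv`, `evaluation.tsv` and a manifest with input checksums
from which the run can be repeated byte-identically.
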