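---
title: "Counting ancestral gene copies from collapsed gene family trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting ancestral gene copies from collapsed gene family trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copymin)
library(dplyr)
```

## The question

Comparative genomics of land plants often asks how many members of a gene
family were already present in the common ancestor of mosses (bryophytes,
represented here by *Physcomitrella patens*) and vascular plants
(tracheophytes: the lycophyte *Selaginella moellendorffii* plus monocots and
eudicots). Given a gene family tree estimated from the members found in a set
of sequenced genomes, each clade that contains genes from **both** sides of
that split must descend from a distinct gene copy in the moss/tracheophyte
common ancestor — gene trees only ever give a *minimum*, because copies
lost on one side leave one-sided clades that cannot be distinguished from
lineage-specific duplications.

`copymin` implements that counting rule, together with the tree
post-processing it presupposes (bootstrap-threshold collapsing, outgroup
rooting), a per-species family census, and a duplication–loss simulator that
provides ground truth to validate the inference.

## The inference rule

Leaves are annotated with species, species are binned into lineage groups
(`lineage_scheme`), and a `focal_split` names the two lineage sets A and B
(default: A = bryophyte, B = lycophyte + monocot + eudicot +
basal angiosperm). A node is **spanning** when its leaf set holds at least
one A-side and one B-side gene; algal outgroup leaves are transparent
throughout — they root trees but never count toward either side.

Starting from the most recent common ancestor $v_0$ of all A- and B-side
leaves, the count is

$$
f(v) \;=\; \sum_{c \,\in\, SC(v)} f(c) \;+\;
\mathbf{1}\!\left[\text{leftover leaves of } v \text{ contain both an A and a B gene}\right],
$$

where $SC(v)$ are the spanning children of $v$ and the *leftover* leaves are
those under $v$'s non-spanning children (outgroup leaves excluded). The
indicator is the **polytomy bonus**: when a collapsed node retains loose moss
and tracheophyte genes that belong to no resolved subclade, those genes still
witness one further ancestral copy. When $SC(v) = \emptyset$ and $v$ is
spanning, the same indicator counts $v$ itself as a single spanning clade.

Two modes are provided:

* **paper** (default): the rule exactly as above. On a fully resolved binary
  tree it equals the number of *minimal spanning nodes* (spanning nodes with
  no spanning child), which is the classical duplication–loss minimum.
* **strict**: the bonus applies only where there is no spanning child. On
  binary trees the two modes coincide; on collapsed trees the strict count is
  never larger. Strict mode exists because the leftover rule can exceed the
  true topological minimum when a collapse has hidden nesting — e.g. when the
  loose leaves would, at full resolution, nest inside one of the counted
  clades.

A family is **ND** (not determined) when its tree has no A-side or no B-side
leaves at all: with the family undetected in one lineage, the ancestral count
at this split is undefined rather than zero.

One deliberate reporting choice: clades at $v_0$ that contain tracheophyte
genes from several lineages but no moss gene are *surfaced* in the clade
report (`counted = FALSE`) but never added to the count. Such clades are
compatible with either a further ancestral copy (lost in mosses) or a
tracheophyte-specific duplication, and the conservative minimum excludes
them. This mirrors how the reference census we validate against tallies its
GAUT row.

```{r gaut}
fx <- make_figure_fixtures()
gaut <- analyze_tree(fx[["Galacturonosyltransferases (GAUTs)"]],
                     default_taxon_map(),
                     family = "Galacturonosyltransferases (GAUTs)")
gaut
clade_report(gaut)
```

## Tree post-processing

**Support collapsing.** Bootstrap supports live on internal node labels (the
RAxML convention: the label of a node is the support of the edge above it).
`collapse_low_support(tree, threshold = 50)` contracts every internal edge
whose child support is *strictly* below the threshold — a support of exactly
50 survives, matching the usual "less than 50%" phrasing. Collapsing never
touches the leaf set, is idempotent, and commutes with raising the threshold.
Supports read from files on the 0–1 scale are auto-rescaled to percent.

**Outgroup rooting.** `root_by_outgroup()` places the root on the edge
separating the outgroup from the ingroup. Supports are treated as edge
properties and follow their edge when its orientation flips, so every
bipartition keeps its bootstrap value (this is why the package carries its
own rerooting rather than relying on generic utilities, which are known to
shuffle node labels). A non-monophyletic outgroup roots at the smallest
clade containing all outgroup leaves, under the input orientation, and flags
the result `outgroup_not_clean`. Families with no algal hit are processed
as read, with a warning — their counts are still reported, as is standard
for rootless families.

**Degenerate inputs.** A fully collapsed tree is a valid star (the count then
comes from the bonus rule alone and is 0 or 1); a single A-gene and a single
B-gene as a cherry count 1; trees containing only algal leaves are an error
rather than ND.

## The census

`build_family_table()` counts gene IDs per family and species through the
same first-match-wins taxon map used for tree leaves, joins inferred
ancestral counts, and `summarize_census()` produces the totals row: ND
families contribute 0 to the ancestral total and are reported separately,
never silently summed. The packaged `reference_family_census()` transcribes
the published 16-family census (229 *Arabidopsis* genes, 69 *Physcomitrella*
genes, 24 ancestral copies, 12 of 16 families with a moss member), so the
census path is testable without any download.

## The simulator and what it does (not) show

`simulate_family()` runs a linear birth–death model down a fixed ten-species
tree (`default_species_tree()`: chlorophyte outgroup, moss, lycophyte, two
monocots, five eudicots; ultrametric, root depth 1 in arbitrary time units).
Each of `k0` root copies duplicates at rate $\lambda$ and dies at rate
$\mu$ per unit branch length; copies crossing a speciation node are
inherited by both daughters. Copies extinct everywhere are pruned, and the
truth table records, for every species-tree node, both the raw number of
entering copies and the number with surviving descendants — the latter is
the only quantity a topology-based method can recover, and is what
`truth_at_split()` returns at the `land_plants` node.

Defaults ($k_0 = 1$, $\lambda = 0.3$, $\mu = 0.2$ per copy per unit time)
give families of realistic size for this study system (a handful to a few
dozen surviving genes) with appreciable loss. Supports are assigned
synthetically: `degrade_supports(p)` makes exactly `round(p × n)` internal
edges weak (uniform in [0, threshold)) and the rest 100, emulating the large
polytomies of real bootstrap trees without simulating sequences — the
inference consumes only the support values, so nothing more is needed.

The validated guarantees, each exercised in the test suite:

* with $\mu = 0$ and no degradation, the paper-mode count **equals** the
  truth at the split (100 replicates per configuration over
  $k_0 \in 1..5$, $\lambda \in \{0, 0.3\}$);
* with $\mu > 0$, the count **never exceeds** the truth (it is a minimum);
* strict mode never exceeds paper mode, degraded or not;
* on 1000 random binary annotated trees (≤ 10 leaves) the paper-mode count
  equals an exhaustive minimal-spanning-node enumeration written as an
  independent oracle.

What the simulator does *not* emulate: sequence-level signal (supports are
assigned, not estimated), gene conversion or transfer (the model assumes
vertical descent with duplication and loss), and estimation error in the
tree topology itself. Passing these tests therefore shows the counting rule
is correct *given* a tree; it says nothing about the upstream quality of any
real tree.

## Fixture trees

`make_figure_fixtures()` builds sixteen small Newick trees whose clade
composition transcribes the published narrative for each pectin-related
family — e.g. the GAUT tree: two resolved moss + lycophyte + angiosperm
clades, one resolved moss-free clade, and loose moss/angiosperm leaves plus
the *Spirogyra* root in one polytomy. Leaf counts within a described clade
are arbitrary small numbers (2–3 per lineage); the suite verifies the
inferred count is invariant to them. Resolved clades carry support 100 and
described polytomies are written as multifurcations, so the 50% collapse
pass is exercised as a no-op on these fixtures and substantively on the
simulator output and random-tree property tests.

## Problem sizes

The packaged analyses are intentionally desk-scale: fixture trees have 8–22
leaves, property tests use 500–1000 random trees of ≤ 20 leaves, and the
simulation study runs 1200 replicates across its parameter grid. These sizes
were chosen as the smallest at which every claimed property is exercised
with all ten species and both polytomy regimes represented.
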