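---
title: "Classifying plant gene families by evolutionary history: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying plant gene families by evolutionary history: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famclade)
```

## The classification model

famclade formalises an evolutionary nomenclature for plant gene families.
The object of study is a gene family spread over plant genomes spanning five
taxon ranks — green algae, bryophytes, lycophytes, monocots and eudicots —
and the claim the nomenclature encodes is about *when* the duplications that
structure the family happened:

* a **group** is everything descended from one gene in the last common
  ancestor of monocots and eudicots;
* groups belong to the same **supergroup** unless the duplication separating
  them predates the embryophyte (bryophyte/vascular-plant) split.

The algorithm is a rank-level reconciliation of a rooted gene tree against
the fixed rank ladder
`(green_algae,(bryophyte,(lycophyte,(monocot,eudicot))))` whose internal
nodes are named *viridiplantae*, *embryophyte*, *vascular*, *angiosperm*.
`lca_map()` assigns each gene-tree node the ladder LCA of its descendant
leaf ranks; a node is a *duplication* precisely when a child maps to the
same ladder node (the rule applies unchanged at polytomies, where any
repeat among child mappings marks a duplication). `find_group_roots()` and
`find_supergroup_roots()` share one traversal, parameterised by a boundary
rank `B` (angiosperm for groups, embryophyte for supergroups): starting at
the root, descend while `M(v)` is strictly above `B` or while `v` is a
duplication with `M(v) = B`; otherwise emit `v`. A duplication at the
boundary means `v` still spans two or more boundary-ancestral genes and must
be split further; a speciation at the boundary is exactly one ancestral
gene, i.e. one group. Emitted clades containing no angiosperm leaves
(bryophyte- or lycophyte-only clades that root a supergroup, algal leaves)
are reported as *unplaced lineage-specific clades* rather than groups.

Mapping is deliberately at rank granularity: within-rank duplications can
never move a group or supergroup boundary, so species-level reconciliation
(and loss counting) is out of scope. Nonplant leaves must be pruned before
classification — they exist to test monophyly and to root, not to be
classified — and `classify()` prunes them itself.

### Naming

The published figures ordered supergroup letters by layout, which is not
recoverable from data. famclade instead names deterministically: supergroups
are lettered in order of descending leaf count (ties broken by the
lexicographically smallest contained leaf id) and groups are numbered with
Roman numerals within each supergroup by the same rule. A leaf's half label
is `E` or `M` by its own rank, rendering as `A-I E`, `A-I M`, `B-II`, etc.
Two classifications of the same tree therefore always agree, and child order
or leaf relabelling (rank-preserving) cannot change the partition.

## Tree building

Distances: `p_distance()` counts mismatches over columns where both
sequences are ungapped; `model_distance()` corrects it either by the Poisson
closed form `d = -ln(1 - p)` or by pairwise maximum likelihood under the JTT
amino-acid model (`jtt_ml`). The JTT rate matrix is hard-coded from the
published exchangeability and frequency tables and scaled to one expected
substitution per site; the pairwise likelihood
`sum over sites of log(pi_x P(x -> y | d))` is maximised by scalar search on
`[0, 10]` to 1e-6. Distances are capped at 10 (with a warning) when the
mismatch proportion reaches 0.95 or the optimiser hits the bracket ceiling —
saturated pairs carry no usable signal and a finite cap keeps the matrix
well-defined. Columns containing `X` or gaps are ignored by the likelihood.

`neighbor_joining()` is the standard Q-criterion agglomeration, made fully
deterministic: exact ties in Q are broken by the lexicographically smallest
pair of cluster labels (a cluster is labelled by its smallest leaf), and a
negative limb length is clamped to zero with the deficit moved to the
sibling limb. The output is unrooted, stored with a basal trifurcation.
Maximum-likelihood and parsimony inference are intentionally not
reimplemented — every downstream stage (support mapping, clans,
classification) accepts any Newick tree, so externally built ML trees drop
in wherever a tree is consumed.

Bootstrap: `bootstrap_support()` resamples alignment columns with
replacement (one RNG substream per `(seed, replicate)` pair, so runs are
reproducible and replicates independent), rebuilds distances and the NJ
tree, and counts for each reference edge the fraction of replicates whose
split set contains that edge's bipartition. Only exact bipartition matches
count; compatible-but-unequal splits of polytomous references do not. A
replicate whose resampled columns leave some pair with no shared sites is
dropped and the denominator decremented. The default is the published 1,000
replicates; the test suite uses 25–100 for runtime. The support convention
is "higher than 75%": `collapse_low_support()` contracts internal edges with
support less than or equal to the threshold, leaving polytomies, and drops
the contracted edge's length.

## Clans and rooting

On an unrooted tree, a *clan* is a leaf set separable by cutting one edge.
`is_clan()` treats the stored rooting as arbitrary; singletons and the full
leaf set are clans by convention (the full set vacuously — only proper
subsets are scientifically informative, but the convention keeps the
complement identity `is_clan(s) == is_clan(complement(s))` exact).
`monophyly_report()` applies the test to every rank class: vertical
inheritance of the plant family is supported when the nonplant homologs form
a single clan. `root_by_outgroup()` refuses to root on a non-clan outgroup —
a silent fallback would manufacture a root that contradicts the tree — and
places the root on the separating edge at a configurable position
(default: midpoint; the published workflow rooted interactively without
stating a position), conserving total branch length.

## Filtering rules

Hit acceptance uses the published thresholds with their stated boundary
semantics: identity "at least 30%" (`>=`), E-value "lower than 1e-50"
(strict `<`), and the "no series of small fragments" rule operationalised as
hit coverage of at least 50% of the query length (the source gives no
number; coverage is the standard proxy and the fraction is configurable).
Sequence exclusion follows "gaps exceeding more than 30% of the alignment
length" as a strict `>`: a row with exactly 30% gaps stays.

Column trimming replaces an aligner-internal local-similarity score that is
not reproducible outside that aligner. The package's transparent stand-in
scores each column as the fraction of unordered non-gap residue pairs with a
strictly positive entry in a standard log-odds matrix (BLOSUM62 by default);
columns scoring below 0.40 are dropped, mirroring the "<40%" threshold.
Columns with fewer than two residues score 0. The score is monotone in the
threshold (lowering it never removes a kept column) and identical sequences
keep every column. The published iterative loop — exclude long-branch
sequences, re-align, rebuild — is a documented recipe
(`gap_filter()` → external re-alignment → rebuild) rather than an automated
stage, because re-alignment itself is out of scope.

## The simulator and what a green test establishes

`simulate_family()` evolves one root gene down a dated species tree:
duplications and losses are independent Poisson processes (rates `dup_rate`,
`loss_rate` per lineage per unit time) along each species-tree branch, every
surviving lineage is copied into both daughters at speciations, and the
simulation conditions on one surviving leaf by resampling with an
incremented seed substream (at most 1000 attempts). Truth labels come from
lineage identity at the epoch boundaries: a leaf's *true group* is its
ancestral lineage immediately before the monocot/eudicot split, its *true
supergroup* the lineage immediately before the embryophyte split — the
definition of the nomenclature, evaluated on the known history.

The stated world: species set `3 eudicots + 2 monocots + 1 lycophyte +
1 bryophyte + 1 alga` (the minimal set exercising every rank boundary);
epoch times in abstract units, 1.0 / 0.8 / 0.6 / 0.4 for the
viridiplantae / embryophyte / vascular / angiosperm splits — only their
order matters to the truth labels. Within-rank splits, which cannot affect
any boundary, are laid out as caterpillars with evenly interpolated times
below crown ages of 0.25 (eudicots) and 0.20 (monocots), values chosen once
as a realistic within-rank depth. Sequences evolve under JTT (or a 20-state
equal-rates model) with `subst_rate` substitutions per site per unit time;
the root sequence is drawn from equilibrium. The full-pipeline validation
uses `subst_rate = 0.5`, putting the deepest leaf-to-leaf path at 1.0
expected substitutions per site.

There is deliberately no indel process: the simulated alignment is exactly
the homologous sites, so simulator-based tests isolate tree inference and
classification, while the gap and column filters are tested on hand-built
fixtures with known answers. A green end-to-end test therefore establishes
that *given a correct alignment*, distances + NJ + rooting + classification
recover the true group partition; it says nothing about alignment quality,
model misspecification across real families, rate heterogeneity, or
horizontal transfer — all outside the simulator's world.

Two provable properties anchor the validation: with no gene loss,
classifying the true gene tree reproduces the truth partition exactly; with
loss, hidden duplications can only make the inferred partition coarser
(merges), never finer (splits), because losing every witness of a
duplication removes a boundary but cannot create one. Both are checked
empirically at scale in the acceptance suite.

## Numerical choices and edge cases

* Supports are fractions in `[0, 1]` internally; Newick supports greater
  than 1 are read as percentages and divided by 100. On writing, support
  sits in the internal-label position of each edge's child node.
* Branch lengths serialise at 15 significant digits, so read-write
  round-trips preserve lengths to 1e-12 (the stock ape writer truncates).
* Alignment columns are 0-based half-open programmatically and 1-based in
  written reports.
* Gap characters `-` and `.` are both accepted and normalised to `-`; `X`
  is a residue, not a gap.
* A distance matrix must be symmetric with a zero diagonal and finite
  entries; saturation is capped at 10 as above.
* NJ on two taxa returns the single split with the distance divided evenly
  across the two limbs.
* One-gene families are representable (a single-leaf tree keeps its
  root-to-tip length) and classify to a single trivial group.

## Known limitations

* Support collapse interacts with the boundary traversal asymmetrically:
  collapsing a polytomy that itself maps to *angiosperm* merges groups (the
  intended behaviour for unresolved angiosperm clades), but collapsing the
  edge above an angiosperm speciation whose parent maps to *vascular* or
  higher lifts the eudicot and monocot clades past the boundary and splits
  the group instead. "Collapse only merges" is therefore guaranteed only
  when the resulting polytomy maps to the boundary rank itself; the package
  follows the traversal rules and reports whatever the collapsed tree
  supports.
* Paraphyletic assemblages are never emitted as labels; they can arise in
  published classifications only via support collapse producing polytomies.
* No duplication-loss reconciliation at species granularity, no dated
  reconciliation, no explicit horizontal-transfer detection (the clan test
  provides the monophyly evidence), no rate-heterogeneity models, and no
  alignment construction — aligned FASTA from any aligner is accepted.
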