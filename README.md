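# famclade

Evolutionary classification of plant gene families into **groups** and
**supergroups**.

## The problem

Large transporter-like gene families in plants (ammonium transporters AMT1/
AMT2, nitrate transporters NRT1/NRT2, peptide transporters PTR, ...) expand
and contract by repeated gene duplication and loss. A useful nomenclature for
such families is evolutionary rather than functional: a **group** is the set
of family members descended from a single gene that was present in the last
common ancestor of monocots and eudicots, and groups are united into a
**supergroup** when the duplications separating them predate the
bryophyte/vascular-plant (embryophyte) split. Within a group, leaves carry an
**E** (eudicot) or **M** (monocot) half label. famclade implements this
classification as an algorithm, together with every pipeline stage around it,
for people studying gene-family evolution across plant genomes.

## The method

Leaves of a rooted gene tree are mapped to the fixed five-rank ladder

```
(green_algae, (bryophyte, (lycophyte, (monocot, eudicot))))
```

with internal nodes *viridiplantae > embryophyte > vascular > angiosperm*.
Each gene-tree node `v` gets the rank-ladder LCA `M(v)` of its descendant
leaf ranks (computed post-order); `v` is a **duplication** iff some child `c`
has `M(c) = M(v)`, else a speciation. A pre-order traversal then descends
while `M(v)` lies strictly above a boundary rank, or while a duplication maps
exactly to the boundary, and emits the first node failing both tests:
boundary `angiosperm` yields group roots, boundary `embryophyte` yields
supergroup roots. Emitted clades without angiosperm leaves are reported as
unplaced lineage-specific clades.

Around this core the package provides homolog-hit filtering (identity >= 30%,
E-value < 1e-50, coverage-based fragment rejection), gap-based sequence
exclusion (> 30% gaps), similarity-based column trimming (< 40% positive-pair
score), Poisson and JTT maximum-likelihood protein distances, deterministic
neighbor joining, bootstrap bipartition support (1,000 replicates by
default, reported when > 75%), clan-based monophyly testing on unrooted
trees, outgroup rooting, member-count tables, and a birth-death simulator of
gene families along the ranked species tree that supplies ground-truth group
labels for end-to-end validation.

## Worked example

```r
library(famclade)
tax <- default_species()
# a family with one pre-angiosperm duplication, rooted on the alga
phy <- read_newick("((b1_1:1,((e1_1:1,m1_1:1):1,(e2_1:1,m2_1:1):1):1):1,a1_1:1);")
cls <- classify(phy, tax)
print(cls)
print(cls$leaves, row.names = FALSE)
```

```
Gene-family classification: 1 supergroup(s), 2 group(s), 4/6 leaves placed
Unplaced lineage-specific clades: 2
 leaf_id supergroup group half  label
    b1_1          A  <NA> none   <NA>
    e1_1          A     I    E  A-I E
    m1_1          A     I    M  A-I M
    e2_1          A    II    E A-II E
    m2_1          A    II    M A-II M
    a1_1       <NA>  <NA> none   <NA>
```

The duplication maps to *angiosperm* (below the embryophyte boundary), so
the two eudicot+monocot clades become groups I and II of a single supergroup
A; the bryophyte leaf roots the supergroup but belongs to no group, and the
algal outgroup is outside the supergroup altogether.

## Analysis workflow

`analysis/01_simulate_families.R` ... `06_report_tables.R` run the pipeline
as a narrative: simulate a cohort of families with known histories, filter
and trim, build NJ trees with bootstrap support, test rank monophyly and
root on the algae, classify and validate against the simulated truth, and
rebuild member-count tables. Each script prints what it found and writes its
tables under `results/`.

## Acceptance script

`scripts/acceptance.R` re-runs the package's end-to-end computation from
scratch: it recomputes the member-count aggregates from the packaged count
table, then simulates a family, estimates JTT distances, builds and
bootstraps the NJ tree, tests clans, roots on the algae, classifies, and
compares the inferred group partition with the simulated truth, writing its
JSON report to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
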