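# the ladder-shaped reference gene tree: one gene per rank
ladder_tree <- function() {
  read_newick("(a1_1:1,(b1_1:1,(l1_1:1,(m1_1:1,e1_1:1):1):1):1);")
}

test_that("LCA mapping and duplication labelling follow the rank ladder", {
  tax <- fixture_taxonomy(nonplant = FALSE)
  ann <- lca_map(ladder_tree(), tax)
  internal <- ann[ann$event != "leaf", ]
  # one gene per rank: every internal node is a speciation
  expect_true(all(internal$event == "speciation"))
  expect_setequal(internal$mapping,
                  c("viridiplantae", "embryophyte", "vascular", "angiosperm"))
  # cherry of two eudicots (node 5): duplication mapping to eudicot
  ann2 <- lca_map(read_newick("((e1_1:1,e2_1:1):1,m1_1:1);"), tax)
  expect_equal(ann2$mapping[ann2$node == 5], "eudicot")
  expect_equal(ann2$event[ann2$node == 5], "duplication")
  # eudicot + monocot children (root, node 4): angiosperm speciation
  expect_equal(ann2$mapping[ann2$node == 4], "angiosperm")
  expect_equal(ann2$event[ann2$node == 4], "speciation")
  # outgroup must be pruned first
  expect_error(lca_map(read_newick("((np_1:1,e1_1:1):1,m1_1:1);"),
                       fixture_taxonomy()), "prune outgroup")
})

test_that("group roots split at ancestral-angiosperm duplications", {
  tax <- fixture_taxonomy(nonplant = FALSE)
  t1 <- ladder_tree()
  ann <- lca_map(t1, tax)
  g <- find_group_roots(t1, ann)
  # exactly one emitted root containing angiosperm leaves: the (m1,e1) node
  sets <- lapply(g, function(v) {
    if (v <= 5) t1$tip.label[v] else ape::extract.clade(t1, v)$tip.label
  })
  angio <- sets[vapply(sets, function(s) any(grepl("^[em]", s)), logical(1))]
  expect_length(angio, 1)
  expect_setequal(angio[[1]], c("m1_1", "e1_1"))

  # duplication at angiosperm -> two groups
  t2 <- read_newick("(((e1_1:1,m1_1:1):1,(e2_1:1,m2_1:1):1):1,b1_1:1);")
  cls2 <- classify(t2, tax)
  expect_length(cls2$group_roots, 2)
  expect_length(cls2$supergroup_roots, 1)
  lv <- cls2$leaves
  expect_equal(lv$group[lv$leaf_id == "m1_1"],
               lv$group[lv$leaf_id == "e1_1"])
  expect_equal(sort(unique(lv$group[!is.na(lv$group)])), c("I", "II"))

  # unresolved polytomy of two eudicot clades and one monocot clade at an
  # angiosperm speciation: a single group spanning all three
  t3 <- read_newick("(((e1_1:1,e1_2:1):1,(e2_1:1,e2_2:1):1,(m1_1:1,m2_1:1):1):1,b1_1:1);")
  cls3 <- classify(t3, tax)
  expect_length(cls3$group_roots, 1)
  expect_equal(sum(cls3$leaves$group == "I", na.rm = TRUE), 6)
})

test_that("supergroup roots split at pre-embryophyte duplications", {
  tax <- fixture_taxonomy(nonplant = FALSE)
  # duplication at embryophyte: two supergroups
  t1 <- read_newick("((b1_1:1,(e1_1:1,m1_1:1):1):1,(b1_2:1,(e2_1:1,m2_1:1):1):1);")
  cls1 <- classify(t1, tax)
  expect_length(cls1$supergroup_roots, 2)
  expect_length(cls1$group_roots, 2)     # one group in each supergroup
  lv <- cls1$leaves
  expect_false(lv$supergroup[lv$leaf_id == "e1_1"] ==
                 lv$supergroup[lv$leaf_id == "e2_1"])
  # duplication below the embryophyte split: one supergroup, two groups
  t2 <- read_newick("(((e1_1:1,m1_1:1):1,(e2_1:1,m2_1:1):1):1,b1_1:1);")
  cls2 <- classify(t2, tax)
  expect_length(cls2$supergroup_roots, 1)
  expect_length(cls2$group_roots, 2)
  # ladder tree: one supergroup
  expect_length(classify(ladder_tree(), tax)$supergroup_roots, 1)
})

test_that("classification naming is deterministic with E/M halves", {
  tax <- fixture_taxonomy(nonplant = FALSE)
  cls <- classify(ladder_tree(), tax)
  lv <- cls$leaves
  expect_equal(lv$label[lv$leaf_id == "e1_1"], "A-I E")
  expect_equal(lv$label[lv$leaf_id == "m1_1"], "A-I M")
  expect_equal(lv$half[lv$leaf_id == "b1_1"], "none")
  expect_true(is.na(lv$group[lv$leaf_id == "a1_1"]))
  # bigger supergroups get earlier letters; groups numbered by size
  t2 <- read_newick(paste0(
    "((b1_1:1,(e1_1:1,m1_1:1):1):1,",
    "(b1_2:1,((e2_1:1,m2_1:1):1,((e3_1:1,e3_2:1):1,(m1_2:1,m2_2:1):1):1):1):1);"))
  cls2 <- classify(t2, tax)
  lv2 <- cls2$leaves
  # the 7-leaf supergroup is A; within it the 4-leaf group is I
  expect_equal(unname(lv2$supergroup[lv2$leaf_id == "e3_1"]), "A")
  expect_equal(unname(lv2$label[lv2$leaf_id == "e3_1"]), "A-I E")
  expect_equal(unname(lv2$label[lv2$leaf_id == "e2_1"]), "A-II E")
  expect_equal(unname(lv2$supergroup[lv2$leaf_id == "e1_1"]), "B")
  # child order does not matter
  t2b <- read_newick(paste0(
    "((b1_2:1,(((m1_2:1,m2_2:1):1,(e3_2:1,e3_1:1):1):1,(m2_1:1,e2_1:1):1):1):1,",
    "((m1_1:1,e1_1:1):1,b1_1:1):1);"))
  cls2b <- classify(t2b, tax)
  m <- merge(lv2, cls2b$leaves, by = "leaf_id")
  expect_true(all(m$label.x == m$label.y | (is.na(m$label.x) & is.na(m$label.y))))
})

test_that("nonplant leaves are pruned and unplaced clades reported", {
  tax <- fixture_taxonomy()
  t1 <- read_newick(paste0("((np_1:1,np_2:1):1,",
                           "(a1_1:1,(b1_1:1,(l1_1:1,(m1_1:1,e1_1:1):1):1):1):1);"))
  cls <- classify(t1, tax)
  expect_false(any(grepl("^np", cls$leaves$leaf_id)))
  # algae, bryophyte and lycophyte leaves are unplaced lineage-specific clades
  expect_setequal(unlist(cls$unplaced), c("a1_1", "b1_1", "l1_1"))
  expect_length(cls$supergroup_roots, 1)
})

test_that("classification respects support collapse", {
  tax <- fixture_taxonomy(nonplant = FALSE)
  # with full resolution the eudicot clade E1 and the (E2, M) clade are two
  # groups; collapsing the weak edge leaves a rank-pure polytomy that maps
  # to angiosperm with no angiosperm-mapped child, i.e. a single group
  t <- read_newick(paste0(
    "(((e1_1:1,e1_2:1)0.95:1,((e2_1:1,e2_2:1)0.95:1,(m1_1:1,m2_1:1)0.95:1)0.5:1)0.95:1,",
    "b1_1:1)1;"))
  cls_keep <- classify(t, tax)
  expect_length(cls_keep$group_roots, 2)
  cls_coll <- classify(t, tax, collapse_threshold = 0.75)
  expect_length(cls_coll$group_roots, 1)
  # collapsing can only merge groups, never split them
  lvk <- cls_keep$leaves; lvc <- cls_coll$leaves
  angio <- lvk$half %in% c("E", "M")
  key_k <- paste(lvk$supergroup, lvk$group)[angio]
  key_c <- paste(lvc$supergroup, lvc$group)[match(lvk$leaf_id, lvc$leaf_id)][angio]
  expect_equal(anyDuplicated(unique(data.frame(key_k, key_c))$key_k), 0)
})

test_that("partition comparison counts merges and splits", {
  tax <- fixture_taxonomy(nonplant = FALSE)
  cls <- classify(read_newick("(((e1_1:1,m1_1:1):1,(e2_1:1,m2_1:1):1):1,b1_1:1);"),
                  tax)
  truth2 <- data.frame(leaf = c("e1_1", "m1_1", "e2_1", "m2_1"),
                       true_group = c(1, 1, 2, 2))
  expect_true(compare_partitions(cls, truth2)$exact_match)
  # inferred merge of the two truth groups
  cls1 <- classify(read_newick("(((e1_1:1,m1_1:1):1,(e2_1:1,m2_1:1):1):1,b1_1:1);"),
                   tax, collapse_threshold = NULL)
  merged <- cls1
  merged$leaves$group <- "I"
  cp <- compare_partitions(merged, truth2)
  expect_false(cp$exact_match)
  expect_equal(cp$merges, 1)
  expect_equal(cp$splits, 0)
  # truth group broken across inferred groups
  truth1 <- data.frame(leaf = c("e1_1", "m1_1", "e2_1", "m2_1"),
                       true_group = 1)
  cp2 <- compare_partitions(cls, truth1)
  expect_equal(cp2$splits, 1)
  expect_equal(cp2$merges, 0)
  expect_error(compare_partitions(cls, data.frame(leaf = "e9_9",
                                                  true_group = 1)),
               "leaf sets")
})

test_that("groups partition the angiosperm leaves on random simulations", {
  tax <- fixture_taxonomy(nonplant = FALSE)
  for (s in 1:15) {
    h <- simulate_history(sim_config(dup_rate = 0.5, loss_rate = 0.2,
                                     seed = 100 + s))
    tt <- true_tree(h)
    cls <- classify(tt, tax)
    lv <- cls$leaves
    angio <- lv$half %in% c("E", "M")
    expect_true(all(!is.na(lv$group[angio])))
    expect_true(all(!is.na(lv$supergroup[angio])))
    expect_true(all(is.na(lv$group[!angio])))
    # groups nest inside exactly one supergroup
    gs <- unique(lv[angio, c("supergroup", "group")])
    expect_equal(anyDuplicated(paste(gs$supergroup, gs$group)), 0)
  }
})
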