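test_that("zero-rate simulation mirrors the species tree exactly", {
  fam <- simulate_family(sim_config(dup_rate = 0, loss_rate = 0,
                                    seq_length = 50, seed = 3))
  tax <- fixture_taxonomy(nonplant = FALSE)
  expect_setequal(fam$tree$tip.label, paste0(tax$abbrev, "_1"))
  # gene tree isomorphic to the dated species tree
  expect_true(is_clan(fam$tree, c("m1_1", "m2_1", "e1_1", "e2_1", "e3_1")))
  expect_true(is_clan(fam$tree, c("e1_1", "e2_1", "e3_1")))
  # all angiosperm leaves in one true group and one true supergroup
  expect_equal(length(unique(fam$truth$true_group)), 1)
  expect_equal(length(unique(fam$truth$true_supergroup)), 1)
  # classification of the true tree assigns everything to supergroup A
  cls <- classify(fam$tree, tax)
  expect_true(all(cls$leaves$supergroup[cls$leaves$half != "none"] == "A"))
  expect_true(all(cls$leaves$group[cls$leaves$half != "none"] == "I"))
})

test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(dup_rate = 0.4, loss_rate = 0.1, seq_length = 80,
                    seed = 77)
  f1 <- simulate_family(cfg)
  f2 <- simulate_family(cfg)
  expect_identical(f1$history$segments, f2$history$segments)
  expect_identical(unclass(f1$alignment), unclass(f2$alignment))
  expect_identical(write_newick(f1$tree), write_newick(f2$tree))
  f3 <- simulate_family(sim_config(dup_rate = 0.4, loss_rate = 0.1,
                                   seq_length = 80, seed = 78))
  expect_false(identical(write_newick(f1$tree), write_newick(f3$tree)))
})

test_that("histories are well-formed event sequences", {
  for (s in 1:10) {
    h <- simulate_history(sim_config(dup_rate = 0.5, loss_rate = 0.3,
                                     seed = 50 + s))
    segs <- h$segments
    expect_true(all(segs$t_start >= segs$t_end))
    expect_true(all(segs$end_type %in%
                      c("duplication", "loss", "speciation", "leaf")))
    # every leaf traces an unbroken lineage to the root gene
    parent <- setNames(segs$parent, segs$id)
    for (id in segs$id[segs$end_type == "leaf"]) {
      steps <- 0
      while (!is.na(id)) {
        id <- parent[[as.character(id)]]
        steps <- steps + 1
        expect_lt(steps, 1e4)
      }
    }
    # gene-tree leaves == surviving (species, lineage) pairs
    tt <- true_tree(h)
    expect_setequal(tt$tip.label, segs$leaf[segs$end_type == "leaf"])
  }
})

test_that("truth labels follow lineage identity at the epoch boundaries", {
  # a duplication after the angiosperm split never creates a second group;
  # pre-angiosperm duplications with survivors on both sides do
  found_post <- FALSE; found_pre <- FALSE
  for (s in 1:60) {
    h <- simulate_history(sim_config(dup_rate = 0.4, loss_rate = 0,
                                     seed = 200 + s))
    segs <- h$segments
    truth <- truth_from_history(h)
    dups <- segs[segs$end_type == "duplication", ]
    ang <- h$cfg$epoch_times[["angiosperm"]]
    vir <- h$cfg$epoch_times[["viridiplantae"]]
    if (nrow(dups) == 0) next
    if (all(dups$t_end < ang)) {
      found_post <- TRUE
      expect_equal(length(unique(truth$true_group)), 1,
                   info = paste("seed", 200 + s))
    }
    if (length(unique(truth$true_group)) > 1) found_pre <- TRUE
    # groups refine supergroups
    map <- unique(truth[c("true_group", "true_supergroup")])
    expect_equal(anyDuplicated(map$true_group), 0)
  }
  expect_true(found_post)
  expect_true(found_pre)
})

test_that("lineage counts at the group boundary match the birth process", {
  # with rate 0.5 over the 0.6 time units from root to the angiosperm
  # split, E[lineages] = exp(0.5 * 0.6) ~ 1.35
  n <- 400
  counts <- vapply(seq_len(n), function(s) {
    h <- simulate_history(sim_config(dup_rate = 0.5, loss_rate = 0,
                                     seed = 1000 + s))
    length(unique(truth_from_history(h)$true_group))
  }, numeric(1))
  expected <- exp(0.5 * 0.6)
  se <- stats::sd(counts) / sqrt(n)
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})

test_that("classifying the true tree recovers the truth partition (mu = 0)", {
  tax <- fixture_taxonomy(nonplant = FALSE)
  for (s in 1:40) {
    h <- simulate_history(sim_config(dup_rate = 0.4, loss_rate = 0,
                                     seed = 300 + s))
    cls <- classify(true_tree(h), tax)
    cp <- compare_partitions(cls, truth_from_history(h))
    expect_true(cp$exact_match, info = paste("seed", 300 + s))
  }
})

test_that("with gene loss the inferred partition only coarsens the truth", {
  tax <- fixture_taxonomy(nonplant = FALSE)
  for (s in 1:40) {
    h <- simulate_history(sim_config(dup_rate = 0.4, loss_rate = 0.25,
                                     seed = 400 + s))
    tt <- true_tree(h)
    if (length(tt$tip.label) < 2) next
    cls <- classify(tt, tax)
    cp <- compare_partitions(cls, truth_from_history(h))
    expect_equal(cp$splits, 0, info = paste("seed", 400 + s))
  }
})

test_that("sequence evolution follows the substitution model", {
  # long branch: mismatch proportion near the model's expectation
  cfg <- sim_config(dup_rate = 0, loss_rate = 0, seq_length = 4000,
                    subst_rate = 0.25, seed = 12)
  fam <- simulate_family(cfg)
  # a1 and e1 are separated by 2.0 time units = 0.5 substitutions/site
  p <- p_distance(fam$alignment[["a1_1"]], fam$alignment[["e1_1"]])$p
  mod <- substitution_model("jtt")
  P <- transition_probs(0.5, mod)
  p_exp <- 1 - sum(mod$freqs * diag(P))
  expect_lt(abs(p - p_exp), 0.03)
  d <- model_distance(fam$alignment[["a1_1"]], fam$alignment[["e1_1"]],
                      "jtt_ml")
  expect_lt(abs(d - 0.5), 0.06)
})
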