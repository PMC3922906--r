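test_that("p-distance counts mismatches over shared non-gap columns", {
  expect_equal(p_distance("ACDEFGHIKL", "ACDEFGHIKL")$p, 0)
  pd <- p_distance("ACDEFGHIKL", "ACDEFGHIAA")
  expect_equal(pd$p, 0.2)
  expect_equal(pd$n_shared, 10)
  # gapped fixture: 12 columns, 10 shared, 3 of them differ
  a <- "AC-EFGHIKLMN"
  b <- "ACDE-GHAAAMN"
  pd <- p_distance(a, b)
  expect_equal(pd$n_shared, 10)
  expect_equal(pd$p, 0.3)
  expect_error(p_distance("A-", "-A"), "no shared columns")
  expect_error(p_distance("AC", "ACD"), "equal length")
})

test_that("model distances match closed forms and the JTT oracle", {
  same <- strrep("L", 50)
  expect_equal(model_distance(same, same, "poisson"), 0)
  expect_equal(model_distance(same, same, "jtt_ml"), 0)
  # poisson closed form at p = 0.5
  a <- paste0(strrep("A", 10), strrep("C", 10))
  b <- paste0(strrep("A", 10), strrep("D", 10))
  expect_equal(model_distance(a, b, "poisson"), log(2))
  # saturated pairs cap at 10 with a warning
  x <- strrep("A", 40); y <- strrep("C", 40)
  expect_warning(d <- model_distance(x, y, "jtt_ml"), "capped")
  expect_equal(d, 10)
  # cross-check jtt_ml against phangorn's independent JTT implementation
  skip_if_not_installed("phangorn")
  set.seed(3)
  mod <- substitution_model("jtt")
  L <- 2000
  root <- sample.int(20, L, TRUE, prob = mod$freqs)
  P <- transition_probs(0.3, mod)
  evolve <- function(st) {
    out <- integer(L)
    for (s in 1:20) {
      i <- which(st == s)
      if (length(i)) out[i] <- sample.int(20, length(i), TRUE, prob = P[s, ])
    }
    out
  }
  pair <- c(x = paste0(AA_ORDER[root], collapse = ""),
            y = paste0(AA_ORDER[evolve(root)], collapse = ""))
  mine <- model_distance(pair[1], pair[2], "jtt_ml")
  pd <- phangorn::phyDat(t(vapply(strsplit(tolower(pair), ""), identity,
                                  character(L))), type = "AA")
  oracle <- as.matrix(phangorn::dist.ml(pd, model = "JTT"))[1, 2]
  expect_equal(mine, oracle, tolerance = 1e-4)
})

test_that("the JTT rate matrix matches the published model's structure", {
  mod <- substitution_model("jtt")
  expect_equal(-sum(mod$freqs * diag(mod$Q)), 1)            # unit scaling
  expect_equal(rowSums(mod$Q), rep(0, 20), ignore_attr = TRUE)
  # detailed balance (reversibility): pi_i q_ij == pi_j q_ji
  F <- diag(mod$freqs) %*% mod$Q
  expect_lt(max(abs(F - t(F))), 1e-12)
  skip_if_not_installed("phangorn")
  expect_equal(unname(mod$freqs), unname(phangorn:::.JTT$bf),
               tolerance = 1e-5)
})

test_that("neighbor joining reproduces closed forms and small cases", {
  lab <- c("A", "B", "C")
  D <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3, 3,
              dimnames = list(lab, lab))
  tr <- neighbor_joining(D)
  limb <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(limb, c(A = 0.05, B = 0.15, C = 0.25))
  # n = 2: one split of total length d
  D2 <- matrix(c(0, .6, .6, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- neighbor_joining(D2)
  expect_equal(sum(t2$edge.length), 0.6)
  expect_error(neighbor_joining(D2 - .1), "negative|symmetric")
})

test_that("neighbor joining is consistent on additive distances", {
  gen <- read_newick("((A:0.1,B:0.2):0.1,(C:0.3,D:0.4):0);")
  D <- ape::cophenetic.phylo(gen)
  tr <- neighbor_joining(D[order(rownames(D)), order(colnames(D))])
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(gen)), 0,
               ignore_attr = TRUE)
  got <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_lt(max(abs(got - D)), 1e-9)
  # and agrees with ape's independent NJ topology on random instances
  set.seed(21)
  for (i in 1:10) {
    gen <- random_tree(sample(5:10, 1))
    D <- ape::cophenetic.phylo(gen)
    mine <- neighbor_joining(D)
    apes <- ape::nj(D)
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(apes)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bipartitions enumerate exactly the internal splits", {
  q <- read_newick("((A,B),(C,D));")
  bp <- bipartitions(q)
  expect_length(bp, 1)
  expect_identical(bp[[1]], c("C", "D"))   # canonical side excludes 'A'
  star <- read_newick("(A,B,C,D,E);")
  expect_length(bipartitions(star), 0)
  # n - 3 splits on random binary trees; invariant under re-rooting
  set.seed(31)
  for (i in 1:30) {
    tr <- random_tree(sample(4:14, 1))
    bp <- bipartitions(tr)
    expect_length(bp, length(tr$tip.label) - 3)
    rerooted <- ape::root(tr, outgroup = sample(tr$tip.label, 1),
                          resolve.root = TRUE)
    expect_setequal(vapply(bipartitions(rerooted), paste, collapse = "|",
                           FUN.VALUE = character(1)),
                    vapply(bp, paste, collapse = "|",
                           FUN.VALUE = character(1)))
  }
})

test_that("support mapping counts exact split matches", {
  ref <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  reps <- list(read_newick("((A:1,B:1):1,(C:1,D:1):1);"),
               read_newick("((A:1,B:1):1,(C:1,D:1):1);"),
               read_newick("((A:1,C:1):1,(B:1,D:1):1);"))
  out <- support_from_trees(ref, reps)
  sup <- tree_support(out)
  expect_equal(sort(unname(sup[!is.na(sup)])), c(2 / 3, 2 / 3))
  expect_error(support_from_trees(ref, list(read_newick("((A,B),(C,E));"))),
               "leaf set")
})

test_that("bootstrap support is deterministic and saturates on clean signal", {
  set.seed(1)
  fam <- simulate_family(sim_config(dup_rate = 0, loss_rate = 0,
                                    seq_length = 400, subst_rate = 0.3,
                                    seed = 8))
  aln <- fam$alignment
  ref <- neighbor_joining(dist_matrix(aln, "poisson"))
  b1 <- bootstrap_support(aln, ref, replicates = 30, seed = 5,
                          model = "poisson")
  b2 <- bootstrap_support(aln, ref, replicates = 30, seed = 5,
                          model = "poisson")
  expect_identical(write_newick(b1), write_newick(b2))
  sup <- tree_support(b1)
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 1))
  # a clean, well-separated alignment supports every reference split fully
  expect_true(all(sup[!is.na(sup)] == 1))
})

test_that("low-support collapse is strict at the threshold", {
  t75 <- read_newick("((A:1,B:1)0.75:1,C:1,D:1);")
  expect_equal(collapse_low_support(t75)$Nnode, 1)   # collapsed at == 0.75
  t76 <- read_newick("((A:1,B:1)0.76:1,C:1,D:1);")
  expect_equal(collapse_low_support(t76)$Nnode, 2)
  # all supports 1: unchanged; all collapsed: star
  full <- read_newick("((A:1,B:1)1:1,(C:1,D:1)1:1,E:1);")
  expect_equal(ape::dist.topo(collapse_low_support(full), full), 0,
               ignore_attr = TRUE)
  weak <- read_newick("((A:1,B:1)0.5:1,(C:1,D:1)0.2:1,E:1);")
  star <- collapse_low_support(weak)
  expect_equal(star$Nnode, 1)
  expect_setequal(star$tip.label, c("A", "B", "C", "D", "E"))
})
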