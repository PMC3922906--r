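#' Default simulated species set
#'
#' The minimal configuration exercising every rank boundary of the ladder:
#' three eudicots, two monocots, one lycophyte, one bryophyte, one alga.
#'
#' @return Data.frame with columns `abbrev`, `species`, `rank`.
#' @export
default_species <- function() {
  data.frame(
    abbrev = c("e1", "e2", "e3", "m1", "m2", "l1", "b1", "a1"),
    species = c("Eudicotya una", "Eudicotya duo", "Eudicotya tria",
                "Monocotya una", "Monocotya duo", "Lycophyta una",
                "Bryophyta una", "Algaphyta una"),
    rank = c("eudicot", "eudicot", "eudicot", "monocot", "monocot",
             "lycophyte", "bryophyte", "green_algae"),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Epoch times are abstract units of time before present, strictly
#' decreasing from root to tips: the whole-green-plant (viridiplantae) root
#' at 1.0, the land-plant (embryophyte) split at 0.8, the vascular split at
#' 0.6 and the monocot/eudicot (angiosperm) split at 0.4. Within-rank
#' splits (not boundary-relevant) are laid out as a caterpillar with evenly
#' interpolated times below the rank's crown age (eudicot crown 0.25,
#' monocot crown 0.20).
#'
#' @param species Species table as in [default_species()].
#' @param epoch_times Named numeric vector of split times before present.
#' @param dup_rate Duplication rate (events per gene lineage per unit time).
#' @param loss_rate Loss rate (same units).
#' @param seq_length Number of simulated sites (amino acids).
#' @param subst_rate Expected substitutions per site per unit time.
#' @param model Sequence model: `"jtt"` or `"equal_rates_20state"`.
#' @param seed Integer seed; all outputs are deterministic given the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(species = default_species(),
                       epoch_times = c(viridiplantae = 1.0, embryophyte = 0.8,
                                       vascular = 0.6, angiosperm = 0.4,
                                       eudicot_crown = 0.25,
                                       monocot_crown = 0.20),
                       dup_rate = 0.3, loss_rate = 0, seq_length = 500L,
                       subst_rate = 0.5,
                       model = c("jtt", "equal_rates_20state"),
                       seed = 1L) {
  model <- match.arg(model)
  stopifnot(dup_rate >= 0, loss_rate >= 0, subst_rate >= 0, seq_length >= 1)
  et <- epoch_times
  stopifnot(et[["viridiplantae"]] > et[["embryophyte"]],
            et[["embryophyte"]] > et[["vascular"]],
            et[["vascular"]] > et[["angiosperm"]])
  validate_taxonomy(species)
  structure(list(species = species, epoch_times = et, dup_rate = dup_rate,
                 loss_rate = loss_rate, seq_length = as.integer(seq_length),
                 subst_rate = subst_rate, model = model,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# dated species tree as a recursive structure {name, time, children};
# leaves carry species abbreviations and time 0
species_tree <- function(cfg) {
  sp <- split(cfg$species$abbrev, cfg$species$rank)
  et <- cfg$epoch_times
  leaf <- function(ab) list(name = ab, time = 0, children = NULL)
  # within-rank caterpillar with evenly interpolated times below `crown`
  rank_clade <- function(abbrevs, crown) {
    if (length(abbrevs) == 1) return(leaf(abbrevs))
    times <- seq(crown, crown / 2, length.out = length(abbrevs) - 1)
    if (length(abbrevs) == 2) times <- crown
    node <- leaf(abbrevs[length(abbrevs)])
    for (i in rev(seq_len(length(abbrevs) - 1))) {
      node <- list(name = NA, time = times[i],
                   children = list(leaf(abbrevs[i]), node))
    }
    node
  }
  eud <- rank_clade(sp$eudicot, et[["eudicot_crown"]])
  mon <- rank_clade(sp$monocot, et[["monocot_crown"]])
  ang <- list(name = "angiosperm", time = et[["angiosperm"]],
              children = list(mon, eud))
  vas <- list(name = "vascular", time = et[["vascular"]],
              children = list(rank_clade(sp$lycophyte, et[["vascular"]] / 2),
                              ang))
  emb <- list(name = "embryophyte", time = et[["embryophyte"]],
              children = list(rank_clade(sp$bryophyte, et[["embryophyte"]] / 2),
                              vas))
  list(name = "viridiplantae", time = et[["viridiplantae"]],
       children = list(rank_clade(sp$green_algae, et[["viridiplantae"]] / 2),
                       emb))
}

#' Simulate the duplication-loss history of one gene family
#'
#' One root gene enters the species tree at the root epoch. Along every
#' species-tree branch each gene lineage independently experiences
#' duplications (rate `dup_rate`) and losses (rate `loss_rate`) as Poisson
#' processes; at speciations every surviving lineage is copied into both
#' daughter lineages. The simulation conditions on at least one surviving
#' leaf by resampling with an incremented seed substream (at most 1000
#' attempts).
#'
#' @param cfg A [sim_config()].
#' @return List of class `gene_history` with `segments` (the event table:
#'   one row per gene lineage segment, with `id`, `parent`, `t_start`,
#'   `t_end`, `end_type`, `species`, `leaf`), `attempt`, and `cfg`.
#' @export
simulate_history <- function(cfg) {
  st <- species_tree(cfg)
  for (attempt in seq_len(1000L)) {
    set.seed((cfg$seed + (attempt - 1L)) %% .Machine$integer.max)
    segs <- sim_attempt(st, cfg)
    if (any(segs$end_type == "leaf")) {
      return(structure(list(segments = segs, attempt = attempt, cfg = cfg),
                       class = "gene_history"))
    }
  }
  stop("gene family went extinct in 1000 attempts; lower loss_rate")
}

# one simulation attempt; returns the segment table
sim_attempt <- function(st, cfg) {
  env <- new.env()
  env$rows <- list()
  env$next_id <- 1L
  env$leaf_counter <- list()
  lam <- cfg$dup_rate; mu <- cfg$loss_rate
  new_seg <- function(parent, t_start) {
    id <- env$next_id
    env$next_id <- id + 1L
    list(id = id, parent = parent, t_start = t_start)
  }
  finish <- function(seg, t_end, end_type, species = NA_character_,
                     leaf = NA_character_) {
    env$rows[[length(env$rows) + 1L]] <-
      data.frame(id = seg$id, parent = seg$parent, t_start = seg$t_start,
                 t_end = t_end, end_type = end_type, species = species,
                 leaf = leaf, stringsAsFactors = FALSE)
  }
  # evolve one gene lineage down a species-tree branch ending at node `nd`
  walk <- function(seg, t_top, nd) {
    t <- t_top
    repeat {
      wait <- if (lam + mu > 0) rexp(1, lam + mu) else Inf
      t_next <- t - wait
      if (t_next <= nd$time) break
      if (runif(1) < lam / (lam + mu)) {
        finish(seg, t_next, "duplication")
        walk(new_seg(seg$id, t_next), t_next, nd)
        walk(new_seg(seg$id, t_next), t_next, nd)
        return(invisible())
      }
      finish(seg, t_next, "loss")
      return(invisible())
    }
    if (is.null(nd$children)) {
      k <- (env$leaf_counter[[nd$name]] %||% 0L) + 1L
      env$leaf_counter[[nd$name]] <- k
      finish(seg, 0, "leaf", species = nd$name,
             leaf = paste0(nd$name, "_", k))
    } else {
      finish(seg, nd$time, "speciation")
      for (ch in nd$children) walk(new_seg(seg$id, nd$time), nd$time, ch)
    }
  }
  root <- new_seg(NA_integer_, st$time)
  finish(root, st$time, "speciation")
  for (ch in st$children) walk(new_seg(root$id, st$time), st$time, ch)
  do.call(rbind, env$rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' True gene tree of a simulated history
#'
#' Prunes extinct lineages and suppresses the resulting unifurcations.
#' Branch lengths are time durations.
#'
#' @param history A `gene_history` from [simulate_history()].
#' @return A rooted `phylo` tree whose leaves are the surviving genes.
#' @export
true_tree <- function(history) {
  segs <- history$segments
  surv <- surviving_segments(segs)
  kids <- split(segs$id, segs$parent)
  build <- function(id) {
    row <- segs[segs$id == id, ]
    ch <- kids[[as.character(id)]]
    ch <- ch[ch %in% surv]
    len <- row$t_start - row$t_end
    if (row$end_type == "leaf") {
      return(list(label = row$leaf, len = len, support = NA_real_,
                  children = NULL))
    }
    sub <- lapply(ch, build)
    if (length(sub) == 1) {          # unifurcation: splice the branch
      sub[[1]]$len <- sub[[1]]$len + len
      return(sub[[1]])
    }
    list(label = NA_character_, len = len, support = NA_real_,
         children = sub)
  }
  root_id <- segs$id[is.na(segs$parent)]
  nd <- build(root_id)
  if (is.null(nd$children)) {
    # single survivor: a one-leaf tree keeping its root-to-tip length
    return(read_newick(paste0("(", nd$label, ":",
                              sprintf("%.15g", nd$len), ");")))
  }
  nd$len <- NA_real_                  # no branch above the root
  rlist_to_phylo(nd)
}

# ids of segments with at least one surviving descendant leaf
surviving_segments <- function(segs) {
  surv <- segs$id[segs$end_type == "leaf"]
  parent <- setNames(segs$parent, segs$id)
  out <- integer(0)
  for (id in surv) {
    v <- id
    while (!is.na(v) && !(v %in% out)) {
      out <- c(out, v)
      v <- parent[[as.character(v)]]
    }
  }
  out
}

#' Ground-truth group and supergroup labels of a simulated history
#'
#' Each surviving angiosperm leaf is traced to its ancestral gene lineage
#' immediately before the monocot/eudicot split (its true group) and
#' immediately before the embryophyte/bryophyte split (its true
#' supergroup).
#'
#' @param history A `gene_history`.
#' @return Data.frame with columns `leaf`, `true_group`, `true_supergroup`.
#' @export
truth_from_history <- function(history) {
  segs <- history$segments
  cfg <- history$cfg
  sp_rank <- setNames(cfg$species$rank, cfg$species$abbrev)
  is_leaf <- segs$end_type == "leaf"
  angio <- is_leaf & sp_rank[segs$species] %in% c("monocot", "eudicot")
  parent <- setNames(segs$parent, segs$id)
  t_start <- setNames(segs$t_start, segs$id)
  t_end <- setNames(segs$t_end, segs$id)
  ancestor_at <- function(id, T) {
    v <- id
    repeat {
      if (t_start[[as.character(v)]] > T && t_end[[as.character(v)]] <= T) {
        return(v)
      }
      v <- parent[[as.character(v)]]
      if (is.na(v)) return(segs$id[is.na(segs$parent)])
    }
  }
  Tg <- cfg$epoch_times[["angiosperm"]]
  Ts <- cfg$epoch_times[["embryophyte"]]
  data.frame(
    leaf = segs$leaf[angio],
    true_group = vapply(segs$id[angio], ancestor_at, numeric(1), T = Tg),
    true_supergroup = vapply(segs$id[angio], ancestor_at, numeric(1), T = Ts),
    stringsAsFactors = FALSE)
}

# evolve sequences down a tree under the chosen model; returns an alignment
evolve_sequences <- function(phy, cfg) {
  mod <- substitution_model(cfg$model)
  L <- cfg$seq_length
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  states <- vector("list", ntip + phy$Nnode)
  states[[root]] <- sample.int(20, L, replace = TRUE, prob = mod$freqs)
  eo <- ape::reorder.phylo(phy, "cladewise")
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1]; v <- eo$edge[k, 2]
    t <- cfg$subst_rate * eo$edge.length[k]
    P <- transition_probs(t, mod)
    parent_state <- states[[p]]
    child <- integer(L)
    for (s in 1:20) {
      idx <- which(parent_state == s)
      if (length(idx)) {
        child[idx] <- sample.int(20, length(idx), replace = TRUE,
                                 prob = P[s, ])
      }
    }
    states[[v]] <- child
  }
  seqs <- vapply(seq_len(ntip), function(v) {
    paste0(AA_ORDER[states[[v]]], collapse = "")
  }, character(1))
  as_alignment(setNames(seqs, phy$tip.label))
}

#' Simulate a complete gene family
#'
#' Composes [simulate_history()], [true_tree()], [truth_from_history()] and
#' sequence evolution: the root sequence is drawn from the model's
#' equilibrium frequencies and substitutions are applied along each gene
#' tree branch with an expected `subst_rate * duration` substitutions per
#' site. Outputs are deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with `alignment` (gap-free, the simulated homologous
#'   sites), `tree` (true rooted gene tree), `history`, `truth`, and
#'   `taxonomy` (the species table).
#' @export
simulate_family <- function(cfg = sim_config()) {
  history <- simulate_history(cfg)
  phy <- true_tree(history)
  truth <- truth_from_history(history)
  aln <- if (length(phy$tip.label) >= 1) evolve_sequences(phy, cfg) else NULL
  list(alignment = aln, tree = phy, history = history, truth = truth,
       taxonomy = history$cfg$species)
}
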