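# shared fixtures, generated in code

# taxonomy matching the simulator's default species plus a nonplant outgroup
fixture_taxonomy <- function(nonplant = TRUE) {
  tax <- default_species()
  if (nonplant) {
    tax <- rbind(tax, data.frame(abbrev = "np", species = "Nonplanta una",
                                 rank = "nonplant"))
  }
  tax
}

# write a small FASTA fixture and return its path
write_fasta_fixture <- function(seqs, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "fixture.fasta")
  write_fasta(seqs, path)
  path
}

# random leaf-labelled binary tree (via ape) with unique short labels
random_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n, tip.label = sprintf("t%02d", seq_len(n)))
  tr
}

# independent clan oracle: enumerate the leaf set below every edge of the
# tree (plus complements) and test membership directly
clan_oracle <- function(phy, leaves) {
  n <- length(phy$tip.label)
  leaves <- unique(leaves)
  if (length(leaves) %in% c(1L, n)) return(TRUE)
  ntip <- length(phy$tip.label)
  below <- function(v) {
    if (v <= ntip) return(phy$tip.label[v])
    unlist(lapply(phy$edge[phy$edge[, 1] == v, 2], below))
  }
  for (k in seq_len(nrow(phy$edge))) {
    side <- below(phy$edge[k, 2])
    if (setequal(side, leaves) ||
        setequal(setdiff(phy$tip.label, side), leaves)) {
      return(TRUE)
    }
  }
  FALSE
}
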