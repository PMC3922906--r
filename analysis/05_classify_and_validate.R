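#!/usr/bin/env Rscript
# Classify each rooted family into supergroups and groups and validate the
# inferred group partition against the simulator's truth labels.

suppressPackageStartupMessages(library(famclade))

out <- "results/classification"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
tax <- read_taxonomy("results/simulated/taxonomy.tsv")
fams <- read.table("results/simulated/cohort_summary.tsv", sep = "\t",
                   header = TRUE)

rows <- list()
for (fam in fams$family) {
  rooted_path <- file.path("results/rooted", paste0(fam, ".rooted.nwk"))
  if (!file.exists(rooted_path)) next
  phy <- read_newick(rooted_path)
  truth <- read.table(file.path("results/simulated", paste0(fam, ".truth.tsv")),
                      sep = "\t", header = TRUE)
  # classify both fully resolved and with the 75% support collapse
  cls <- classify(phy, tax)
  cls75 <- classify(phy, tax, collapse_threshold = 0.75)
  write.table(cls$leaves, file.path(out, paste0(fam, ".membership.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cp <- compare_partitions(cls, truth)
  cp75 <- compare_partitions(cls75, truth)
  rows[[fam]] <- data.frame(
    family = fam,
    true_groups = length(unique(truth$true_group)),
    inferred_groups = length(cls$group_roots),
    supergroups = length(cls$supergroup_roots),
    exact = cp$exact_match, merges = cp$merges, splits = cp$splits,
    exact_collapsed = cp75$exact_match)
}
tab <- do.call(rbind, rows)
write.table(tab, file.path(out, "validation_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("Group-partition recovery against the simulated truth (splits ",
        "indicate inference errors, merges mostly reflect gene loss):")
print(tab, row.names = FALSE)
message(sum(tab$exact), "/", nrow(tab),
        " families recovered exactly on the resolved tree")
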