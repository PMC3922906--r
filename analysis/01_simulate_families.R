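#!/usr/bin/env Rscript
# Simulate a cohort of gene families with known duplication/loss histories.
#
# Writes, per family: the protein alignment (FASTA), the true gene tree
# (Newick), the event history and the truth labels (TSV), plus the shared
# species taxonomy. Later scripts consume these artifacts.

suppressPackageStartupMessages(library(famclade))

seed <- local({
  a <- commandArgs(trailingOnly = TRUE)
  i <- which(a == "--seed")
  if (length(i) == 1 && i < length(a)) as.integer(a[i + 1]) else 20260917L
})
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

n_families <- 10
scenarios <- data.frame(
  family = sprintf("fam%02d", seq_len(n_families)),
  dup_rate = rep(c(0, 0.3, 0.3, 0.5, 0.5), 2),
  loss_rate = rep(c(0, 0, 0.2, 0, 0.2), 2))

write_taxonomy(default_species(), file.path(out, "taxonomy.tsv"))

summary <- list()
for (i in seq_len(nrow(scenarios))) {
  sc <- scenarios[i, ]
  cfg <- sim_config(dup_rate = sc$dup_rate, loss_rate = sc$loss_rate,
                    seq_length = 2000, subst_rate = 0.5,
                    seed = seed + i)
  fam <- simulate_family(cfg)
  prefix <- file.path(out, sc$family)
  write_fasta(unclass(fam$alignment), paste0(prefix, ".fasta"))
  write_newick(fam$tree, paste0(prefix, ".true.nwk"))
  write.table(fam$history$segments, paste0(prefix, ".events.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(fam$truth, paste0(prefix, ".truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary[[i]] <- data.frame(
    family = sc$family, dup_rate = sc$dup_rate, loss_rate = sc$loss_rate,
    genes = length(fam$tree$tip.label),
    true_groups = length(unique(fam$truth$true_group)),
    true_supergroups = length(unique(fam$truth$true_supergroup)))
}
summary <- do.call(rbind, summary)
write.table(summary, file.path(out, "cohort_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("Simulated ", nrow(summary), " families; gene counts ",
        min(summary$genes), "-", max(summary$genes),
        "; true group counts ", min(summary$true_groups), "-",
        max(summary$true_groups))
print(summary, row.names = FALSE)
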