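#' Pipeline configuration
#'
#' Bundles every stage's settings for [run_pipeline()]. Defaults are the
#' published settings: 30% identity, E-value < 1e-50, 40% column score,
#' 30% gap fraction, 1000 bootstrap replicates, 75% support threshold, and
#' JTT maximum-likelihood distances.
#'
#' @param alignment_path Aligned FASTA of the family members (required).
#' @param taxonomy_path Species taxonomy TSV (required).
#' @param out_dir Output directory for stage artifacts.
#' @param hits_path Optional 12-column hit table; when given (together with
#'   `query_fasta_path`), hit filtering runs first and only accepted
#'   subjects are retained in the alignment.
#' @param query_fasta_path FASTA of query sequences (for hit coverage).
#' @param filters A [filter_config()].
#' @param dist_model `"jtt_ml"` or `"poisson"`.
#' @param replicates,seed Bootstrap settings.
#' @param collapse_threshold Support threshold for collapsing before
#'   classification (`NULL` to skip collapsing).
#' @param outgroup_rank Rank used for rooting (default `green_algae`).
#' @param family_name Family label used in the member-count artifact.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(alignment_path, taxonomy_path, out_dir,
                            hits_path = NULL, query_fasta_path = NULL,
                            filters = filter_config(),
                            dist_model = "jtt_ml",
                            replicates = 1000L, seed = 1L,
                            collapse_threshold = 0.75,
                            outgroup_rank = "green_algae",
                            family_name = "family") {
  structure(list(alignment_path = alignment_path,
                 taxonomy_path = taxonomy_path, out_dir = out_dir,
                 hits_path = hits_path, query_fasta_path = query_fasta_path,
                 filters = filters, dist_model = dist_model,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 collapse_threshold = collapse_threshold,
                 outgroup_rank = outgroup_rank, family_name = family_name),
            class = "pipeline_config")
}

log_stage <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full classification pipeline
#'
#' Executes, in order: hit filtering (optional), gap filtering, column
#' trimming, distance estimation, neighbor joining, bootstrap support
#' mapping, the clan-based monophyly report, outgroup pruning and rooting,
#' group/supergroup classification, and member-count reporting. Every stage
#' writes its artifact under `cfg$out_dir` and logs a summary line; any
#' stage error aborts with the stage name.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a named list of artifact paths plus the
#'   classification object.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- list()
  out <- function(f) file.path(cfg$out_dir, f)

  taxonomy <- run_stage("taxonomy", read_taxonomy(cfg$taxonomy_path))
  aln <- run_stage("alignment", read_alignment(cfg$alignment_path))
  log_stage("alignment", length(aln), " sequences x ",
            alignment_length(aln), " columns")

  if (!is.null(cfg$hits_path)) {
    res <- run_stage("filter-hits", {
      hits <- read_hits(cfg$hits_path)
      qlen <- nchar(gsub("-", "", read_fasta(cfg$query_fasta_path),
                         fixed = TRUE))
      filter_hits(hits, qlen, cfg$filters)
    })
    art$accepted_hits <- write_hits(res$accepted, out("accepted_hits.tsv"))
    log_stage("filter-hits", nrow(res$accepted), " accepted / ",
              nrow(res$rejected), " rejected")
    keep <- names(aln) %in% c(res$accepted$subject_id, res$accepted$query_id)
    if (any(keep)) aln <- as_alignment(unclass(aln)[keep])
  }

  gf <- run_stage("gap-filter", gap_filter(aln, cfg$filters))
  log_stage("gap-filter", length(gf$kept), " kept, ",
            length(gf$excluded_ids), " excluded")
  tr <- run_stage("trim", trim_columns(gf$kept, cfg$filters))
  log_stage("trim", length(tr$kept_columns), "/",
            alignment_length(gf$kept), " columns kept")
  art$trimmed_alignment <- out("trimmed.fasta")
  write_fasta(unclass(tr$trimmed), art$trimmed_alignment)
  # kept columns reported 1-based inclusive
  writeLines(as.character(tr$kept_columns + 1L),
             art$kept_columns <- out("kept_columns.tsv"))

  D <- run_stage("distances", dist_matrix(tr$trimmed, cfg$dist_model))
  art$distances <- out("distances.tsv")
  write.table(D, art$distances, sep = "\t", quote = FALSE)
  phy <- run_stage("nj", neighbor_joining(D))
  art$nj_tree <- write_newick(phy, out("nj_tree.nwk"))
  sup_tree <- run_stage("bootstrap",
    bootstrap_support(tr$trimmed, phy, cfg$replicates, cfg$seed,
                      cfg$dist_model))
  art$supported_tree <- write_newick(sup_tree, out("supported_tree.nwk"))
  sup <- tree_support(sup_tree)
  log_stage("bootstrap", cfg$replicates, " replicates; median support ",
            signif(stats::median(sup, na.rm = TRUE), 3))

  mono <- run_stage("monophyly", monophyly_report(sup_tree, taxonomy))
  art$monophyly <- out("monophyly.tsv")
  write.table(mono, art$monophyly, sep = "\t", quote = FALSE,
              row.names = FALSE)
  log_stage("monophyly", sum(mono$clan), "/", nrow(mono),
            " classes form clans")

  ranks <- leaf_ranks(sup_tree$tip.label, taxonomy)
  og <- sup_tree$tip.label[ranks == cfg$outgroup_rank]
  if (length(og) == 0) {
    stop("pipeline stage 'root' failed: no leaves of outgroup rank ",
         cfg$outgroup_rank, call. = FALSE)
  }
  rooted <- run_stage("root", root_by_outgroup(sup_tree, og))
  art$rooted_tree <- write_newick(rooted, out("rooted_tree.nwk"))

  cls <- run_stage("classify",
    classify(rooted, taxonomy, cfg$collapse_threshold))
  art$membership <- out("membership.tsv")
  write.table(cls$leaves, art$membership, sep = "\t", quote = FALSE,
              row.names = FALSE)
  log_stage("classify", length(cls$supergroup_roots), " supergroup(s), ",
            length(cls$group_roots), " group(s)")

  assignments <- run_stage("report", {
    ab <- vapply(cls$leaves$leaf_id, function(lb) {
      cand <- taxonomy$abbrev[order(nchar(taxonomy$abbrev),
                                    decreasing = TRUE)]
      cand[startsWith(lb, cand)][1]
    }, character(1))
    data.frame(seq_id = cls$leaves$leaf_id, species_abbrev = ab,
               family = cfg$family_name, stringsAsFactors = FALSE)
  })
  counts <- count_table(assignments, taxonomy)
  art$counts <- write_count_table(counts, out("counts.tsv"))
  log_stage("report", sum(counts[[cfg$family_name]]), " members counted")

  invisible(c(art, list(classification = cls)))
}
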