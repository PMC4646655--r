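#' Run the pan-genome clustering pipeline on a set of proteomes
#'
#' All-vs-all local alignment, reciprocal-hit orthology, COG clustering,
#' core/accessory/unique classification and the presence/absence matrix, in
#' one call.
#'
#' @param proteins `data.frame` with `genome_id`, `gene_id`, `seq`.
#' @param params A [scoring_params()] object.
#' @param thresholds An [orthology_thresholds()] object.
#' @param reciprocal_best Use reciprocal best hits instead of the literal
#'   reciprocal-hit reading.
#' @param max_evalue Hit-retention cutoff for [all_vs_all()].
#' @param profile_hits Optional profile-search merge table for
#'   [merge_by_profile_hits()].
#' @return List with `hits`, `membership`, `summary` (classified),
#'   `pam` and `n_genomes`.
#' @export
run_pangenome_pipeline <- function(proteins, params = scoring_params(),
                                   thresholds = orthology_thresholds(),
                                   reciprocal_best = FALSE,
                                   max_evalue = 1e-3,
                                   profile_hits = NULL) {
  hits <- all_vs_all(proteins, params, max_evalue = max_evalue)
  genes <- data.frame(gene_id = proteins$gene_id,
                      genome_id = proteins$genome_id,
                      length = nchar(proteins$seq),
                      stringsAsFactors = FALSE)
  graph <- build_ortholog_graph(hits, genes, thresholds,
                                reciprocal_best = reciprocal_best)
  membership <- cluster_cogs(graph, genes)
  if (!is.null(profile_hits))
    membership <- merge_by_profile_hits(membership, profile_hits, thresholds)
  n_genomes <- length(unique(proteins$genome_id))
  summ <- classify_cogs(cog_summary(membership), n_genomes)
  list(hits = hits, membership = membership, summary = summ,
       pam = presence_absence_matrix(membership), n_genomes = n_genomes)
}

#' Per-COG alignments from a membership table
#'
#' Builds one protein alignment per selected COG via [progressive_msa()],
#' rows named by genome id. COGs with within-genome paralogs keep the first
#' gene per genome (sorted by gene id).
#'
#' @param membership COG membership table.
#' @param proteins Protein table (`gene_id`, `seq`).
#' @param cog_ids COGs to align (default: all).
#' @param params A [scoring_params()] object.
#' @return Named list of alignments.
#' @export
cog_alignments <- function(membership, proteins, cog_ids = NULL,
                           params = scoring_params()) {
  if (is.null(cog_ids)) cog_ids <- unique(membership$cog_id)
  seq_of <- setNames(proteins$seq, proteins$gene_id)
  out <- list()
  for (cid in cog_ids) {
    mem <- membership[membership$cog_id == cid, , drop = FALSE]
    mem <- mem[order(mem$genome_id, mem$gene_id), , drop = FALSE]
    mem <- mem[!duplicated(mem$genome_id), , drop = FALSE]
    seqs <- setNames(seq_of[mem$gene_id], mem$genome_id)
    out[[cid]] <- progressive_msa(seqs, params)
  }
  out
}

#' Does a tree contain a given leaf bipartition?
#'
#' Checks whether `tips | rest` is a (possibly trivial) split of the tree:
#' used to test recovery of planted clusters as clades.
#'
#' @param tree A `phylo` tree.
#' @param tips Character vector of leaf labels forming one side.
#' @return `TRUE` or `FALSE`.
#' @export
has_split <- function(tree, tips) {
  labs <- tree$tip.label
  stopifnot(all(tips %in% labs))
  other <- setdiff(labs, tips)
  if (length(tips) < 2L || length(other) < 2L) return(TRUE)
  anchor <- min(labs)
  side <- if (anchor %in% tips) tips else other
  key <- paste(sort(side), collapse = ",")
  key %in% tree_bipartitions(tree)
}
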