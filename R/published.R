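#' Pan-genome census of a genome collection from FASTA files
#'
#' End-to-end reproduction pipeline for a directory of genome FASTA files
#' (one genome per file): ORF calling, all-vs-all protein alignment,
#' reciprocal-hit clustering under both orthology readings (literal
#' reciprocal hits and reciprocal best hits), and the COG category census.
#' Intended for re-running the published 20-genome analysis once the GenBank
#' sequences have been downloaded; the sequences themselves are not
#' distributed with the package.
#'
#' @param genome_dir Directory containing one FASTA file per genome.
#' @param min_codons Minimum ORF length for [find_orfs()].
#' @param thresholds An [orthology_thresholds()] object.
#' @return A list with, per mode (`literal`, `reciprocal_best`): the COG
#'   category counts, the classified summary, and mean per-genome category
#'   fractions.
#' @export
published_cog_census <- function(genome_dir, min_codons = 30L,
                                 thresholds = orthology_thresholds()) {
  files <- list.files(genome_dir, pattern = "\\.(fa|fasta|fna)$",
                      full.names = TRUE)
  if (!length(files)) stop("no FASTA files found in ", genome_dir)
  proteins <- list()
  for (f in files) {
    recs <- read_fasta(f)
    gid <- sub("\\.(fa|fasta|fna)$", "", basename(f))
    for (k in seq_len(nrow(recs))) {
      orfs <- find_orfs(recs$seq[k], genome_id = gid,
                        min_codons = min_codons)
      proteins[[length(proteins) + 1L]] <-
        data.frame(genome_id = gid, gene_id = orfs$gene_id,
                   seq = orfs$protein, stringsAsFactors = FALSE)
    }
  }
  proteins <- do.call(rbind, proteins)
  out <- list()
  for (mode in c("literal", "reciprocal_best")) {
    res <- run_pangenome_pipeline(proteins, thresholds = thresholds,
                                  reciprocal_best = mode == "reciprocal_best")
    fr <- genome_fractions(res$membership, res$summary)
    out[[mode]] <- list(
      counts = c(total = nrow(res$summary),
                 table(res$summary$category)),
      summary = res$summary,
      mean_fractions = colMeans(fr[, c("core", "accessory", "unique")]))
  }
  out
}
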