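#' Thresholds for the reciprocal-hit orthology rule
#'
#' A gene pair is orthologous when both directional hits pass e-value <=
#' `evalue_max` and the alignment covers at least `coverage_min` of the
#' shorter sequence. For short sequences (shorter partner under
#' `short_length` residues) the e-value requirement is waived when both hits
#' have percent identity >= `short_identity_min`; the coverage requirement
#' always stands. Profile-search merges use `profile_evalue_max`.
#'
#' @param evalue_max Reciprocal-hit e-value cutoff.
#' @param coverage_min Minimum alignment length as a fraction of the shorter
#'   sequence.
#' @param short_length Length (aa) below which the identity exception applies.
#' @param short_identity_min Percent identity for the short-sequence route.
#' @param profile_evalue_max E-value cutoff for profile-hit merging.
#' @return An object of class `orthology_thresholds`.
#' @export
orthology_thresholds <- function(evalue_max = 1e-5, coverage_min = 0.5,
                                 short_length = 100, short_identity_min = 35,
                                 profile_evalue_max = 1e-5) {
  stopifnot(coverage_min > 0, coverage_min <= 1, evalue_max > 0,
            short_length > 0, short_identity_min >= 0,
            profile_evalue_max > 0)
  structure(list(evalue_max = evalue_max, coverage_min = coverage_min,
                 short_length = short_length,
                 short_identity_min = short_identity_min,
                 profile_evalue_max = profile_evalue_max),
            class = "orthology_thresholds")
}

#' Decide orthology for one gene pair from its reciprocal hits
#'
#' @param hit_ab,hit_ba One-row hit records (lists or data.frame rows) with
#'   fields `evalue`, `align_len`, `pident`, or `NULL` when the direction has
#'   no hit (the pair is then not orthologous).
#' @param len_a,len_b Sequence lengths (aa), positive.
#' @param thresholds An [orthology_thresholds()] object.
#' @return `TRUE` or `FALSE`.
#' @export
ortholog_pair <- function(hit_ab, hit_ba, len_a, len_b,
                          thresholds = orthology_thresholds()) {
  if (len_a <= 0 || len_b <= 0) stop("sequence lengths must be positive")
  if (is.null(hit_ab) || is.null(hit_ba)) return(FALSE)
  shorter <- min(len_a, len_b)
  cov_ok <- hit_ab$align_len >= thresholds$coverage_min * shorter &&
    hit_ba$align_len >= thresholds$coverage_min * shorter
  if (!cov_ok) return(FALSE)
  e_ok <- hit_ab$evalue <= thresholds$evalue_max &&
    hit_ba$evalue <= thresholds$evalue_max
  if (e_ok) return(TRUE)
  shorter < thresholds$short_length &&
    hit_ab$pident >= thresholds$short_identity_min &&
    hit_ba$pident >= thresholds$short_identity_min
}

#' Build the ortholog graph from a hit table
#'
#' One undirected edge per unordered gene pair whose reciprocal hits satisfy
#' [ortholog_pair()]. When several hits exist for a direction, the hit with
#' the lowest e-value (ties broken by highest bit score) is used. With
#' `reciprocal_best = TRUE` each gene must additionally be the other's
#' best-scoring hit within its genome (classic reciprocal best hits).
#'
#' @param hits Hit table ([parse_hits_table()] layout).
#' @param genes `data.frame` with `gene_id`, `genome_id` and `length` (aa)
#'   for every gene in the analysis (including genes without hits).
#' @param thresholds An [orthology_thresholds()] object.
#' @param reciprocal_best Require reciprocal best hits per genome pair.
#' @return An [igraph][igraph::graph_from_data_frame] graph whose vertices
#'   are all gene ids.
#' @export
build_ortholog_graph <- function(hits, genes,
                                 thresholds = orthology_thresholds(),
                                 reciprocal_best = FALSE) {
  stopifnot(all(c("gene_id", "genome_id", "length") %in% names(genes)))
  if (any(genes$length <= 0)) stop("sequence lengths must be positive")
  unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)), genes$gene_id)
  if (length(unknown))
    stop("hit references unknown gene id: ", paste(unknown, collapse = ", "))
  lens <- setNames(genes$length, genes$gene_id)
  genome_of <- setNames(genes$genome_id, genes$gene_id)
  edges <- NULL
  if (nrow(hits)) {
    h <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
    # best hit per directed pair: lowest e-value, ties by highest bit score
    o <- order(h$query_id, h$subject_id, h$evalue, -h$bit_score)
    h <- h[o, , drop = FALSE]
    h <- h[!duplicated(paste(h$query_id, h$subject_id, sep = "\r")), ,
           drop = FALSE]
    key_fwd <- paste(h$query_id, h$subject_id, sep = "\r")
    key_rev <- paste(h$subject_id, h$query_id, sep = "\r")
    idx_rev <- match(key_rev, key_fwd)
    has_recip <- !is.na(idx_rev)
    first_dir <- has_recip & h$query_id < h$subject_id
    cand <- which(first_dir)
    if (length(cand)) {
      ab <- h[cand, , drop = FALSE]
      ba <- h[idx_rev[cand], , drop = FALSE]
      shorter <- pmin(lens[ab$query_id], lens[ab$subject_id])
      cov_ok <- ab$align_len >= thresholds$coverage_min * shorter &
        ba$align_len >= thresholds$coverage_min * shorter
      e_ok <- ab$evalue <= thresholds$evalue_max &
        ba$evalue <= thresholds$evalue_max
      short_ok <- shorter < thresholds$short_length &
        ab$pident >= thresholds$short_identity_min &
        ba$pident >= thresholds$short_identity_min
      pass <- cov_ok & (e_ok | short_ok)
      if (reciprocal_best) {
        # best subject per (query, subject genome): highest bit, ties lowest e
        bb <- h[order(h$query_id, -h$bit_score, h$evalue), , drop = FALSE]
        gkey <- paste(bb$query_id, genome_of[bb$subject_id], sep = "\r")
        bb <- bb[!duplicated(gkey), , drop = FALSE]
        best <- setNames(bb$subject_id,
                         paste(bb$query_id, genome_of[bb$subject_id],
                               sep = "\r"))
        fwd_best <- best[paste(ab$query_id, genome_of[ab$subject_id],
                               sep = "\r")] == ab$subject_id
        rev_best <- best[paste(ab$subject_id, genome_of[ab$query_id],
                               sep = "\r")] == ab$query_id
        pass <- pass & !is.na(fwd_best) & fwd_best &
          !is.na(rev_best) & rev_best
      }
      if (any(pass))
        edges <- data.frame(from = ab$query_id[pass],
                            to = ab$subject_id[pass],
                            stringsAsFactors = FALSE)
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(genes), name = genes$gene_id)
  if (!is.null(edges))
    g <- igraph::add_edges(g, rbind(edges$from, edges$to))
  g
}

#' Cluster genes into orthologous groups (COGs)
#'
#' COGs are the connected components of the ortholog graph (single-linkage
#' transitive closure); genes without edges form singleton COGs. COG ids are
#' assigned deterministically in order of each component's smallest member
#' gene id.
#'
#' @param graph Ortholog graph from [build_ortholog_graph()].
#' @param genes `data.frame` with `gene_id` and `genome_id`; every vertex of
#'   `graph` must appear here.
#' @return A membership `data.frame` with columns `cog_id`, `genome_id`,
#'   `gene_id`.
#' @export
cluster_cogs <- function(graph, genes) {
  vnames <- igraph::V(graph)$name
  missing_ <- setdiff(vnames, genes$gene_id)
  if (length(missing_))
    stop("graph vertex not in gene table: ", paste(missing_, collapse = ", "))
  comp <- igraph::components(graph)$membership
  comp <- comp[genes$gene_id]
  if (anyNA(comp)) {
    # genes absent from the graph become singletons
    extra <- which(is.na(comp))
    comp[extra] <- max(comp, 0, na.rm = TRUE) + seq_along(extra)
  }
  smallest <- tapply(genes$gene_id, comp, min)
  rank_ <- rank(smallest)  # deterministic: by smallest member gene id
  cog_id <- sprintf("COG%04d", rank_[as.character(comp)])
  out <- data.frame(cog_id = cog_id, genome_id = genes$genome_id,
                    gene_id = genes$gene_id, stringsAsFactors = FALSE)
  out[order(out$cog_id, out$genome_id, out$gene_id), , drop = FALSE] ->
    out
  rownames(out) <- NULL
  out
}

#' Merge COGs linked by profile-search hits
#'
#' Each profile hit with e-value <= `profile_evalue_max` links the COG of
#' its gene with the target COG; all linked COGs are merged. Merging is
#' computed as connected components over the merge relation, so the result
#' is independent of hit order. COG ids are reassigned deterministically as
#' in [cluster_cogs()].
#'
#' @param membership COG membership table from [cluster_cogs()].
#' @param profile_hits `data.frame` with columns `gene_id`, `target_cog_id`,
#'   `e_value`.
#' @param thresholds An [orthology_thresholds()] object.
#' @return Updated membership table.
#' @export
merge_by_profile_hits <- function(membership, profile_hits,
                                  thresholds = orthology_thresholds()) {
  if (!nrow(profile_hits)) return(membership)
  unknown_gene <- setdiff(profile_hits$gene_id, membership$gene_id)
  if (length(unknown_gene))
    stop("profile hit references unknown gene id: ",
         paste(unknown_gene, collapse = ", "))
  unknown_cog <- setdiff(profile_hits$target_cog_id, membership$cog_id)
  if (length(unknown_cog))
    stop("profile hit references unknown COG id: ",
         paste(unknown_cog, collapse = ", "))
  sig <- profile_hits[profile_hits$e_value <= thresholds$profile_evalue_max, ,
                      drop = FALSE]
  cog_of <- setNames(membership$cog_id, membership$gene_id)
  cogs <- sort(unique(membership$cog_id))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(cogs), name = cogs)
  if (nrow(sig))
    g <- igraph::add_edges(g, rbind(cog_of[sig$gene_id], sig$target_cog_id))
  comp <- igraph::components(g)$membership
  merged <- comp[membership$cog_id]
  smallest <- tapply(membership$gene_id, merged, min)
  rank_ <- rank(smallest)
  membership$cog_id <- sprintf("COG%04d", rank_[as.character(merged)])
  membership <- membership[order(membership$cog_id, membership$genome_id,
                                 membership$gene_id), , drop = FALSE]
  rownames(membership) <- NULL
  membership
}

#' Summarise COG membership
#'
#' @param membership COG membership table.
#' @return `data.frame` with `cog_id`, `n_members`, `genome_count`.
#' @export
cog_summary <- function(membership) {
  sp <- split(membership$genome_id, membership$cog_id)
  data.frame(cog_id = names(sp),
             n_members = lengths(sp),
             genome_count = vapply(sp, function(g) length(unique(g)), 0L),
             row.names = NULL, stringsAsFactors = FALSE)
}
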