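#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining via [ape::nj()]; negative branch-length
#' estimates are clamped to zero. NJ is exact on additive distance matrices.
#'
#' @param d Symmetric distance matrix (labels as dimnames), >= 3 taxa.
#' @return Unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d) || nrow(d) < 3L) stop("need at least 3 labels")
  tree <- ape::nj(as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' UPGMA / WPGMA clustering tree
#'
#' Agglomerative average-linkage clustering with arithmetic (UPGMA) or
#' simple (WPGMA, a.k.a. McQuitty) averaging, via phangorn. Join heights are
#' halved into ultrametric branch lengths.
#'
#' @param d Symmetric distance matrix, >= 2 labels.
#' @param weighting `"upgma"` or `"wpgma"`.
#' @return Rooted `phylo` tree (ultrametric for UPGMA).
#' @export
upgma_tree <- function(d, weighting = c("upgma", "wpgma")) {
  weighting <- match.arg(weighting)
  if (!is.matrix(d) || nrow(d) < 2L) stop("need at least 2 labels")
  if (weighting == "upgma") phangorn::upgma(as.dist(d))
  else phangorn::wpgma(as.dist(d))
}

#' Distance tree with bootstrap supports
#'
#' Builds the point-estimate tree from the full alignment, then resamples
#' alignment columns with replacement `n_replicates` times, rebuilds a tree
#' per replicate, and attaches to each internal edge of the point tree the
#' percentage of replicates containing the same bipartition.
#'
#' @param aln Alignment (named character vector of equal-length rows).
#' @param n_replicates Bootstrap replicates (>= 1).
#' @param seed Random seed.
#' @param model Distance model for [protein_distance()].
#' @param method `"nj"`, `"upgma"` or `"wpgma"`.
#' @return `phylo` tree whose `node.label` holds supports in `[0, 100]`
#'   (root label empty).
#' @export
bootstrap_tree <- function(aln, n_replicates = 1000L, seed = 1L,
                           model = "poisson", method = c("nj", "upgma",
                                                         "wpgma")) {
  method <- match.arg(method)
  stopifnot(n_replicates >= 1L)
  m <- do.call(rbind, strsplit(unclass(aln), "", fixed = TRUE))
  rownames(m) <- names(aln)
  if (ncol(m) < 2L) stop("alignment has fewer than 2 columns")
  build <- function(mat) {
    rows <- setNames(apply(mat, 1L, paste, collapse = ""), rownames(mat))
    d <- protein_distance(rows, model = model)
    if (method == "nj") neighbor_joining(d) else upgma_tree(d, method)
  }
  point <- build(m)
  ref_splits <- tree_bipartitions(point)
  counts <- setNames(numeric(length(ref_splits)), ref_splits)
  set.seed(seed)
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(ncol(m), replace = TRUE)
    rep_tree <- build(m[, cols, drop = FALSE])
    hit <- ref_splits %in% tree_bipartitions(rep_tree)
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / n_replicates
  .attach_supports(point, support)
}

# map split keys -> internal node labels of `tree`
.attach_supports <- function(tree, support) {
  keys <- .node_split_keys(tree)
  labels <- rep("", tree$Nnode)
  hit <- !is.na(keys) & keys %in% names(support)
  labels[hit] <- vapply(support[keys[hit]],
                        function(s) format(round(s, 1)), "")
  tree$node.label <- labels
  tree
}
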