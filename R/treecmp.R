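.node_split_keys <- function(tree) {
  # canonical nontrivial split key per internal node; NA for trivial splits
  n_tip <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  anchor <- min(labs)
  keys <- rep(NA_character_, tree$Nnode)
  for (k in seq_along(pp)) {
    clade <- labs[pp[[k]]]
    other <- setdiff(labs, clade)
    if (length(clade) < 2L || length(other) < 2L) next
    side <- if (anchor %in% clade) clade else other
    keys[k] <- paste(sort(side), collapse = ",")
  }
  keys
}

.split_key_for_node <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  .node_split_keys(tree)[node - n_tip]
}

#' Nontrivial bipartitions of a tree
#'
#' One split per internal edge, in canonical form: the side containing the
#' lexically smallest leaf, with members sorted and comma-joined. Trivial
#' splits (a single leaf on either side) are excluded.
#'
#' @param tree A `phylo` tree.
#' @return Character vector of unique split keys (possibly empty).
#' @export
tree_bipartitions <- function(tree) {
  keys <- .node_split_keys(tree)
  unique(keys[!is.na(keys)])
}

#' Robinson-Foulds (symmetric-difference) distance
#'
#' Number of nontrivial bipartitions present in exactly one of the two
#' trees. Requires identical leaf sets.
#'
#' @param t1,t2 `phylo` trees on the same leaves.
#' @return Non-negative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    only1 <- setdiff(l1, l2); only2 <- setdiff(l2, l1)
    stop("leaf sets differ: ",
         if (length(only1)) paste("only in tree 1:",
                                  paste(only1, collapse = ", ")) else "",
         if (length(only2)) paste(" only in tree 2:",
                                  paste(only2, collapse = ", ")) else "")
  }
  s1 <- tree_bipartitions(t1)
  s2 <- tree_bipartitions(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Pairwise Robinson-Foulds distance matrix over a set of trees
#'
#' @param trees Named list of `phylo` trees on the same leaf set.
#' @return Symmetric integer matrix, zero diagonal, labelled by tree name.
#' @export
tree_distance_matrix <- function(trees) {
  if (length(trees) < 2L) stop("need at least 2 trees")
  if (is.null(names(trees))) names(trees) <- paste0("tree", seq_along(trees))
  splits <- lapply(trees, tree_bipartitions)
  # leaf-set validation via robinson_foulds on the first pair of each tree
  n <- length(trees)
  d <- matrix(0L, n, n, dimnames = list(names(trees), names(trees)))
  for (i in seq_len(n - 1L)) {
    l1 <- sort(trees[[i]]$tip.label)
    for (j in (i + 1L):n) {
      if (!identical(l1, sort(trees[[j]]$tip.label)))
        stop("leaf sets differ between trees ", names(trees)[i], " and ",
             names(trees)[j])
      d[i, j] <- d[j, i] <- length(setdiff(splits[[i]], splits[[j]])) +
        length(setdiff(splits[[j]], splits[[i]]))
    }
  }
  d
}

.split_sides <- function(key, labs) {
  side <- strsplit(key, ",", fixed = TRUE)[[1L]]
  list(side = side, other = setdiff(labs, side))
}

.splits_compatible <- function(a, b) {
  # both canonical sides contain the anchor, so a$side and b$side intersect
  length(intersect(a$side, b$other)) == 0L ||
    length(intersect(b$side, a$other)) == 0L ||
    length(intersect(a$other, b$other)) == 0L
}

#' Extended majority-rule consensus tree
#'
#' Includes every split occurring in more than half of the input trees, then
#' greedily adds the remaining splits in order of decreasing frequency (ties
#' broken by the canonical split key) whenever compatible with the splits
#' already included. Split frequencies (percent) are attached as
#' internal-node labels.
#'
#' @param trees List of `phylo` trees on the same leaf set.
#' @return A `phylo` tree with supports as `node.label`.
#' @export
consensus_extended_majority <- function(trees) {
  stopifnot(length(trees) >= 1L)
  labs <- sort(trees[[1L]]$tip.label)
  for (t in trees)
    if (!identical(sort(t$tip.label), labs)) stop("leaf sets differ")
  n_tree <- length(trees)
  all_splits <- unlist(lapply(trees, tree_bipartitions))
  freq <- table(all_splits) / n_tree
  ord <- order(-as.numeric(freq), names(freq))
  keys <- names(freq)[ord]
  freqs <- as.numeric(freq)[ord]
  accepted <- character()
  acc_sides <- list()
  for (k in seq_along(keys)) {
    cand <- .split_sides(keys[k], labs)
    if (freqs[k] > 0.5 ||
        all(vapply(acc_sides, .splits_compatible, TRUE, b = cand))) {
      accepted <- c(accepted, keys[k])
      acc_sides[[length(acc_sides) + 1L]] <- cand
    }
  }
  support <- setNames(100 * freqs[match(accepted, keys)], accepted)
  .tree_from_splits(accepted, labs, support)
}

# Build a rooted phylo from a laminar family of canonical splits. The clade
# of each split is the side NOT containing the anchor (lexically smallest
# leaf); nesting is resolved by containment.
.tree_from_splits <- function(keys, labs, support = NULL) {
  anchor <- min(labs)
  clades <- lapply(keys, function(k) {
    s <- .split_sides(k, labs)
    if (anchor %in% s$side) s$other else s$side
  })
  sizes <- vapply(clades, length, 0L)
  ord <- order(-sizes)
  clades <- clades[ord]
  keys <- keys[ord]
  emit <- function(members, avail) {
    # avail: indices of clades strictly inside `members` not yet consumed
    child_idx <- avail[vapply(avail, function(i)
      all(clades[[i]] %in% members), TRUE)]
    taken <- character()
    parts <- character()
    for (i in child_idx) {
      if (any(clades[[i]] %in% taken)) next
      inner <- child_idx[vapply(child_idx, function(j)
        j != i && all(clades[[j]] %in% clades[[i]]), TRUE)]
      lab <- if (!is.null(support)) format(round(support[[keys[i]]], 1)) else ""
      parts <- c(parts, paste0(emit(clades[[i]], inner), lab))
      taken <- c(taken, clades[[i]])
    }
    loose <- setdiff(members, taken)
    paste0("(", paste(c(parts, sort(loose)), collapse = ","), ")")
  }
  newick <- paste0(emit(labs, seq_along(clades)), ";")
  parse_newick(newick)
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Kruskal stress-1 minimisation via [vegan::monoMDS()] (global model) with
#' seeded multiple random restarts plus a classical-scaling start; the best
#' (lowest-stress) configuration is returned, centred at the origin.
#'
#' @param d Symmetric distance matrix, >= 3 items.
#' @param dims Embedding dimension.
#' @param restarts Number of random restarts.
#' @param seed Random seed.
#' @param maxit Maximum iterations per restart.
#' @return List of class `nmds_fit` with `points`, `stress`, `restarts`,
#'   `seed`, `degenerate`.
#' @export
nmds <- function(d, dims = 2L, restarts = 20L, seed = 1L, maxit = 500L) {
  stopifnot(is.matrix(d), nrow(d) >= 3L)
  n <- nrow(d)
  if (all(d == 0)) {
    pts <- matrix(0, n, dims, dimnames = list(rownames(d), NULL))
    return(structure(list(points = pts, stress = 0, restarts = 0L,
                          seed = seed, degenerate = TRUE),
                     class = "nmds_fit"))
  }
  dd <- as.dist(d)
  inits <- vector("list", restarts + 1L)
  cmd <- suppressWarnings(stats::cmdscale(dd, k = dims))
  if (ncol(cmd) < dims)
    cmd <- cbind(cmd, matrix(0, n, dims - ncol(cmd)))
  inits[[1L]] <- cmd
  for (r in seq_len(restarts)) {
    set.seed(seed + r)
    inits[[r + 1L]] <- matrix(runif(n * dims, -1, 1), n, dims)
  }
  best <- NULL
  for (init in inits) {
    fit <- try(vegan::monoMDS(dd, y = init, k = dims, model = "global",
                              maxit = maxit, smin = 1e-7,
                              sratmax = 1 - 1e-9), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  if (is.null(best)) stop("NMDS failed for every start")
  pts <- sweep(best$points, 2L, colMeans(best$points))
  rownames(pts) <- rownames(d)
  structure(list(points = pts, stress = best$stress, restarts = restarts,
                 seed = seed, degenerate = FALSE), class = "nmds_fit")
}

#' Gene-content distance between genomes
#'
#' `jaccard`: 1 - |intersection| / |union| over COG presence (via
#' [vegan::vegdist()]). `cfn`: the two-state Cavender-Farris-Neyman
#' maximum-likelihood correction `-0.5 * ln(1 - 2p)` with `p` the fraction
#' of discordant columns; saturated pairs (`p >= 0.5`) are capped at the
#' largest finite distance in the matrix, with a warning.
#'
#' @param pam Presence/absence matrix (genomes x COGs).
#' @param method `"jaccard"` or `"cfn"`.
#' @return Symmetric distance matrix.
#' @export
gene_content_distance <- function(pam, method = c("jaccard", "cfn")) {
  method <- match.arg(method)
  if (nrow(pam) < 2L) stop("need at least 2 genomes")
  if (method == "jaccard") {
    d <- as.matrix(vegan::vegdist(pam, method = "jaccard", binary = TRUE))
    diag(d) <- 0
    return(d)
  }
  p <- as.matrix(dist(pam, method = "manhattan")) / ncol(pam)
  sat <- p >= 0.5 & row(p) != col(p)
  d <- matrix(NA_real_, nrow(p), ncol(p), dimnames = dimnames(p))
  d[!sat] <- -0.5 * log(1 - 2 * p[!sat])
  if (any(sat)) {
    cap <- max(d[is.finite(d)], na.rm = TRUE)
    warning(sum(sat) / 2, " saturated pair(s) (p >= 0.5) capped at ",
            signif(cap, 4))
    d[sat] <- cap
  }
  diag(d) <- 0
  d
}

#' Gene-content dendrograms of genomes and genes
#'
#' Genomes are clustered by WPGMA on gene-content distances between
#' presence/absence rows; genes (COGs) by UPGMA on distances between
#' columns. For the accessory-gene analysis, pass the matrix restricted to
#' accessory COGs.
#'
#' @param pam Presence/absence matrix.
#' @param method Distance for [gene_content_distance()].
#' @return List with `phage_tree` (WPGMA, rooted) and `gene_tree` (UPGMA,
#'   rooted).
#' @export
content_dendrograms <- function(pam, method = "jaccard") {
  phage_tree <- upgma_tree(gene_content_distance(pam, method), "wpgma")
  gene_tree <- upgma_tree(gene_content_distance(t(pam), method), "upgma")
  list(phage_tree = phage_tree, gene_tree = gene_tree)
}
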