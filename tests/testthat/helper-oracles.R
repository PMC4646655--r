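# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain-R dynamic programming, union-find,
# exhaustive enumeration.

aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n) paste(sample(aa20, n, replace = TRUE),
                                    collapse = "")

blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})

# brute-force affine-gap Smith-Waterman (three full matrices)
sw_score_oracle <- function(a, b, sub = blosum62, go = 11, ge = 1) {
  ea <- match(strsplit(a, "")[[1]], rownames(sub))
  eb <- match(strsplit(b, "")[[1]], rownames(sub))
  n <- length(ea); m <- length(eb); goe <- go + ge
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - goe, E[i, j - 1] - ge)
    F[i, j] <- max(H[i - 1, j] - goe, F[i - 1, j] - ge)
    H[i, j] <- max(0, H[i - 1, j - 1] + sub[ea[i - 1], eb[j - 1]],
                   E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# brute-force affine-gap global (Needleman-Wunsch) score, end gaps penalized
nw_score_oracle <- function(a, b, sub = blosum62, go = 11, ge = 1) {
  ea <- match(strsplit(a, "")[[1]], rownames(sub))
  eb <- match(strsplit(b, "")[[1]], rownames(sub))
  n <- length(ea); m <- length(eb); goe <- go + ge
  H <- matrix(-Inf, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  H[1, 1] <- 0
  for (j in 2:(m + 1)) { E[1, j] <- -(goe + (j - 2) * ge); H[1, j] <- E[1, j] }
  for (i in 2:(n + 1)) { F[i, 1] <- -(goe + (i - 2) * ge); H[i, 1] <- F[i, 1] }
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - goe, E[i, j - 1] - ge)
    F[i, j] <- max(H[i - 1, j] - goe, F[i - 1, j] - ge)
    H[i, j] <- max(H[i - 1, j - 1] + sub[ea[i - 1], eb[j - 1]],
                   E[i, j], F[i, j])
  }
  H[n + 1, m + 1]
}

# union-find over gene ids
uf_components <- function(nodes, edges) {
  parent <- setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    ra <- find(edges$from[k]); rb <- find(edges$to[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  vapply(nodes, find, "")
}

# enumerate nontrivial splits of a phylo tree by cutting each internal edge
# and flooding the resulting components (independent of the package's code)
splits_oracle <- function(tree) {
  tree <- ape::unroot(tree)
  n_tip <- length(tree$tip.label)
  edges <- tree$edge
  out <- character()
  for (k in seq_len(nrow(edges))) {
    if (edges[k, 2] <= n_tip) next  # trivial
    # flood from child node without crossing edge k
    adj <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
    seen <- edges[k, 2]; queue <- edges[k, 2]
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[as.character(v)]]) {
        if (w %in% seen) next
        if ((v == edges[k, 1] && w == edges[k, 2]) ||
            (v == edges[k, 2] && w == edges[k, 1])) next
        seen <- c(seen, w); queue <- c(queue, w)
      }
    }
    side <- sort(tree$tip.label[seen[seen <= n_tip]])
    if (length(side) < 2 || length(side) > n_tip - 2) next
    if (!(min(tree$tip.label) %in% side))
      side <- sort(setdiff(tree$tip.label, side))
    out <- c(out, paste(side, collapse = ","))
  }
  unique(out)
}

rf_oracle <- function(t1, t2) {
  s1 <- splits_oracle(t1); s2 <- splits_oracle(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# random unrooted binary tree with unit branch lengths
random_tree <- function(n, labels = paste0("t", seq_len(n))) {
  ape::rtree(n, tip.label = sample(labels), br = runif)
}

# random additive distance matrix from a random binary tree
random_additive <- function(n) {
  tr <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# tiny deterministic protein families for clustering tests
make_family <- function(base, genomes, divergence = 0.2) {
  setNames(vapply(seq_along(genomes), function(i)
    mutate_protein(base, divergence), ""), genomes)
}
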