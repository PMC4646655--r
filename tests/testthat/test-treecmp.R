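test_that("bipartitions enumerate internal edges in canonical form", {
  t4 <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  bp <- tree_bipartitions(t4)
  expect_equal(bp, "A,B")
  star <- parse_newick("(A:1,B:1,C:1,D:1,E:1);")
  expect_equal(length(tree_bipartitions(star)), 0L)
  set.seed(163)
  for (i in 1:10) {
    tr <- random_tree(8)
    expect_equal(length(tree_bipartitions(ape::unroot(tr))), 8 - 3)
    expect_setequal(tree_bipartitions(tr), splits_oracle(tr))
  }
})

test_that("Robinson-Foulds equals the enumeration oracle and is a metric", {
  ta <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  tb <- parse_newick("((A:1,C:1):1,(B:1,D:1):1);")
  expect_equal(robinson_foulds(ta, ta), 0L)
  expect_equal(robinson_foulds(ta, tb), 2L)
  set.seed(167)
  labels <- paste0("t", 1:8)
  trees <- replicate(12, random_tree(8, labels), simplify = FALSE)
  for (i in 1:11) for (j in (i + 1):12) {
    rf <- robinson_foulds(trees[[i]], trees[[j]])
    expect_equal(rf, rf_oracle(trees[[i]], trees[[j]]))
    # cross-check against an independent implementation
    expect_equal(rf, as.integer(phangorn::RF.dist(trees[[i]], trees[[j]])))
    expect_lte(rf, 2 * (8 - 3))
  }
  # symmetry and triangle inequality on random triples
  for (k in 1:10) {
    idx <- sample(12, 3)
    d12 <- robinson_foulds(trees[[idx[1]]], trees[[idx[2]]])
    d21 <- robinson_foulds(trees[[idx[2]]], trees[[idx[1]]])
    d13 <- robinson_foulds(trees[[idx[1]]], trees[[idx[3]]])
    d23 <- robinson_foulds(trees[[idx[2]]], trees[[idx[3]]])
    expect_equal(d12, d21)
    expect_lte(d13, d12 + d23)
  }
  expect_error(robinson_foulds(ta, parse_newick("((A,B),(C,E));")),
               "leaf sets differ")
})

test_that("tree distance matrix is symmetric with zero diagonal", {
  t1 <- parse_newick("((A,B),(C,D),E);")
  dm <- tree_distance_matrix(list(x = t1, y = t1))
  expect_equal(dm, matrix(0L, 2, 2, dimnames = list(c("x", "y"),
                                                    c("x", "y"))))
  set.seed(173)
  trees <- replicate(15, random_tree(7), simplify = FALSE)
  names(trees) <- paste0("g", 1:15)
  dm2 <- tree_distance_matrix(trees)
  expect_equal(dm2, t(dm2))
  expect_equal(unname(diag(dm2)), rep(0L, 15))
  for (k in 1:10) {
    i <- sample(15, 1); j <- sample(15, 1)
    expect_equal(dm2[i, j], rf_oracle(trees[[i]], trees[[j]]))
  }
})

test_that("extended majority consensus matches a frequency/compatibility oracle", {
  t1 <- parse_newick("((A,B),(C,D),E);")
  cons1 <- consensus_extended_majority(list(t1, t1, t1))
  expect_equal(robinson_foulds(cons1, t1), 0L)
  expect_true(all(as.numeric(cons1$node.label[cons1$node.label != ""]) == 100))
  # a split occurring in 2 of 3 trees is included with support 66.7
  t2 <- parse_newick("((A,B),(C,E),D);")
  t3 <- parse_newick("((A,C),(B,D),E);")
  cons2 <- consensus_extended_majority(list(t1, t2, t3))
  expect_true(has_split(cons2, c("A", "B")))
  keys <- phagepan:::.node_split_keys(cons2)
  lab <- cons2$node.label[which(keys == "A,B")]
  expect_equal(round(as.numeric(lab), 1), 66.7)
  # single tree: itself with all supports 100
  single <- consensus_extended_majority(list(t3))
  expect_equal(robinson_foulds(single, t3), 0L)
  # oracle: all consensus splits appear in input trees; any split more
  # frequent than an accepted one is either accepted or incompatible
  set.seed(179)
  for (rep in 1:5) {
    trees <- replicate(7, random_tree(6, paste0("x", 1:6)), simplify = FALSE)
    cons <- consensus_extended_majority(trees)
    all_splits <- unlist(lapply(trees, tree_bipartitions))
    freq <- table(all_splits) / length(trees)
    got <- tree_bipartitions(cons)
    expect_true(all(got %in% names(freq)))
    # every majority split is present
    expect_true(all(names(freq)[freq > 0.5] %in% got))
    # greedy property: a rejected split must conflict with an accepted one
    # of frequency >= its own
    labs <- sort(trees[[1]]$tip.label)
    for (s in setdiff(names(freq), got)) {
      cand <- phagepan:::.split_sides(s, labs)
      conflict <- vapply(got, function(g) {
        acc <- phagepan:::.split_sides(g, labs)
        !phagepan:::.splits_compatible(acc, cand) &&
          freq[[g]] >= freq[[s]]
      }, TRUE)
      expect_true(any(conflict))
    }
  }
  expect_error(consensus_extended_majority(
    list(t1, parse_newick("((A,B),(C,F),E);"))), "leaf sets differ")
})

test_that("NMDS recovers planar configurations and ranks drive stress", {
  set.seed(181)
  pts <- matrix(rnorm(8), 4, 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("p", 1:4), paste0("p", 1:4))
  fit <- nmds(d, dims = 2, restarts = 10, seed = 7)
  expect_lt(fit$stress, 1e-3)
  expect_equal(unname(colMeans(fit$points)), c(0, 0), tolerance = 1e-8)
  # doubling distances leaves rank-based stress unchanged
  fit2 <- nmds(2 * d, dims = 2, restarts = 10, seed = 7)
  expect_equal(fit$stress, fit2$stress, tolerance = 1e-6)
  # degenerate all-zero matrix
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  fz <- nmds(z)
  expect_true(fz$degenerate)
  expect_true(all(fz$points == 0))
  # larger planar recovery
  set.seed(191)
  pts2 <- matrix(rnorm(24), 12, 2)
  d2 <- as.matrix(dist(pts2))
  dimnames(d2) <- list(paste0("q", 1:12), paste0("q", 1:12))
  expect_lt(nmds(d2, restarts = 10, seed = 11)$stress, 1e-3)
})

test_that("gene-content distances follow Jaccard and CFN definitions", {
  pam <- rbind(g1 = c(1, 1, 0, 0, 1), g2 = c(1, 1, 0, 0, 1),
               g3 = c(0, 0, 1, 1, 0))
  colnames(pam) <- paste0("c", 1:5)
  dj <- gene_content_distance(pam, "jaccard")
  expect_equal(dj["g1", "g2"], 0)
  expect_equal(dj["g1", "g3"], 1)
  # cfn closed form at p = 0.2
  pam2 <- rbind(a = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 0),
                b = c(1, 1, 1, 1, 1, 1, 1, 1, 0, 1))
  colnames(pam2) <- paste0("c", 1:10)
  dc <- gene_content_distance(pam2, "cfn")
  expect_equal(dc["a", "b"], -0.5 * log(0.6), tolerance = 1e-12)
  expect_equal(round(dc["a", "b"], 4), 0.2554)
  # saturated pairs are capped with a warning
  pam3 <- rbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1), c = c(1, 1, 0, 1))
  colnames(pam3) <- paste0("c", 1:4)
  expect_warning(d3 <- gene_content_distance(pam3, "cfn"), "capped")
  expect_true(all(is.finite(d3)))
  # jaccard set oracle on random matrices
  set.seed(193)
  m <- matrix(rbinom(6 * 30, 1, 0.4), 6, 30,
              dimnames = list(paste0("g", 1:6), paste0("c", 1:30)))
  m[, colSums(m) == 0] <- 1
  dj2 <- gene_content_distance(m, "jaccard")
  for (k in 1:6) {
    i <- sample(6, 1); j <- sample(6, 1)
    a <- which(m[i, ] == 1); b <- which(m[j, ] == 1)
    want <- if (i == j) 0 else 1 - length(intersect(a, b)) /
      length(union(a, b))
    expect_equal(dj2[i, j], want)
  }
})

test_that("content dendrograms cluster planted blocks and round trip", {
  # two genomes with identical accessory rows join at height zero
  pam <- rbind(g1 = c(1, 1, 0, 0), g2 = c(1, 1, 0, 0),
               g3 = c(0, 0, 1, 1), g4 = c(0, 1, 1, 1))
  colnames(pam) <- paste0("c", 1:4)
  dd <- content_dendrograms(pam)
  cop <- ape::cophenetic.phylo(dd$phage_tree)
  expect_equal(cop["g1", "g2"], 0)
  expect_true(has_split(dd$phage_tree, c("g1", "g2")))
  # trees survive a Newick round trip
  for (tr in dd) {
    back <- parse_newick(write_newick(tr))
    expect_equal(robinson_foulds(back, tr), 0L)
  }
  expect_equal(sort(dd$gene_tree$tip.label), paste0("c", 1:4))
})
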