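mk_hit <- function(evalue, align_len, pident = 50) {
  list(evalue = evalue, align_len = align_len, pident = pident)
}

test_that("the reciprocal-hit rule applies cutoffs and the short exception", {
  th <- orthology_thresholds()
  # both directions significant, coverage 120 >= 0.5 * 180
  expect_true(ortholog_pair(mk_hit(1e-10, 120), mk_hit(1e-10, 120),
                            200, 180, th))
  # short-sequence exception: e-value waived when identity >= 35
  expect_true(ortholog_pair(mk_hit(1e-3, 48, 40), mk_hit(1e-3, 48, 40),
                            200, 80, th))
  # exception inapplicable at shorter length 150
  expect_false(ortholog_pair(mk_hit(1e-3, 120, 40), mk_hit(1e-3, 120, 40),
                             200, 150, th))
  # coverage failure trumps significance
  expect_false(ortholog_pair(mk_hit(1e-10, 72), mk_hit(1e-10, 72),
                             200, 180, th))
  # the short exception never waives coverage
  expect_false(ortholog_pair(mk_hit(1e-3, 30, 40), mk_hit(1e-3, 30, 40),
                             200, 80, th))
  # a missing direction is not orthology
  expect_false(ortholog_pair(mk_hit(1e-10, 120), NULL, 200, 180, th))
  expect_error(ortholog_pair(mk_hit(1e-10, 120), mk_hit(1e-10, 120),
                             0, 180, th), "positive")
})

rand_hits <- function(genes, n_hits) {
  pairs <- expand.grid(q = genes$gene_id, s = genes$gene_id,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$q != pairs$s, ]
  pick <- pairs[sample(nrow(pairs), n_hits, replace = TRUE), ]
  data.frame(query_id = pick$q, subject_id = pick$s,
             pident = runif(n_hits, 20, 100),
             align_len = sample(20:200, n_hits, TRUE),
             mismatches = 0, gap_opens = 0, q_start = 1, q_end = 1,
             s_start = 1, s_end = 1,
             evalue = 10^runif(n_hits, -30, 0),
             bit_score = runif(n_hits, 20, 200), stringsAsFactors = FALSE)
}

test_that("ortholog graph equals an exhaustive per-pair rule oracle", {
  set.seed(53)
  th <- orthology_thresholds()
  for (rep in 1:5) {
    genes <- data.frame(gene_id = sprintf("x%02d", 1:20),
                        genome_id = rep(sprintf("g%d", 1:5), each = 4),
                        length = sample(40:300, 20, TRUE),
                        stringsAsFactors = FALSE)
    hits <- rand_hits(genes, 150)
    g <- build_ortholog_graph(hits, genes, th)
    got <- igraph::as_edgelist(g)
    got_keys <- sort(paste(pmin(got[, 1], got[, 2]),
                           pmax(got[, 1], got[, 2])))
    # oracle: best hit per direction, then re-check the quoted rule
    want <- character()
    lens <- setNames(genes$length, genes$gene_id)
    for (i in 1:19) for (j in (i + 1):20) {
      a <- genes$gene_id[i]; b <- genes$gene_id[j]
      pick_best <- function(q, s) {
        hh <- hits[hits$query_id == q & hits$subject_id == s, ]
        if (!nrow(hh)) return(NULL)
        hh <- hh[order(hh$evalue, -hh$bit_score), ][1, ]
        mk_hit(hh$evalue, hh$align_len, hh$pident)
      }
      if (ortholog_pair(pick_best(a, b), pick_best(b, a),
                        lens[[a]], lens[[b]], th))
        want <- c(want, paste(min(a, b), max(a, b)))
    }
    expect_equal(got_keys, sort(want))
  }
})

test_that("a one-directional hit never creates an edge", {
  genes <- data.frame(gene_id = c("a", "b"), genome_id = c("g1", "g2"),
                      length = c(100, 100), stringsAsFactors = FALSE)
  h <- rand_hits(genes, 1)
  h$query_id <- "a"; h$subject_id <- "b"
  h$evalue <- 1e-20; h$align_len <- 90
  g <- build_ortholog_graph(h, genes)
  expect_equal(igraph::ecount(g), 0)
  expect_error(build_ortholog_graph(transform(h, query_id = "zz"), genes),
               "unknown gene id")
})

test_that("COG clustering equals a union-find oracle on random graphs", {
  set.seed(59)
  for (rep in 1:5) {
    n <- sample(20:200, 1)
    genes <- data.frame(gene_id = sprintf("y%03d", 1:n),
                        genome_id = sprintf("g%d", sample(1:10, n, TRUE)),
                        stringsAsFactors = FALSE)
    n_edge <- sample(0:(2 * n), 1)
    edges <- data.frame(from = sample(genes$gene_id, n_edge, TRUE),
                        to = sample(genes$gene_id, n_edge, TRUE),
                        stringsAsFactors = FALSE)
    edges <- edges[edges$from != edges$to, ]
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, n, name = genes$gene_id)
    if (nrow(edges)) g <- igraph::add_edges(g, rbind(edges$from, edges$to))
    mem <- cluster_cogs(g, genes)
    expect_setequal(mem$gene_id, genes$gene_id)
    expect_equal(anyDuplicated(mem$gene_id), 0L)
    roots <- uf_components(genes$gene_id, edges)
    # same partition: identical multisets of components
    got <- split(mem$gene_id, mem$cog_id)
    want <- split(genes$gene_id, roots[genes$gene_id])
    expect_setequal(
      unname(vapply(got, function(v) paste(sort(v), collapse = "|"), "")),
      unname(vapply(want, function(v) paste(sort(v), collapse = "|"), "")))
    # deterministic ids: COG index ordered by smallest member gene id
    firsts <- vapply(got, min, "")
    expect_equal(names(firsts)[order(firsts)], sort(names(firsts)))
  }
})

test_that("transitive closure and singleton behaviour are as specified", {
  genes <- data.frame(gene_id = letters[1:8],
                      genome_id = paste0("g", 1:8), stringsAsFactors = FALSE)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, 8, name = genes$gene_id)
  g <- igraph::add_edges(g, c("a", "b", "b", "c"))
  mem <- cluster_cogs(g, genes)
  abc <- mem$cog_id[mem$gene_id == "a"]
  expect_equal(sort(mem$gene_id[mem$cog_id == abc]), c("a", "b", "c"))
  # five isolated genes -> five singleton COGs
  expect_equal(length(unique(mem$cog_id)), 6L)
})

test_that("profile merging respects the threshold and is order-independent", {
  genes <- data.frame(gene_id = sprintf("p%02d", 1:12),
                      genome_id = rep(paste0("g", 1:4), 3),
                      stringsAsFactors = FALSE)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, 12, name = genes$gene_id)
  g <- igraph::add_edges(g, c("p01", "p02", "p03", "p04", "p05", "p06"))
  mem <- cluster_cogs(g, genes)
  n0 <- length(unique(mem$cog_id))
  cog_of <- setNames(mem$cog_id, mem$gene_id)
  # one significant link -> exactly one fewer COG
  ph <- data.frame(gene_id = "p01", target_cog_id = cog_of[["p03"]],
                   e_value = 1e-6, stringsAsFactors = FALSE)
  m1 <- merge_by_profile_hits(mem, ph)
  expect_equal(length(unique(m1$cog_id)), n0 - 1L)
  # non-significant hit -> no merge
  ph$e_value <- 1e-4
  expect_equal(length(unique(merge_by_profile_hits(mem, ph)$cog_id)), n0)
  # chains in shuffled orders give the same partition
  chain <- data.frame(
    gene_id = c("p01", "p03", "p05", "p07"),
    target_cog_id = cog_of[c("p03", "p05", "p07", "p09")],
    e_value = 1e-8, stringsAsFactors = FALSE)
  set.seed(61)
  parts <- lapply(1:5, function(i) {
    m <- merge_by_profile_hits(mem, chain[sample(nrow(chain)), ])
    unname(split(m$gene_id, m$cog_id))
  })
  for (i in 2:5) expect_equal(parts[[i]], parts[[1]])
  expect_error(merge_by_profile_hits(mem, transform(ph, gene_id = "zz")),
               "unknown gene")
  expect_error(merge_by_profile_hits(mem, transform(ph, target_cog_id = "zz")),
               "unknown COG")
})

test_that("partition property: every gene in exactly one COG", {
  set.seed(67)
  sim <- simulate_genome_set(sim_config(), seed = 5)
  pr <- sim$proteins[sim$proteins$genome_id %in% sprintf("G%02d", 1:6), ]
  res <- run_pangenome_pipeline(pr)
  expect_setequal(res$membership$gene_id, pr$gene_id)
  expect_equal(anyDuplicated(res$membership$gene_id), 0L)
  expect_equal(sum(res$summary$n_members), nrow(pr))
})
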