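mk_membership <- function(pam) {
  idx <- which(pam == 1L, arr.ind = TRUE)
  data.frame(cog_id = colnames(pam)[idx[, 2]],
             genome_id = rownames(pam)[idx[, 1]],
             gene_id = paste0(rownames(pam)[idx[, 1]], "_",
                              colnames(pam)[idx[, 2]]),
             stringsAsFactors = FALSE)
}

rand_pam <- function(n_genomes, n_cogs) {
  repeat {
    m <- matrix(rbinom(n_genomes * n_cogs, 1, 0.5), n_genomes, n_cogs,
                dimnames = list(sprintf("g%02d", 1:n_genomes),
                                sprintf("c%03d", 1:n_cogs)))
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

test_that("COG categories follow the genome-count rule", {
  s <- data.frame(cog_id = c("a", "b", "c", "d"),
                  n_members = c(20, 14, 1, 2),
                  genome_count = c(20, 14, 1, 2))
  cl <- classify_cogs(s, 20)
  expect_equal(cl$category, c("core", "accessory", "unique", "accessory"))
  expect_error(classify_cogs(transform(s, genome_count = 21), 20), "exceeds")
})

test_that("accumulation curves match exhaustive enumeration for small N", {
  set.seed(71)
  for (rep in 1:5) {
    n <- sample(3:5, 1)
    pam <- rand_pam(n, sample(6:15, 1))
    # exhaustive oracle over all n! genome orders
    perms <- as.matrix(expand.grid(rep(list(1:n), n)))
    perms <- perms[apply(perms, 1, function(r) !anyDuplicated(r)), ,
                   drop = FALSE]
    pan_o <- core_o <- matrix(0, nrow(perms), n)
    for (p in seq_len(nrow(perms))) for (k in 1:n) {
      sub <- pam[perms[p, 1:k], , drop = FALSE]
      pan_o[p, k] <- sum(colSums(sub) > 0)
      core_o[p, k] <- sum(colSums(sub) == k)
    }
    # exhaustive mode reproduces the subset-enumeration oracle exactly
    cv <- accumulation_curves(pam, exhaustive = TRUE)
    expect_equal(cv$pan_mean, colMeans(pan_o))
    expect_equal(cv$core_mean, colMeans(core_o))
    # exact invariants at the ends
    expect_equal(cv$pan_mean[n], ncol(pam))
    expect_equal(cv$pan_lo[n], ncol(pam))
    expect_equal(cv$core_mean[n], sum(colSums(pam) == n))
    expect_equal(cv$pan_mean[1], mean(rowSums(pam)))
    expect_true(all(diff(cv$pan_mean) >= 0))
    expect_true(all(diff(cv$core_mean) <= 0))
  }
  expect_error(accumulation_curves(matrix(0, 0, 0)), "empty")
})

test_that("accumulation curves are monotone and reproducible at larger N", {
  set.seed(73)
  pam <- rand_pam(20, 300)
  c1 <- accumulation_curves(pam, n_permutations = 200, seed = 42)
  c2 <- accumulation_curves(pam, n_permutations = 200, seed = 42)
  expect_equal(c1, c2)
  expect_true(all(diff(c1$pan_mean) >= 0))
  expect_true(all(diff(c1$core_mean) <= 0))
  expect_true(all(c1$pan_lo <= c1$pan_hi))
  expect_true(all(c1$core_lo <= c1$core_hi))
})

test_that("genome fractions partition gene counts and sum lengths", {
  pam <- matrix(1L, 3, 2, dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  mem <- mk_membership(pam)
  cats <- classify_cogs(cog_summary(mem), 3)
  fr <- genome_fractions(mem, cats)
  expect_equal(fr$core, rep(1, 3))
  expect_equal(fr$accessory + fr$unique, rep(0, 3))
  # planted lengths: length fraction equals direct arithmetic
  set.seed(79)
  genes <- data.frame(gene_id = mem$gene_id,
                      start = sample(1:1000, nrow(mem)),
                      stringsAsFactors = FALSE)
  genes$end <- genes$start + sample(300:900, nrow(mem))
  glen <- c(g1 = 5000, g2 = 6000, g3 = 7000)
  fr2 <- genome_fractions(mem, cats, genes, glen)
  for (g in names(glen)) {
    ids <- mem$gene_id[mem$genome_id == g]
    want <- sum(genes$end[match(ids, genes$gene_id)] -
                genes$start[match(ids, genes$gene_id)] + 1) / glen[[g]]
    expect_equal(fr2$core_length_fraction[fr2$genome_id == g], unname(want))
  }
  # count fractions always sum to one
  set.seed(83)
  pam3 <- rand_pam(6, 40)
  mem3 <- mk_membership(pam3)
  cats3 <- classify_cogs(cog_summary(mem3), 6)
  fr3 <- genome_fractions(mem3, cats3)
  expect_equal(fr3$core + fr3$accessory + fr3$unique, rep(1, 6))
})

test_that("pairwise shared fraction matches a set-intersection oracle", {
  expect_error(pairwise_shared_fraction(matrix(1, 1, 1)), "at least 2")
  m <- rbind(g1 = c(1, 1, 0, 0), g2 = c(1, 1, 0, 0), g3 = c(0, 0, 1, 1))
  colnames(m) <- paste0("c", 1:4)
  f <- pairwise_shared_fraction(m)
  expect_equal(f["g1", "g2"], 1)
  expect_equal(f["g1", "g3"], 0)
  expect_equal(diag(f), c(g1 = 1, g2 = 1, g3 = 1))
  set.seed(89)
  pam <- rand_pam(8, 30)
  f2 <- pairwise_shared_fraction(pam)
  fj <- pairwise_shared_fraction(pam, denominator = "union")
  expect_equal(f2, t(f2))
  for (k in 1:10) {
    i <- sample(8, 1); j <- sample(8, 1)
    if (i == j) next
    a <- which(pam[i, ] == 1); b <- which(pam[j, ] == 1)
    expect_equal(f2[i, j],
                 length(intersect(a, b)) / mean(c(length(a), length(b))))
    expect_equal(fj[i, j],
                 length(intersect(a, b)) / length(union(a, b)))
  }
})

test_that("OLS regression matches the normal-equation oracle", {
  x <- 1:10
  r <- linear_regression(x, 2 * x + 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_equal(r$r_squared, 1)
  set.seed(97)
  x <- rnorm(200); y <- rnorm(200)
  r0 <- linear_regression(x, y)
  expect_lt(r0$r_squared, 0.05)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(r0$intercept, beta[1], tolerance = 1e-10)
  expect_equal(r0$slope, beta[2], tolerance = 1e-10)
  expect_error(linear_regression(rep(1, 5), 1:5), "constant")
  expect_error(linear_regression(1:2, 1:2), "n >= 3")
})
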