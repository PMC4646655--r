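#' Classify COGs as core, accessory or unique
#'
#' Core: present in all genomes; unique: present in exactly one; accessory:
#' anything in between.
#'
#' @param summary COG summary from [cog_summary()] (needs `cog_id`,
#'   `genome_count`).
#' @param n_genomes Number of genomes in the analysis.
#' @return The summary with an added `category` column.
#' @export
classify_cogs <- function(summary, n_genomes) {
  if (any(summary$genome_count > n_genomes))
    stop("COG genome_count exceeds the number of genomes")
  summary$category <- ifelse(summary$genome_count == n_genomes, "core",
                             ifelse(summary$genome_count == 1L, "unique",
                                    "accessory"))
  summary
}

#' Genome x COG presence/absence matrix
#'
#' @param membership COG membership table from [cluster_cogs()].
#' @return Binary matrix, genomes as rows, COGs as columns.
#' @export
presence_absence_matrix <- function(membership) {
  genomes <- sort(unique(membership$genome_id))
  cogs <- sort(unique(membership$cog_id))
  m <- matrix(0L, nrow = length(genomes), ncol = length(cogs),
              dimnames = list(genomes, cogs))
  m[cbind(match(membership$genome_id, genomes),
          match(membership$cog_id, cogs))] <- 1L
  m
}

#' Pan- and core-genome accumulation (rarefaction) curves
#'
#' For each random permutation of genome order, the running union (pan) and
#' intersection (core) of gene families over the first k genomes is
#' recorded; the curve reports the mean and the 2.5/97.5 percentile band
#' across permutations at each k.
#'
#' @param pam Presence/absence matrix from [presence_absence_matrix()].
#' @param n_permutations Number of genome-order permutations.
#' @param seed Random seed (reproducible).
#' @param exhaustive Enumerate all `n!` genome orders instead of sampling
#'   (allowed for up to 8 genomes); `n_permutations` and `seed` are then
#'   ignored.
#' @return A `data.frame` of class `accumulation_curves` with columns `k`,
#'   `pan_mean`, `pan_lo`, `pan_hi`, `core_mean`, `core_lo`, `core_hi`.
#' @export
accumulation_curves <- function(pam, n_permutations = 1000L, seed = 1L,
                                exhaustive = FALSE) {
  if (!is.matrix(pam) || nrow(pam) == 0L || ncol(pam) == 0L)
    stop("empty presence/absence matrix")
  stopifnot(n_permutations >= 1L)
  n <- nrow(pam)
  orders <- NULL
  if (exhaustive) {
    if (n > 8L) stop("exhaustive enumeration is limited to 8 genomes")
    orders <- .all_permutations(n)
    n_permutations <- nrow(orders)
  }
  set.seed(seed)
  pan <- matrix(0L, n_permutations, n)
  core <- matrix(0L, n_permutations, n)
  for (p in seq_len(n_permutations)) {
    ord <- if (exhaustive) orders[p, ] else sample.int(n)
    m <- pam[ord, , drop = FALSE]
    # first row (in permuted order) where each family appears / disappears
    first_present <- apply(m, 2L, function(col) which(col == 1L)[1L])
    first_absent <- apply(m, 2L, function(col) {
      w <- which(col == 0L)
      if (length(w)) w[1L] else n + 1L
    })
    pan[p, ] <- cumsum(tabulate(first_present, nbins = n))
    core[p, ] <- ncol(m) - cumsum(tabulate(first_absent, nbins = n))
  }
  q <- function(m, pr) apply(m, 2L, quantile, probs = pr, names = FALSE)
  out <- data.frame(k = seq_len(n),
                    pan_mean = colMeans(pan),
                    pan_lo = q(pan, 0.025), pan_hi = q(pan, 0.975),
                    core_mean = colMeans(core),
                    core_lo = q(core, 0.025), core_hi = q(core, 0.975))
  attr(out, "n_permutations") <- n_permutations
  attr(out, "seed") <- if (exhaustive) NA_integer_ else seed
  class(out) <- c("accumulation_curves", "data.frame")
  out
}

.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' @export
plot.accumulation_curves <- function(x, ...) {
  plot(x$k, x$pan_mean, type = "l", ylim = c(0, max(x$pan_hi)),
       xlab = "number of genomes sampled", ylab = "gene families (COGs)",
       ...)
  graphics::lines(x$k, x$pan_lo, lty = 2)
  graphics::lines(x$k, x$pan_hi, lty = 2)
  graphics::lines(x$k, x$core_mean, col = 2)
  graphics::lines(x$k, x$core_lo, lty = 2, col = 2)
  graphics::lines(x$k, x$core_hi, lty = 2, col = 2)
  graphics::legend("topleft", legend = c("pan", "core"), col = c(1, 2),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Per-genome core/accessory/unique fractions
#'
#' Count fractions partition each genome's genes by the category of their
#' COG; the length fraction is the summed nucleotide length of core genes
#' over the genome length.
#'
#' @param membership COG membership table.
#' @param categories Classified summary from [classify_cogs()].
#' @param genes Gene table with `gene_id`, `start`, `end` (1-based
#'   inclusive); required for the length fraction.
#' @param genome_lengths Named vector of genome lengths (bp).
#' @return `data.frame` with per-genome fractions `core`, `accessory`,
#'   `unique` (by gene count) and `core_length_fraction`.
#' @export
genome_fractions <- function(membership, categories, genes = NULL,
                             genome_lengths = NULL) {
  cat_of <- setNames(categories$category, categories$cog_id)
  if (anyNA(cat_of[membership$cog_id]))
    stop("gene assigned to a COG without category")
  gcat <- cat_of[membership$cog_id]
  tab <- table(membership$genome_id, factor(gcat, c("core", "accessory",
                                                    "unique")))
  frac <- prop.table(tab, margin = 1L)
  out <- data.frame(genome_id = rownames(tab),
                    core = as.numeric(frac[, "core"]),
                    accessory = as.numeric(frac[, "accessory"]),
                    unique = as.numeric(frac[, "unique"]),
                    stringsAsFactors = FALSE)
  if (!is.null(genes) && !is.null(genome_lengths)) {
    glen <- setNames(genes$end - genes$start + 1L, genes$gene_id)
    if (anyNA(glen[membership$gene_id]))
      stop("gene without coordinates: ",
           membership$gene_id[which(is.na(glen[membership$gene_id]))[1L]])
    core_genes <- membership[gcat == "core", , drop = FALSE]
    core_len <- tapply(glen[core_genes$gene_id], core_genes$genome_id, sum)
    out$core_length_fraction <-
      as.numeric(core_len[out$genome_id]) /
      as.numeric(genome_lengths[out$genome_id])
  }
  out
}

#' Pairwise shared-gene fraction between genomes
#'
#' For genomes i and j: number of gene families present in both, divided by
#' the mean of the two genomes' family counts (default) or by the union size
#' (Jaccard-style alternative). Symmetric, diagonal 1.
#'
#' @param pam Presence/absence matrix.
#' @param denominator `"mean"` or `"union"`.
#' @return Symmetric matrix of fractions.
#' @export
pairwise_shared_fraction <- function(pam, denominator = c("mean", "union")) {
  denominator <- match.arg(denominator)
  if (nrow(pam) < 2L) stop("need at least 2 genomes")
  inter <- pam %*% t(pam)
  rs <- rowSums(pam)
  den <- if (denominator == "mean") outer(rs, rs, `+`) / 2
  else outer(rs, rs, `+`) - inter
  f <- inter / den
  diag(f) <- 1
  f
}

#' Ordinary least-squares line with r-squared
#'
#' Fits `y ~ x` via [stats::lm()]; `r_squared` is the squared Pearson
#' correlation.
#'
#' @param x,y Numeric vectors, length >= 3; `x` must not be constant.
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
linear_regression <- function(x, y) {
  if (length(x) < 3L || length(y) != length(x))
    stop("need n >= 3 paired observations")
  if (sd(x) == 0) stop("x is constant")
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = cor(x, y)^2, n = length(x))
}

#' Mean core-gene percent identity between genome pairs
#'
#' Averages, over core-gene alignments, the pairwise percent identity
#' (identical columns over columns where neither row is a gap) between each
#' pair of genomes.
#'
#' @param alignments List of core-gene alignments (named character vectors
#'   of gapped rows, names = genome ids; one sequence per genome).
#' @return Symmetric matrix of mean percent identities, diagonal 100.
#' @export
core_identity_matrix <- function(alignments) {
  stopifnot(length(alignments) >= 1L)
  genomes <- sort(names(alignments[[1L]]))
  acc <- matrix(0, length(genomes), length(genomes),
                dimnames = list(genomes, genomes))
  for (aln in alignments) {
    p <- protein_distance(aln, model = "p")[genomes, genomes]
    acc <- acc + 100 * (1 - p)
  }
  acc / length(alignments)
}
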