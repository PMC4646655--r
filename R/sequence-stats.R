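#' G+C content of a nucleotide sequence
#'
#' Fraction (G + C) / (A + C + G + T). IUPAC ambiguity codes are excluded
#' from both numerator and denominator, so the result is invariant under
#' reversal and complementation.
#'
#' @param seq A single nucleotide string.
#' @return G+C fraction in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty sequence")
  counts <- table(strsplit(toupper(seq), "", fixed = TRUE)[[1L]])
  acgt <- sum(counts[c("A", "C", "G", "T")], na.rm = TRUE)
  if (acgt == 0) stop("no unambiguous bases in sequence")
  gc <- sum(counts[c("G", "C")], na.rm = TRUE)
  gc / acgt
}

#' Per-group summary of percent G+C
#'
#' Computes n, mean, sample standard deviation (n - 1 denominator), minimum
#' and maximum of percent G+C for each group of genomes. Values are kept at
#' full precision; round only when reporting.
#'
#' @param x Either a numeric vector of percent G+C values named by genome
#'   id, or a sequence table (`data.frame` with `id` and `seq`) from which
#'   percent G+C is computed.
#' @param groups Named character vector mapping genome id to group label.
#' @return A `data.frame` with columns `group`, `n`, `mean_gc`, `sd_gc`,
#'   `min_gc`, `max_gc`.
#' @export
group_gc_summary <- function(x, groups) {
  if (is.data.frame(x)) {
    gc <- setNames(vapply(x$seq, gc_content, 0) * 100, x$id)
  } else {
    stopifnot(is.numeric(x))
    gc <- x
  }
  if (is.null(names(gc))) stop("G+C values must be named by genome id")
  missing_grp <- setdiff(names(gc), names(groups))
  if (length(missing_grp))
    stop("genome not assigned to any group: ",
         paste(missing_grp, collapse = ", "))
  grp <- groups[names(gc)]
  out <- do.call(rbind, lapply(split(gc, grp), function(v) {
    data.frame(n = length(v), mean_gc = mean(v),
               sd_gc = if (length(v) > 1L) sd(v) else 0,
               min_gc = min(v), max_gc = max(v))
  }))
  data.frame(group = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value, via [stats::t.test()]. When both groups are
#' constant and equal the comparison is degenerate; by convention `t = 0`,
#' `p = 1`, flagged in the result.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return A list with `t`, `df`, `p`, `degenerate`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observations")
  if (sd(x) == 0 && sd(y) == 0) {
    if (x[1L] == y[1L])
      return(list(t = 0, df = NA_real_, p = 1, degenerate = TRUE))
    stop("both groups constant with different values: t is infinite")
  }
  fit <- t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value, degenerate = FALSE)
}

#' Published marine cyanopodovirus genome metadata
#'
#' The 20-genome summary table shipped with the package: phage name, GenBank
#' accession, host genus, phylogenetic cluster, genome size (bp), annotated
#' ORF count and percent G+C, as printed in the source study. These values
#' serve as desk-scale inputs for the compositional statistics.
#'
#' @return A `data.frame` with one row per genome.
#' @export
cyanopodovirus_metadata <- function() {
  path <- system.file("extdata", "cyanopodovirus_genomes.tsv",
                      package = "phagepan", mustWork = TRUE)
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
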