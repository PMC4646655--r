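.aln_to_profile <- function(rows, alphabet) {
  # residue-count matrix (alphabet x columns); gaps contribute nothing
  L <- nchar(rows[1L])
  prof <- matrix(0, nrow = length(alphabet), ncol = L)
  for (r in rows) {
    code <- match(strsplit(r, "", fixed = TRUE)[[1L]], alphabet)
    ok <- which(!is.na(code))
    idx <- cbind(code[ok], ok)
    prof[idx] <- prof[idx] + 1
  }
  prof
}

.apply_path <- function(rows, path) {
  # path: 1-based source columns, 0 = inserted gap
  chars <- lapply(rows, function(r) strsplit(r, "", fixed = TRUE)[[1L]])
  vapply(chars, function(ch) {
    out <- rep("-", length(path))
    out[path > 0L] <- ch[path[path > 0L]]
    paste(out, collapse = "")
  }, "")
}

#' Shared k-mer distance between protein sequences
#'
#' `1 - shared / min(#kmers)` over the sets of overlapping k-mers; the guide
#' distance for [progressive_msa()].
#'
#' @param seqs Named character vector of protein sequences.
#' @param k Word size.
#' @return Symmetric distance matrix.
#' @export
kmer_distance <- function(seqs, k = 3L) {
  km <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      denom <- min(length(km[[i]]), length(km[[j]]))
      shared <- if (denom) length(intersect(km[[i]], km[[j]])) else 0L
      d[i, j] <- d[j, i] <- if (denom) 1 - shared / denom else 1
    }
  }
  d
}

#' Progressive multiple sequence alignment
#'
#' Clustal-class progressive alignment: a UPGMA guide tree from shared
#' 3-mer distances, then profile-profile global alignment with affine gaps
#' (BLOSUM62, open 11, extend 1) along the guide tree. Deterministic for a
#' fixed input order; no randomness involved.
#'
#' @param seqs Named character vector of protein sequences (>= 1).
#' @param params A [scoring_params()] object.
#' @param k Guide-tree word size.
#' @return Named character vector of equal-length gapped rows, in the input
#'   order (class `protein_alignment`).
#' @export
progressive_msa <- function(seqs, params = scoring_params(), k = 3L) {
  if (length(seqs) == 0L) stop("no sequences to align")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  if (any(!nzchar(seqs))) stop("empty sequence")
  if (length(seqs) == 1L)
    return(structure(seqs, class = "protein_alignment"))
  d <- kmer_distance(seqs, k = k)
  hc <- hclust(as.dist(d), method = "average")
  profiles <- lapply(seq_along(seqs), function(i) {
    structure(list(rows = setNames(seqs[i], names(seqs)[i])), done = TRUE)
  })
  merged <- vector("list", nrow(hc$merge))
  get_node <- function(v) if (v < 0L) profiles[[-v]] else merged[[v]]
  for (s in seq_len(nrow(hc$merge))) {
    a <- get_node(hc$merge[s, 1L])
    b <- get_node(hc$merge[s, 2L])
    pa <- .aln_to_profile(a$rows, params$alphabet)
    pb <- .aln_to_profile(b$rows, params$alphabet)
    al <- .nw_profile_align(pa, pb, params$submat, length(a$rows),
                            length(b$rows), params$gap_open,
                            params$gap_extend)
    rows <- c(.apply_path(a$rows, al$path_a),
              .apply_path(b$rows, al$path_b))
    names(rows) <- c(names(a$rows), names(b$rows))
    merged[[s]] <- list(rows = rows)
  }
  out <- merged[[nrow(hc$merge)]]$rows[names(seqs)]
  structure(out, class = "protein_alignment")
}

#' Trim divergent/gappy alignment blocks
#'
#' Drops columns whose gap fraction exceeds `max_gap_fraction` or whose
#' modal residue frequency (most common non-gap residue over the number of
#' rows) is below `min_conservation`; runs of retained columns shorter than
#' `min_block` are then dropped too. The retained column indices are kept in
#' the `"kept_columns"` attribute.
#'
#' @param aln Alignment (named character vector of equal-length rows).
#' @param max_gap_fraction Maximum tolerated gap fraction per column.
#' @param min_conservation Minimum modal-residue frequency per column.
#' @param min_block Minimum length of a retained run of columns.
#' @return Trimmed alignment with attribute `kept_columns`.
#' @export
trim_blocks <- function(aln, max_gap_fraction = 0.5, min_conservation = 0.5,
                        min_block = 5L) {
  if (length(aln) == 0L) stop("empty alignment")
  m <- do.call(rbind, strsplit(unclass(aln), "", fixed = TRUE))
  nr <- nrow(m)
  gap_frac <- colMeans(m == "-")
  modal <- apply(m, 2L, function(col) {
    col <- col[col != "-"]
    if (!length(col)) 0 else max(table(col)) / nr
  })
  keep <- gap_frac <= max_gap_fraction & modal >= min_conservation
  # drop short runs of retained columns
  r <- rle(keep)
  r$values[r$values & r$lengths < min_block] <- FALSE
  keep <- inverse.rle(r)
  if (!any(keep)) stop("empty after trimming: no column satisfies the rules")
  rows <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  out <- setNames(rows, names(aln))
  attr(out, "kept_columns") <- which(keep)
  class(out) <- "protein_alignment"
  out
}

#' Concatenate per-COG core alignments into a supermatrix
#'
#' One row per genome; columns are the input alignments laid side by side in
#' deterministic (sorted) COG-id order. Every alignment must contain exactly
#' one row per genome.
#'
#' @param alignments Named list (COG id -> alignment with rows named by
#'   genome id).
#' @param genomes Character vector of genome ids (row order of the result).
#' @return List with `alignment` (the supermatrix) and `map` (a `data.frame`
#'   of per-COG column ranges `cog_id`, `start`, `end`).
#' @export
concatenate_core <- function(alignments, genomes) {
  stopifnot(length(alignments) >= 1L, !is.null(names(alignments)))
  ord <- order(names(alignments))
  alignments <- alignments[ord]
  for (cid in names(alignments)) {
    missing_ <- setdiff(genomes, names(alignments[[cid]]))
    if (length(missing_))
      stop("genome missing from core alignment ", cid, ": ",
           paste(missing_, collapse = ", "))
  }
  widths <- vapply(alignments, function(a) nchar(a[[1L]]), 0)
  ends <- cumsum(widths)
  starts <- ends - widths + 1
  rows <- vapply(genomes, function(g) {
    paste(vapply(alignments, function(a) unname(a[[g]]), ""), collapse = "")
  }, "")
  aln <- structure(setNames(rows, genomes), class = "protein_alignment")
  list(alignment = aln,
       map = data.frame(cog_id = names(alignments), start = starts,
                        end = ends, row.names = NULL,
                        stringsAsFactors = FALSE))
}

#' Pairwise protein distances from an alignment
#'
#' p-distance: mismatch fraction over columns where neither row is a gap.
#' Poisson correction: `-ln(1 - p)`.
#'
#' @param aln Alignment (named character vector of equal-length rows).
#' @param model `"p"` or `"poisson"`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
protein_distance <- function(aln, model = c("p", "poisson")) {
  model <- match.arg(model)
  if (length(aln) < 2L) stop("need at least 2 sequences")
  m <- do.call(rbind, strsplit(unclass(aln), "", fixed = TRUE))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok))
        stop("no comparable columns between ", names(aln)[i], " and ",
             names(aln)[j])
      p <- mean(m[i, ok] != m[j, ok])
      if (model == "poisson") {
        if (p >= 1)
          stop("saturated pair under poisson correction: ", names(aln)[i],
               " vs ", names(aln)[j], " (p = ", p, ")")
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}
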