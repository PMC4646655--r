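#' Parse a Newick string into a phylogenetic tree
#'
#' Thin validating layer over [ape::read.tree()]. Bootstrap or consensus
#' supports, when present, are carried as internal-node labels in `[0, 100]`
#' (written before the branch length, i.e. `label:length`).
#'
#' @param text A Newick string (terminating semicolon required).
#' @return An object of class `phylo`.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!grepl(";\\s*$", text)) stop("Newick string lacks terminating semicolon")
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop("unbalanced parentheses in Newick string (", n_open, " '(' vs ",
         n_close, "')')")
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("failed to parse Newick string")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate leaf label: ", paste(dup, collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch length in Newick input")
  tree
}

#' Serialize a tree to Newick
#'
#' @param tree A `phylo` object; internal-node labels (supports) are kept.
#' @param digits Significant digits for branch lengths.
#' @return A Newick string.
#' @export
write_newick <- function(tree, digits = 6L) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = digits)
}

#' Write a labelled matrix as TSV
#'
#' First column holds row labels; the header row holds column labels.
#'
#' @param m A matrix (binary or real).
#' @param path Output file path.
#' @param row_labels,col_labels Optional label vectors; default to the
#'   dimnames of `m`.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, row_labels = rownames(m),
                             col_labels = colnames(m)) {
  stopifnot(is.matrix(m))
  if (is.null(row_labels) || is.null(col_labels))
    stop("row and column labels are required")
  if (anyDuplicated(row_labels)) stop("duplicate row label")
  if (anyDuplicated(col_labels)) stop("duplicate column label")
  dimnames(m) <- list(row_labels, col_labels)
  df <- data.frame(label = row_labels, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a labelled TSV matrix written by [write_matrix_tsv()]
#'
#' @param path Input file path.
#' @return A numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("empty matrix file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != nfield[1L]))
    stop("ragged row at line ", which(nfield != nfield[1L])[1L], " of ", path)
  header <- parts[[1L]][-1L]
  if (anyDuplicated(header)) stop("duplicate column label in ", path)
  body <- parts[-1L]
  labels <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(labels)) stop("duplicate row label in ", path)
  vals <- vapply(body, function(p) as.numeric(p[-1L]), numeric(length(header)))
  m <- if (length(header) == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (anyNA(m)) stop("non-numeric matrix entry in ", path)
  dimnames(m) <- list(labels, header)
  m
}
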