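#' Scoring parameters for protein local alignment
#'
#' BLOSUM62 with affine gaps (open 11, extend 1) and the fixed gapped
#' Karlin-Altschul constants lambda = 0.267, K = 0.041 used to convert raw
#' scores to bit scores and e-values. E-values use the pairwise search space
#' `m * n`, not database-wide effective lengths, so they are reproducible
#' without modelling a search database.
#'
#' @param matrix_name Substitution matrix name (shipped with Biostrings).
#' @param gap_open,gap_extend Affine gap penalties; a gap of length k costs
#'   `gap_open + k * gap_extend`.
#' @param lambda,K Karlin-Altschul constants for the chosen scoring system.
#' @return An object of class `scoring_params`.
#' @export
scoring_params <- function(matrix_name = "BLOSUM62", gap_open = 11,
                           gap_extend = 1, lambda = 0.267, K = 0.041) {
  stopifnot(gap_open >= gap_extend, gap_extend >= 0, lambda > 0, K > 0)
  env <- new.env()
  utils::data(list = matrix_name, package = "Biostrings", envir = env)
  submat <- get(matrix_name, envir = env)
  structure(list(matrix_name = matrix_name, submat = submat,
                 alphabet = rownames(submat), gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "scoring_params")
}

.aa_encode <- function(seq, alphabet) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  code <- match(ch, alphabet) - 1L
  if (anyNA(code))
    stop("residue outside the substitution-matrix alphabet: ",
         ch[which(is.na(code))[1L]])
  code
}

#' Bit score from a raw alignment score
#'
#' `bit = (lambda * S - ln K) / ln 2`.
#'
#' @param score Raw alignment score.
#' @param params A [scoring_params()] object.
#' @return Bit score.
#' @export
bit_score <- function(score, params = scoring_params()) {
  (params$lambda * score - log(params$K)) / log(2)
}

#' E-value for a bit score in a pairwise search space
#'
#' `E = m * n / 2^bit`.
#'
#' @param bit Bit score.
#' @param m,n Query and subject lengths (residues), both positive.
#' @return Expected number of chance alignments, >= 0.
#' @export
evalue <- function(bit, m, n) {
  if (any(m <= 0) || any(n <= 0)) stop("sequence lengths must be positive")
  m * n * 2^(-bit)
}

#' Optimal local alignment of two proteins
#'
#' Smith-Waterman with affine gaps under the given scoring parameters.
#' Percent identity is identical columns over the alignment length (gap
#' columns included).
#'
#' @param a,b Protein strings (query, subject).
#' @param params A [scoring_params()] object.
#' @return A list with `score`, `bit_score`, `evalue`, `pident`,
#'   `align_len`, `mismatches`, `gap_opens`, `q_start`, `q_end`, `s_start`,
#'   `s_end`.
#' @export
align_local <- function(a, b, params = scoring_params()) {
  stopifnot(is.character(a), is.character(b))
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  ea <- .aa_encode(a, params$alphabet)
  eb <- .aa_encode(b, params$alphabet)
  r <- .sw_align_pair(ea, eb, params$submat, params$gap_open,
                      params$gap_extend)
  bit <- bit_score(r$score, params)
  list(score = r$score, bit_score = bit,
       evalue = evalue(bit, nchar(a), nchar(b)),
       pident = if (r$align_len > 0) 100 * r$n_ident / r$align_len else 0,
       align_len = r$align_len, mismatches = r$n_mismatch,
       gap_opens = r$gap_opens, q_start = r$q_start, q_end = r$q_end,
       s_start = r$s_start, s_end = r$s_end)
}

#' All-vs-all protein similarity search
#'
#' Computes the exact optimal local alignment score for every unordered pair
#' of distinct genes (a fast score-only pass), then materialises full hit
#' statistics for pairs whose e-value passes `max_evalue`, reporting one hit
#' per ordered direction. Self-hits are excluded. With `max_evalue = Inf`
#' every positive-score pair is reported.
#'
#' When `prefilter` is on (default whenever `max_evalue` is finite), only
#' pairs sharing exact 4-residue words are aligned (two shared words when
#' both sequences are 200 aa or longer, one otherwise). Like any word-seeded
#' search, this is a sensitivity/speed trade-off: for pairs within ~45%
#' divergence the expected number of shared words is large and the pruning
#' does not affect the reported hit set, while beyond ~55% divergence a
#' short pair can occasionally be missed. Set `prefilter = FALSE` for the
#' exhaustive behaviour.
#'
#' @param proteins `data.frame` with columns `genome_id`, `gene_id`, `seq`;
#'   gene ids must be globally unique.
#' @param params A [scoring_params()] object.
#' @param max_evalue Keep hits with e-value at or below this cutoff.
#' @param prefilter Restrict alignment to pairs sharing a 4-mer word.
#' @return Hit table in the 12-column layout of [parse_hits_table()],
#'   ordered by query then subject id.
#' @export
all_vs_all <- function(proteins, params = scoring_params(),
                       max_evalue = 1e-3, prefilter = is.finite(max_evalue)) {
  stopifnot(all(c("gene_id", "seq") %in% names(proteins)))
  ids <- proteins$gene_id
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate gene id: ", paste(dup, collapse = ", "))
  n <- length(ids)
  enc <- lapply(proteins$seq, .aa_encode, alphabet = params$alphabet)
  lens <- nchar(proteins$seq)
  if (n < 2L) return(.empty_hits())
  if (prefilter) {
    keys <- .seed_candidate_pairs(proteins$seq, n)
    if (!length(keys)) return(.empty_hits())
    pi <- as.integer((keys - 1) %/% n)
    pj <- as.integer((keys - 1) %% n)
  } else {
    pi <- rep.int(seq_len(n) - 1L, times = (n - 1L):0L)
    pj <- unlist(lapply(seq_len(n - 1L), function(i) i:(n - 1L)),
                 use.names = FALSE)
  }
  scores <- .sw_score_pairs(enc, pi, pj, params$submat, params$gap_open,
                            params$gap_extend)
  bits <- bit_score(scores, params)
  ev <- evalue(bits, lens[pi + 1L], lens[pj + 1L])
  keep <- which(scores > 0 & ev <= max_evalue)
  if (!length(keep)) return(.empty_hits())
  nk <- length(keep)
  det <- matrix(0, nrow = nk, ncol = 8L)  # per-pair traceback statistics
  for (k in seq_len(nk)) {
    p <- keep[k]
    r <- .sw_align_pair(enc[[pi[p] + 1L]], enc[[pj[p] + 1L]], params$submat,
                        params$gap_open, params$gap_extend)
    det[k, ] <- c(r$n_ident, r$n_mismatch, r$align_len, r$gap_opens,
                  r$q_start, r$q_end, r$s_start, r$s_end)
  }
  i <- pi[keep] + 1L; j <- pj[keep] + 1L
  pid <- ifelse(det[, 3L] > 0, 100 * det[, 1L] / det[, 3L], 0)
  out <- data.frame(
    query_id = c(ids[i], ids[j]), subject_id = c(ids[j], ids[i]),
    pident = c(pid, pid), align_len = rep(det[, 3L], 2L),
    mismatches = rep(det[, 2L], 2L), gap_opens = rep(det[, 4L], 2L),
    q_start = c(det[, 5L], det[, 7L]), q_end = c(det[, 6L], det[, 8L]),
    s_start = c(det[, 7L], det[, 5L]), s_end = c(det[, 8L], det[, 6L]),
    evalue = rep(ev[keep], 2L), bit_score = rep(bits[keep], 2L),
    stringsAsFactors = FALSE)
  out <- out[order(out$query_id, out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Unordered candidate pairs (0-based i < j) sharing 4-mer words, encoded
# i*n+j+1. Pairs where both sequences are >= 200 aa must share two distinct
# words (at that length any alignment a practical cutoff could accept shares
# many); shorter pairs need a single shared word.
.seed_candidate_pairs <- function(seqs, n, k = 4L, min_shared = 2L,
                                  long_len = 200L) {
  words <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character())
    unique(substring(s, 1:(L - k + 1L), k:L))
  })
  idx <- rep(seq_len(n) - 1L, lengths(words))
  sets <- split(idx, unlist(words, use.names = FALSE))
  sets <- sets[lengths(sets) >= 2L]
  if (!length(sets)) return(numeric())
  keys <- lapply(sets, function(v) {
    m <- length(v)
    a <- rep(v, times = (m - 1L):0L)
    b <- v[unlist(lapply(seq_len(m - 1L), function(i) (i + 1L):m),
               use.names = FALSE)]
    as.numeric(a) * n + b + 1
  })
  keys <- sort(unlist(keys, use.names = FALSE))
  r <- rle(keys)
  out <- r$values[r$lengths >= min_shared]
  if (min_shared > 1L) {
    short <- which(nchar(seqs) < long_len) - 1L
    if (length(short)) {
      once <- r$values[r$lengths < min_shared]
      oi <- (once - 1) %/% n
      oj <- (once - 1) %% n
      out <- sort(c(out, once[oi %in% short | oj %in% short]))
    }
  }
  out
}

.empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pident = numeric(), align_len = numeric(),
             mismatches = numeric(), gap_opens = numeric(),
             q_start = numeric(), q_end = numeric(), s_start = numeric(),
             s_end = numeric(), evalue = numeric(), bit_score = numeric(),
             stringsAsFactors = FALSE)
}
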