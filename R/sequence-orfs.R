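.code11 <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::getGeneticCode("11")
    tab
  }
})

#' Translate a codon string under the bacterial/plastid code (table 11)
#'
#' @param codons Nucleotide string with length divisible by 3.
#' @param initiator If `TRUE` and the first codon is an allowed start
#'   (ATG, GTG, TTG), it is rendered as `M`.
#' @param strict If `TRUE`, an internal stop codon is an error; the trailing
#'   stop, when present, is always dropped.
#' @return Amino-acid string.
#' @export
translate_codons <- function(codons, initiator = FALSE, strict = TRUE) {
  stopifnot(is.character(codons), length(codons) == 1L)
  codons <- toupper(codons)
  n <- nchar(codons)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  if (grepl("[^ACGT]", codons)) stop("non-nucleotide characters in sequence")
  triplets <- substring(codons, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(.code11()[triplets])
  if (initiator && length(aa) && triplets[1L] %in% c("ATG", "GTG", "TTG"))
    aa[1L] <- "M"
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (strict && any(aa == "*"))
    stop("internal stop codon at codon ", which(aa == "*")[1L])
  paste(aa, collapse = "")
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Find open reading frames in a genome
#'
#' Six-frame scan of a linear genome. Within each stop-to-stop region the
#' longest ORF beginning at an allowed start codon and ending at a stop is
#' reported when it spans at least `min_codons` codons (stop included).
#' Reverse-strand ORFs are reported in forward-strand coordinates with
#' strand `-`. Proteins are translated with code table 11 and the initiator
#' codon rendered as `M`; the stop is not part of the protein.
#'
#' @param seq Genome nucleotide string (A/C/G/T only).
#' @param genome_id Identifier used to derive gene ids.
#' @param min_codons Minimum ORF length in codons, stop codon included.
#' @param start_codons Allowed initiator codons.
#' @return A `data.frame` with columns `genome_id`, `gene_id`, `start`,
#'   `end`, `strand`, `protein`, ordered by `start`.
#' @export
find_orfs <- function(seq, genome_id = "genome", min_codons = 30L,
                      start_codons = c("ATG", "GTG", "TTG")) {
  stopifnot(is.character(seq), length(seq) == 1L, min_codons >= 2L)
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) stop("non-nucleotide characters in sequence")
  L <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  scan_strand <- function(s, strand) {
    out <- list()
    for (off in 0:2) {
      n_codon <- (nchar(s) - off) %/% 3L
      if (n_codon < 1L) next
      pos <- off + seq(1L, by = 3L, length.out = n_codon)
      cod <- substring(s, pos, pos + 2L)
      stop_idx <- which(cod %in% stops)
      region_start <- 1L
      for (si in stop_idx) {
        starts_in <- which(cod[region_start:si] %in% start_codons)
        if (length(starts_in)) {
          first <- region_start + starts_in[1L] - 1L
          len_codons <- si - first + 1L  # stop included
          if (len_codons >= min_codons) {
            nt_start <- pos[first]
            nt_end <- pos[si] + 2L
            prot <- translate_codons(substr(s, nt_start, nt_end),
                                     initiator = TRUE)
            out[[length(out) + 1L]] <-
              data.frame(start = nt_start, end = nt_end, strand = strand,
                         protein = prot, stringsAsFactors = FALSE)
          }
        }
        region_start <- si + 1L
      }
    }
    out
  }
  fwd <- scan_strand(seq, "+")
  rev_ <- scan_strand(.revcomp(seq), "-")
  rev_ <- lapply(rev_, function(d) {
    new_start <- L - d$end + 1L
    d$end <- L - d$start + 1L
    d$start <- new_start
    d
  })
  all <- c(fwd, rev_)
  if (!length(all)) {
    return(data.frame(genome_id = character(), gene_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), protein = character(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, all)
  df <- df[order(df$start, df$end, df$strand), , drop = FALSE]
  data.frame(genome_id = genome_id,
             gene_id = sprintf("%s_%03d", genome_id, seq_len(nrow(df))),
             df, row.names = NULL, stringsAsFactors = FALSE)
}
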