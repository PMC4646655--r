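#' Read a FASTA file into a sequence table
#'
#' Parses FASTA via [Biostrings::readBStringSet()] and returns one row per
#' record. The token up to the first whitespace in the header is the record
#' id; the remainder is the description. Wrapped sequence lines are
#' concatenated and residues uppercased.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` with columns `id`, `desc`, `seq`. An empty FASTA
#'   file yields a zero-row table.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank) == 0L) {
    return(data.frame(id = character(), desc = character(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  if (substr(trimws(nonblank[1L]), 1L, 1L) != ">")
    stop("not a FASTA file (first non-blank character is not '>'): ", path)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("record with empty sequence: ", paste(ids[empty], collapse = ", "))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA id: ", paste(dup, collapse = ", "))
  data.frame(id = ids, desc = desc, seq = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write a sequence table to FASTA
#'
#' @param records A `data.frame` with columns `id`, `seq` and optionally
#'   `desc`, as returned by [read_fasta()].
#' @param path Output file path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  dup <- unique(records$id[duplicated(records$id)])
  if (length(dup)) stop("duplicate FASTA id: ", paste(dup, collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  desc <- if ("desc" %in% names(records)) records$desc else rep("", nrow(records))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(desc[i])) paste(records$id[i], desc[i]) else records$id[i]
    writeLines(paste0(">", hdr), con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Parse a 12-column tabular similarity-hit file
#'
#' Reads the standard 12-column tab-separated layout emitted by pairwise
#' similarity-search tools: query id, subject id, percent identity,
#' alignment length, mismatches, gap opens, query start/end, subject
#' start/end, e-value, bit score. Coordinates are 1-based inclusive.
#'
#' @param path Path to the tabular file.
#' @return A `data.frame` of hits (columns `query_id`, `subject_id`,
#'   `pident`, `align_len`, `mismatches`, `gap_opens`, `q_start`, `q_end`,
#'   `s_start`, `s_end`, `evalue`, `bit_score`). An empty file yields a
#'   zero-row table.
#' @export
parse_hits_table <- function(path) {
  if (!file.exists(path)) stop("hits file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  cols <- c("query_id", "subject_id", "pident", "align_len", "mismatches",
            "gap_opens", "q_start", "q_end", "s_start", "s_end",
            "evalue", "bit_score")
  if (length(lines) == 0L) {
    out <- data.frame(matrix(nrow = 0, ncol = 12))
    names(out) <- cols
    out$query_id <- character(); out$subject_id <- character()
    for (nm in cols[-(1:2)]) out[[nm]] <- numeric()
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- which(nfield != 12L)
  if (length(bad))
    stop("expected 12 tab-separated columns but found ", nfield[bad[1L]],
         " at line ", bad[1L], " of ", path)
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  out <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                    stringsAsFactors = FALSE)
  for (k in 3:12) {
    v <- suppressWarnings(as.numeric(m[, k]))
    nab <- which(is.na(v) & !is.na(m[, k]))
    if (length(nab))
      stop("unparsable numeric field '", m[nab[1L], k], "' in column ", k,
           " at line ", nab[1L], " of ", path)
    out[[cols[k]]] <- v
  }
  validate_hits(out)
  out
}

validate_hits <- function(hits) {
  bad <- hits$q_start > hits$q_end | hits$s_start > hits$s_end
  if (any(bad)) stop("hit with start > end at row ", which(bad)[1L])
  if (any(hits$pident < 0 | hits$pident > 100))
    stop("percent identity outside [0, 100]")
  if (any(hits$evalue < 0)) stop("negative e-value")
  if (any(hits$align_len < 1)) stop("alignment length < 1")
  invisible(hits)
}

#' Write hits in the 12-column tabular layout
#'
#' @param hits Hit table as returned by [parse_hits_table()] or
#'   [all_vs_all()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hits_table <- function(hits, path) {
  df <- hits[, c("query_id", "subject_id", "pident", "align_len",
                 "mismatches", "gap_opens", "q_start", "q_end",
                 "s_start", "s_end", "evalue", "bit_score")]
  df$evalue <- formatC(df$evalue, format = "g", digits = 6)
  df$bit_score <- formatC(df$bit_score, format = "g", digits = 6)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
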