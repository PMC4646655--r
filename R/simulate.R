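# amino-acid background frequencies (approximate natural composition)
.aa_background <- c(A = 0.079, R = 0.051, N = 0.045, D = 0.054, C = 0.019,
                    Q = 0.043, E = 0.063, G = 0.074, H = 0.022, I = 0.052,
                    L = 0.091, K = 0.057, M = 0.022, F = 0.039, P = 0.052,
                    S = 0.071, T = 0.058, W = 0.013, Y = 0.032, V = 0.065)

#' Point-substitute a protein sequence
#'
#' Each site is substituted independently with probability
#' `expected_fraction`; the replacement is drawn from a fixed amino-acid
#' background excluding the original residue.
#'
#' @param seq Protein string.
#' @param expected_fraction Per-site substitution probability in `[0, 1)`.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return Mutated protein string.
#' @export
mutate_protein <- function(seq, expected_fraction, seed = NULL) {
  if (expected_fraction < 0 || expected_fraction >= 1)
    stop("expected_fraction must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(ch)) < expected_fraction)
  aa <- names(.aa_background)
  repl <- sample(aa, length(hit), replace = TRUE, prob = .aa_background)
  same <- which(repl == ch[hit])
  while (length(same)) {  # redraw collisions: replacement excludes original
    repl[same] <- sample(aa, length(same), replace = TRUE,
                         prob = .aa_background)
    same <- same[repl[same] == ch[hit][same]]
  }
  ch[hit] <- repl
  paste(ch, collapse = "")
}

.random_protein <- function(n_codons) {
  body <- sample(names(.aa_background), n_codons - 1L, replace = TRUE,
                 prob = .aa_background)
  paste(c("M", body), collapse = "")
}

# synonymous codon table (code 11, stops excluded), split by third-base G/C
.codon_classes <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    code <- Biostrings::getGeneticCode("11")
    code <- code[code != "*"]
    by_aa <- split(names(code), code)
    cache <<- lapply(by_aa, function(cods) {
      third_gc <- substr(cods, 3L, 3L) %in% c("G", "C")
      list(gc = cods[third_gc], at = cods[!third_gc],
           gc_count_gc = if (any(third_gc))
             mean(vapply(strsplit(cods[third_gc], ""), function(x)
               sum(x %in% c("G", "C")), 0)) else NA_real_,
           gc_count_at = if (any(!third_gc))
             mean(vapply(strsplit(cods[!third_gc], ""), function(x)
               sum(x %in% c("G", "C")), 0)) else NA_real_)
    })
    cache
  }
})

# back-translate with two-class third-position G+C steering toward `target`
.back_translate <- function(protein, target) {
  classes <- .codon_classes()
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  info <- classes[aa]
  has_both <- vapply(info, function(x)
    length(x$gc) > 0 && length(x$at) > 0, TRUE)
  g_at <- vapply(info, function(x)
    if (length(x$at)) x$gc_count_at else x$gc_count_gc, 0)
  g_gc <- vapply(info, function(x)
    if (length(x$gc)) x$gc_count_gc else x$gc_count_at, 0)
  # expected GC count = sum(g_at) + q * sum over steerable of (g_gc - g_at);
  # the TAA stop contributes 3 nt and no G/C
  need <- target * (3L * length(aa) + 3L)
  base <- sum(g_at)
  gain <- sum((g_gc - g_at)[has_both])
  q <- if (gain > 0) (need - base) / gain else 0
  q <- min(1, max(0, q))
  pick_gc <- runif(length(aa)) < q & has_both
  codons <- vapply(seq_along(aa), function(i) {
    pool <- if (pick_gc[i] || length(info[[i]]$at) == 0L) info[[i]]$gc
    else info[[i]]$at
    if (length(pool) == 1L) pool else sample(pool, 1L)
  }, "")
  paste(c(codons, "TAA"), collapse = "")
}

.random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# ultrametric caterpillar Newick for a leaf set, root height hmax
.pectinate_newick <- function(leaves, hmax) {
  n <- length(leaves)
  if (n == 1L) return(list(text = leaves, height = 0))
  heights <- hmax * seq_len(n - 1L) / (n - 1L)
  cur <- leaves[1L]
  hprev <- 0
  for (i in 2L:n) {
    h <- heights[i - 1L]
    cur <- sprintf("(%s:%g,%s:%g)", cur, h - hprev, leaves[i], h)
    hprev <- h
  }
  list(text = cur, height = hprev)
}

.join_newick <- function(parts, h) {
  inner <- paste(vapply(parts, function(p)
    sprintf("%s:%g", p$text, h - p$height), ""), collapse = ",")
  list(text = sprintf("(%s)", inner), height = h)
}

#' Configuration for the synthetic phage-genome generator
#'
#' Defaults emulate a 20-genome marine cyanopodovirus-like collection: two
#' phylogenetic clusters (5 + 15 genomes), four subclusters within the large
#' cluster, 15 core genes shared by all genomes, cluster- and
#' subcluster-specific accessory blocks, ~12 unique genes per genome, two
#' host-group G+C regimes (0.39 and 0.50), genome lengths in 42.3-47.7 kb,
#' and 5 of the 15 core genes evolving on an alternative (recombined) guide
#' tree.
#'
#' @param n_core Number of core gene families.
#' @param n_recombinant_core Core families evolved on the alternative tree.
#' @param unique_per_genome Unique genes per genome.
#' @param gc_targets G+C targets for the low- and high-G+C host groups.
#' @param genome_length_range Genome length window (bp).
#' @param core_len_meanlog,core_len_sdlog Log-normal core gene length
#'   (codons).
#' @param acc_len_meanlog,acc_len_sdlog Log-normal accessory/unique gene
#'   length (codons).
#' @param within_subcluster_height,subcluster_height,cluster_height
#'   Ultrametric node heights of the genome tree, in expected substitutions
#'   per site (so maximum pairwise divergence is twice `cluster_height`).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_core = 15L, n_recombinant_core = 5L,
                       unique_per_genome = 12L,
                       gc_targets = c(low = 0.39, high = 0.50),
                       genome_length_range = c(42300L, 47700L),
                       core_len_meanlog = log(450), core_len_sdlog = 0.25,
                       acc_len_meanlog = log(150), acc_len_sdlog = 0.35,
                       within_subcluster_height = 0.04,
                       subcluster_height = 0.10,
                       cluster_height = 0.225) {
  stopifnot(n_core >= 0L, n_recombinant_core <= n_core,
            unique_per_genome >= 0L, all(gc_targets > 0 & gc_targets < 1))
  genomes <- sprintf("G%02d", 1:20)
  subclusters <- list(A1 = genomes[1:3], A2 = genomes[4:5],
                      B1 = genomes[6:10], B2 = genomes[11:15],
                      B3 = genomes[16:18], B4 = genomes[19:20])
  clusters <- list(A = genomes[1:5], B = genomes[6:20])
  gc_group <- setNames(rep("low", 20), genomes)
  gc_group[c(genomes[1:4], genomes[16:20])] <- "high"
  # accessory blocks: cluster-wide, subcluster-specific, subcluster pairs
  blocks <- list(
    list(name = "accA", genomes = clusters$A, n = 10L),
    list(name = "accB", genomes = clusters$B, n = 10L),
    list(name = "accA1", genomes = subclusters$A1, n = 5L),
    list(name = "accA2", genomes = subclusters$A2, n = 4L),
    list(name = "accB1", genomes = subclusters$B1, n = 6L),
    list(name = "accB2", genomes = subclusters$B2, n = 6L),
    list(name = "accB3", genomes = subclusters$B3, n = 6L),
    list(name = "accB4", genomes = subclusters$B4, n = 6L),
    list(name = "accB12", genomes = c(subclusters$B1, subclusters$B2),
         n = 4L),
    list(name = "accB34", genomes = c(subclusters$B3, subclusters$B4),
         n = 4L))
  structure(list(
    genomes = genomes, clusters = clusters, subclusters = subclusters,
    gc_group = gc_group, gc_targets = gc_targets, n_core = n_core,
    n_recombinant_core = n_recombinant_core, accessory_blocks = blocks,
    unique_per_genome = unique_per_genome,
    genome_length_range = genome_length_range,
    core_len_meanlog = core_len_meanlog, core_len_sdlog = core_len_sdlog,
    acc_len_meanlog = acc_len_meanlog, acc_len_sdlog = acc_len_sdlog,
    within_subcluster_height = within_subcluster_height,
    subcluster_height = subcluster_height,
    cluster_height = cluster_height), class = "sim_config")
}

.genome_tree <- function(config) {
  sc <- config$subclusters
  hw <- config$within_subcluster_height
  hs <- config$subcluster_height
  hc <- config$cluster_height
  sub <- lapply(sc, .pectinate_newick, hmax = hw)
  a <- .join_newick(sub[c("A1", "A2")], hs)
  b12 <- .join_newick(sub[c("B1", "B2")], hs)
  b34 <- .join_newick(sub[c("B3", "B4")], hs)
  b <- .join_newick(list(b12, b34), hs * 1.4)
  root <- .join_newick(list(a, b), hc)
  parse_newick(paste0(root$text, ";"))
}

# evolve an ancestral protein down a rooted tree; returns leaf sequences.
# The initiator residue is kept fixed (conserved start).
.evolve_on_tree <- function(tree, ancestral) {
  n_tip <- length(tree$tip.label)
  seqs <- vector("character", n_tip + tree$Nnode)
  root <- n_tip + 1L
  seqs[root] <- ancestral
  ord <- stats::reorder(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
    len <- ord$edge.length[e]
    mutated <- mutate_protein(seqs[parent], min(len, 0.95))
    substr(mutated, 1L, 1L) <- substr(seqs[parent], 1L, 1L)
    seqs[child] <- mutated
  }
  setNames(seqs[seq_len(n_tip)], tree$tip.label)
}

#' Simulate a phage genome collection with planted ground truth
#'
#' Draws an ancestral protein per gene family, evolves copies along the
#' genome tree (or, for the planted recombinant core families, along an
#' alternative guide tree obtained by permuting the genome labels),
#' back-translates each gene with third-position codon steering toward the
#' host group's G+C target, and lays genes out colinearly (shared families
#' in a common order, unique genes inserted at random positions) with random
#' intergenic spacers so that genome lengths fall in the configured window.
#' Byte-identical output for a fixed seed.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed.
#' @return An object of class `phage_simulation`: list with `genomes`
#'   (`id`, `seq`), `proteins` (`genome_id`, `gene_id`, `seq`), `genes`
#'   (`genome_id`, `gene_id`, `start`, `end`, `strand`) and `truth`
#'   (planted membership, categories, genome/alternative trees, recombinant
#'   family ids, cluster, subcluster and G+C group labels).
#' @export
simulate_genome_set <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  genomes <- config$genomes
  tree <- .genome_tree(config)
  alt_tree <- tree
  alt_tree$tip.label <- sample(tree$tip.label)  # recombined guide tree
  core_ids <- sprintf("CORE%02d", seq_len(config$n_core))
  recomb <- if (config$n_recombinant_core > 0L)
    core_ids[seq_len(config$n_recombinant_core)] else character()
  # family table: id, member genomes, category, guide tree
  fams <- list()
  for (cid in core_ids)
    fams[[cid]] <- list(genomes = genomes, category = "core",
                        alt = cid %in% recomb, core = TRUE)
  for (b in config$accessory_blocks)
    for (i in seq_len(b$n))
      fams[[sprintf("%s_%02d", toupper(b$name), i)]] <-
        list(genomes = b$genomes, category = "accessory", alt = FALSE,
             core = FALSE)
  # shared-family syntenic order: core anchors interleaved with blocks
  shared_ids <- names(fams)
  layout_order <- shared_ids[order(rank(shared_ids) %% 7L, shared_ids)]
  # draw ancestral proteins and evolve
  fam_seqs <- list()
  for (fid in names(fams)) {
    f <- fams[[fid]]
    len <- if (f$core)
      rlnorm(1L, config$core_len_meanlog, config$core_len_sdlog)
    else rlnorm(1L, config$acc_len_meanlog, config$acc_len_sdlog)
    len <- as.integer(max(60L, min(900L, round(len))))
    anc <- .random_protein(len)
    use_tree <- if (f$alt) alt_tree else tree
    leaves <- .evolve_on_tree(use_tree, anc)
    fam_seqs[[fid]] <- leaves[f$genomes]
  }
  # assemble genomes
  membership <- list(); proteins <- list(); genes <- list(); genome_rows <- list()
  low_hi <- config$gc_targets
  for (g in genomes) {
    present <- layout_order[vapply(layout_order, function(fid)
      g %in% fams[[fid]]$genomes, TRUE)]
    uniq_ids <- sprintf("UNIQ_%s_%02d", g, seq_len(config$unique_per_genome))
    slots <- sort(sample.int(length(present) + 1L,
                             config$unique_per_genome, replace = TRUE))
    order_ids <- character()
    ptr <- 1L
    for (s in seq_len(length(present) + 1L)) {
      order_ids <- c(order_ids, uniq_ids[slots == s])
      if (s <= length(present)) order_ids <- c(order_ids, present[s])
    }
    gc_t <- unname(low_hi[config$gc_group[g]])
    prot_of <- character(); nt_of <- character()
    for (fid in order_ids) {
      p <- if (startsWith(fid, "UNIQ")) {
        len <- as.integer(max(60L, min(900L, round(
          rlnorm(1L, config$acc_len_meanlog, config$acc_len_sdlog)))))
        .random_protein(len)
      } else fam_seqs[[fid]][[g]]
      prot_of[fid] <- p
      nt_of[fid] <- .back_translate(p, gc_t)
    }
    coding <- sum(nchar(nt_of))
    target_len <- round(runif(1L, config$genome_length_range[1L],
                              config$genome_length_range[2L]))
    n_gaps <- length(order_ids) + 1L
    spacer_total <- max(target_len - coding, 2L * n_gaps)
    gaps <- as.vector(rmultinom(1L, spacer_total - 2L * n_gaps,
                                rep(1, n_gaps))) + 2L
    pos <- 1L
    seq_parts <- character()
    gene_rows <- list()
    for (k in seq_along(order_ids)) {
      seq_parts <- c(seq_parts, .random_dna(gaps[k], gc_t))
      pos <- pos + gaps[k]
      nt <- nt_of[order_ids[k]]
      seq_parts <- c(seq_parts, nt)
      gene_id <- sprintf("%s_%03d", g, k)
      gene_rows[[k]] <- data.frame(
        genome_id = g, gene_id = gene_id, start = pos,
        end = pos + nchar(nt) - 1L, strand = "+",
        stringsAsFactors = FALSE)
      membership[[length(membership) + 1L]] <- data.frame(
        cog_id = order_ids[k], genome_id = g, gene_id = gene_id,
        stringsAsFactors = FALSE)
      proteins[[length(proteins) + 1L]] <- data.frame(
        genome_id = g, gene_id = gene_id, seq = prot_of[[order_ids[k]]],
        stringsAsFactors = FALSE)
      pos <- pos + nchar(nt)
    }
    seq_parts <- c(seq_parts, .random_dna(gaps[n_gaps], gc_t))
    genome_rows[[g]] <- data.frame(id = g,
                                   seq = paste(seq_parts, collapse = ""),
                                   stringsAsFactors = FALSE)
    genes[[g]] <- do.call(rbind, gene_rows)
  }
  membership <- do.call(rbind, membership)
  categories <- data.frame(
    cog_id = unique(membership$cog_id), stringsAsFactors = FALSE)
  categories$category <- ifelse(startsWith(categories$cog_id, "CORE"),
                                "core",
                                ifelse(startsWith(categories$cog_id, "UNIQ"),
                                       "unique", "accessory"))
  sub_of <- setNames(rep(names(config$subclusters),
                         lengths(config$subclusters)),
                     unlist(config$subclusters))
  clus_of <- setNames(rep(names(config$clusters),
                          lengths(config$clusters)),
                      unlist(config$clusters))
  structure(list(
    genomes = do.call(rbind, c(genome_rows, list(make.row.names = FALSE))),
    proteins = do.call(rbind, c(proteins, list(make.row.names = FALSE))),
    genes = do.call(rbind, c(genes, list(make.row.names = FALSE))),
    truth = list(membership = membership, categories = categories,
                 genome_tree = tree, alt_tree = alt_tree,
                 recombinant_core = recomb,
                 cluster = clus_of[genomes], subcluster = sub_of[genomes],
                 gc_group = config$gc_group),
    config = config, seed = seed), class = "phage_simulation")
}

#' @export
print.phage_simulation <- function(x, ...) {
  cat("phage_simulation:", nrow(x$genomes), "genomes,",
      nrow(x$proteins), "genes,",
      length(unique(x$truth$membership$cog_id)), "planted families",
      sprintf("(seed %d)\n", x$seed))
  invisible(x)
}
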