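# Independent oracles used across the suite. These deliberately avoid the
# package's own dynamic-programming code paths.

# Brute-force global affine alignment score by exhaustive enumeration of
# every monotone path through the alignment grid. A gap run of length L
# costs go + L * ge. Only usable for tiny sequences.
brute_global_score <- function(a, b, S, go = 10, ge = 0.2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  rec <- function(i, j, state) {
    if (i == n && j == m) return(0)
    best <- -Inf
    if (i < n && j < m) {
      best <- max(best, S[av[i + 1], bv[j + 1]] + rec(i + 1, j + 1, "m"))
    }
    if (i < n) {
      cost <- if (state == "x") ge else go + ge
      best <- max(best, -cost + rec(i + 1, j, "x"))
    }
    if (j < m) {
      cost <- if (state == "y") ge else go + ge
      best <- max(best, -cost + rec(i, j + 1, "y"))
    }
    best
  }
  rec(0, 0, "m")
}

# Brute-force local score: best global score over all substring pairs
# (the empty alignment scores 0).
brute_local_score <- function(a, b, S, go = 10, ge = 0.2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- 0
  for (i1 in seq_along(av)) for (i2 in i1:length(av)) {
    for (j1 in seq_along(bv)) for (j2 in j1:length(bv)) {
      s <- brute_global_score(paste(av[i1:i2], collapse = ""),
                              paste(bv[j1:j2], collapse = ""), S, go, ge)
      if (s > best) best <- s
    }
  }
  best
}

random_peptide <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), len,
               replace = TRUE), collapse = "")
}

mk_loci <- function(gene_id, chromosome, start, is_scaffold = FALSE,
                    len = 3000L) {
  data.frame(gene_id = gene_id, chromosome = chromosome,
             start = as.integer(start), end = as.integer(start + len - 1L),
             strand = "+", is_scaffold = is_scaffold,
             stringsAsFactors = FALSE)
}

# random genome layout: family genes interleaved with background genes
random_layout <- function(n_fam = 12, n_bg = 40, n_chrom = 3) {
  n <- n_fam + n_bg
  chrom <- sprintf("Chr%d", sample(n_chrom, n, replace = TRUE))
  start <- sample(1:3e6, n)
  ids <- c(sprintf("F%03d", seq_len(n_fam)), sprintf("B%03d", seq_len(n_bg)))
  all_loci <- mk_loci(ids, chrom, start, len = 1000L)
  list(all = all_loci, fam = all_loci[seq_len(n_fam), , drop = FALSE])
}

# O(n^2) adjacency-closure oracle for tandem clusters: union-find over ALL
# pairs of chromosome-placed family genes under the dual criterion.
oracle_clusters <- function(family_loci, all_loci, max_intervening = 5,
                            max_gap_bp = 100000) {
  all_loci <- lecfam::rank_loci(all_loci)
  loc <- all_loci[all_loci$gene_id %in% family_loci$gene_id, , drop = FALSE]
  if (!"is_scaffold" %in% names(loc)) loc$is_scaffold <- FALSE
  loc <- loc[!loc$is_scaffold, , drop = FALSE]
  n <- nrow(loc)
  parent <- seq_len(n)
  findp <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  fam_ranks <- split(loc$rank, loc$chromosome)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      if (loc$chromosome[i] != loc$chromosome[j]) next
      r1 <- min(loc$rank[i], loc$rank[j]); r2 <- max(loc$rank[i], loc$rank[j])
      fr <- fam_ranks[[loc$chromosome[i]]]
      nonfam <- (r2 - r1 - 1) - sum(fr > r1 & fr < r2)
      lo <- if (loc$start[i] <= loc$start[j]) i else j
      hi <- if (lo == i) j else i
      gap <- loc$start[hi] - loc$end[lo]
      if (nonfam <= max_intervening || gap <= max_gap_bp) {
        pi_ <- findp(i); pj <- findp(j)
        if (pi_ != pj) parent[pj] <- pi_
      }
    }
  }
  comp <- vapply(seq_len(n), findp, integer(1))
  groups <- split(loc$gene_id, comp)
  groups <- groups[vapply(groups, length, integer(1)) >= 2L]
  # canonical form: sorted members, sorted list
  sets <- sort(vapply(groups, function(g) paste(sort(g), collapse = ","),
                      character(1)))
  unname(sets)
}

cluster_sets <- function(clusters) {
  if (nrow(clusters) == 0L) return(character(0))
  sort(vapply(strsplit(clusters$members, ","), function(g)
    paste(sort(g), collapse = ","), character(1)))
}

# Named branch lengths keyed by canonical bipartition, for comparing trees
# on the same leaf set edge by edge.
edge_lengths_by_split <- function(tree, lens = tree$edge.length) {
  tips <- tree$tip.label
  ntip <- length(tips)
  res <- numeric(0)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    desc <- if (child <= ntip) tips[child] else
      tips[phangorn::Descendants(tree, child, "tips")[[1]]]
    side <- if (min(tips) %in% desc) setdiff(tips, desc) else desc
    res[paste(sort(side), collapse = "|")] <- lens[e]
  }
  res
}

# A random tree with strictly positive branch lengths and its additive
# (path-length) distance matrix.
random_additive_case <- function(ntaxa) {
  tr <- ape::rtree(ntaxa, br = NULL)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
  tr <- ape::unroot(tr)
  D <- ape::cophenetic.phylo(tr)
  D <- D[order(rownames(D)), order(colnames(D))]
  list(tree = tr, D = D)
}

# Evolve a 300-column protein alignment down a fixed 12-taxon tree with
# per-edge private diagnostic substitutions and zero homoplasy: every
# internal edge is supported by many exclusive columns.
strong_signal_alignment <- function(n_per_edge = 20, ncol_total = 300) {
  newick <- "(((t1,t2),(t3,t4)),((t5,t6),(t7,t8)),((t9,t10),(t11,t12)));"
  tr <- ape::read.tree(text = newick)
  tips <- tr$tip.label
  set.seed(99)
  anc <- sample(c("A", "G", "S", "T"), ncol_total, replace = TRUE)
  aln <- matrix(rep(anc, each = length(tips)), nrow = length(tips),
                dimnames = list(tips, NULL))
  ntip <- length(tips)
  col_cursor <- 1L
  internal <- which(tr$edge[, 2] > ntip)
  states <- c("W", "Y", "F", "H", "K", "R", "E", "D", "Q", "N", "M", "I",
              "L", "V", "C", "P")
  for (k in seq_along(internal)) {
    child <- tr$edge[internal[k], 2]
    desc <- tips[phangorn::Descendants(tr, child, "tips")[[1]]]
    cols <- col_cursor:(col_cursor + n_per_edge - 1L)
    stopifnot(max(cols) <= ncol_total)
    # private, edge-specific derived state: zero homoplasy by construction
    aln[desc, cols] <- states[(k - 1L) %% length(states) + 1L]
    col_cursor <- col_cursor + n_per_edge
  }
  structure(aln, class = "lecfam_msa")
}

# Tiny default configs used by several files (kept small for speed);
# overrides replace the small defaults.
small_sim_config <- function(...) {
  base <- list(
    n_family_members = 24,
    type_proportions = c(G = 16, L = 7, C = 1) / 24,
    class_distribution = c(I = 5, II = 8, III = 1, IV = 2, V = 1, VI = 2,
                           VII = 1, VIII = 1, NO_TM = 3) / 24,
    n_background_proteins = 20,
    tandem_cluster_sizes = c(3L), tandem_cluster_types = "G",
    super_cluster_size = 0L, n_scaffold_genes = 2L,
    divergence_rate = 0, fpkm_noise_sd = 0, seed = 42)
  args <- list(...)
  base[names(args)] <- args
  do.call(family_sim_config, base)
}
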