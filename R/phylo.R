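#' Progressive multiple sequence alignment
#'
#' Classic progressive strategy: p-distances from exact pairwise global
#' affine-gap alignments, a UPGMA guide tree (average-linkage clustering on
#' those distances), and profile-profile merges up the guide tree. Profile
#' columns are scored by the expected substitution score between the two
#' residue frequency profiles (gap frequency scores zero); gap penalties
#' are the scheme's affine costs. Sequences are ordered internally by
#' identifier, so the result is invariant to input order (up to row order,
#' which follows the input).
#'
#' @param sequences Named character vector of at least two amino-acid
#'   sequences.
#' @param scheme A [scoring_scheme()].
#' @return Object of class `lecfam_msa`: a character matrix of aligned
#'   rows ("-" for gaps), with sequence ids as rownames.
#' @export
progressive_msa <- function(sequences, scheme = scoring_scheme()) {
  if (length(sequences) < 2L) stop("need at least two sequences")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("sequences must carry unique names")
  }
  for (k in seq_along(sequences)) {
    check_aa_sequence(sequences[[k]], names(sequences)[k])
  }
  input_order <- names(sequences)
  sequences <- sequences[order(names(sequences))]
  ids <- names(sequences)
  alpha <- rownames(scheme$matrix)
  enc <- lapply(sequences, encode_aa, alphabet = alpha)
  D <- pairwise_pdist_cpp(enc, scheme$matrix, scheme$gap_open,
                          scheme$gap_extend)
  dimnames(D) <- list(ids, ids)
  S20 <- scheme$matrix[AA_ALPHABET20, AA_ALPHABET20]

  if (length(sequences) == 2L) {
    merged <- merge_profiles(seq_char_matrix(sequences[1]),
                             seq_char_matrix(sequences[2]), S20, scheme)
    return(structure(merged[input_order, , drop = FALSE],
                     class = "lecfam_msa"))
  }

  hc <- stats::hclust(stats::as.dist(D), method = "average")
  # nodes: negative = leaf index, positive = previous merge
  sub <- vector("list", nrow(hc$merge))
  get_aln <- function(node) {
    if (node < 0) seq_char_matrix(sequences[-node]) else sub[[node]]
  }
  for (k in seq_len(nrow(hc$merge))) {
    a <- get_aln(hc$merge[k, 1])
    b <- get_aln(hc$merge[k, 2])
    # deterministic child order: smaller first id goes left
    if (min(rownames(b)) < min(rownames(a))) { tmp <- a; a <- b; b <- tmp }
    sub[[k]] <- merge_profiles(a, b, S20, scheme)
  }
  aln <- sub[[nrow(hc$merge)]]
  structure(aln[input_order, , drop = FALSE], class = "lecfam_msa")
}

seq_char_matrix <- function(seqs) {
  m <- do.call(rbind, strsplit(unname(unlist(seqs)), ""))
  rownames(m) <- names(seqs)
  m
}

profile_freq <- function(aln) {
  vapply(AA_ALPHABET20, function(aa) colMeans(aln == aa),
         numeric(ncol(aln)))
}

merge_profiles <- function(a, b, S20, scheme) {
  fa <- profile_freq(a)                      # La x 20
  fb <- profile_freq(b)                      # Lb x 20
  if (ncol(a) == 1L) fa <- matrix(fa, nrow = 1L)
  if (ncol(b) == 1L) fb <- matrix(fb, nrow = 1L)
  CS <- fa %*% S20 %*% t(fb)
  path <- profile_align_cpp(CS, scheme$gap_open, scheme$gap_extend)
  moves <- path$moves
  out <- matrix("-", nrow = nrow(a) + nrow(b), ncol = length(moves))
  rownames(out) <- c(rownames(a), rownames(b))
  ia <- 0L; ib <- 0L
  ra <- seq_len(nrow(a)); rb <- nrow(a) + seq_len(nrow(b))
  for (k in seq_along(moves)) {
    if (moves[k] != 2L) { ia <- ia + 1L; out[ra, k] <- a[, ia] }
    if (moves[k] != 1L) { ib <- ib + 1L; out[rb, k] <- b[, ib] }
  }
  out
}

#' Pairwise distance between two aligned rows
#'
#' The raw p-distance is the mismatch fraction over the shared non-gap
#' columns. The protein Jukes-Cantor analogue corrects for multiple hits
#' over a 20-state alphabet: `d = -(19/20) * log(1 - (20/19) * p)`, defined
#' for `p < 19/20`; at or beyond that saturation bound the distance is
#' undefined and an error is raised.
#'
#' @param row_i,row_j Aligned rows (equal-length character vectors of
#'   residues and "-" gaps, or single gapped strings).
#' @param correction `"none"` (p-distance) or `"jukes_cantor_protein"`.
#' @return The distance (non-negative scalar).
#' @export
protein_distance <- function(row_i, row_j,
                             correction = c("jukes_cantor_protein", "none")) {
  correction <- match.arg(correction)
  if (is.character(row_i) && length(row_i) == 1L) row_i <- strsplit(row_i, "")[[1]]
  if (is.character(row_j) && length(row_j) == 1L) row_j <- strsplit(row_j, "")[[1]]
  if (length(row_i) != length(row_j)) stop("aligned rows must have equal length")
  shared <- row_i != "-" & row_j != "-"
  if (!any(shared)) stop("no shared non-gap columns")
  p <- sum(row_i[shared] != row_j[shared]) / sum(shared)
  if (correction == "none") return(p)
  if (p >= 19 / 20) stop("saturated distance: p = ", signif(p, 4),
                         " >= 19/20")
  -(19 / 20) * log(1 - (20 / 19) * p)
}

#' Distance matrix from a multiple alignment
#'
#' @param msa A `lecfam_msa` (or character matrix of aligned rows).
#' @param correction See [protein_distance()].
#' @return Symmetric distance matrix with zero diagonal.
#' @export
msa_distance_matrix <- function(msa,
                                correction = c("jukes_cantor_protein", "none")) {
  correction <- match.arg(correction)
  m <- unclass(msa)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- protein_distance(m[i, ], m[j, ], correction)
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  D
}

validate_distance_matrix <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm),
            !is.null(rownames(dm)),
            identical(rownames(dm), colnames(dm)))
  if (any(dm < 0)) stop("distance matrix has negative entries")
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(abs(diag(dm)) > 1e-12)) stop("distance matrix diagonal must be zero")
  dm
}

#' Neighbor-joining tree
#'
#' Classical neighbor joining (Saitou-Nei Q criterion with iterative
#' agglomeration). When several pairs minimise Q, the lowest (i, j) index
#' pair of the current matrix is taken, so the result is deterministic.
#' Negative branch-length estimates are clamped to zero in the returned
#' tree; the pre-clamp lengths are preserved in the
#' `"preclamp_edge_length"` attribute (aligned with `tree$edge`) and the
#' total clamped deficit in `"clamp_deficit"`. On an additive matrix the
#' generating topology and branch lengths are recovered exactly
#' (pre-clamp).
#'
#' @param dm Symmetric distance matrix with zero diagonal and row/column
#'   names (at least 3 taxa).
#' @return An [ape::read.tree()] "phylo" object (unrooted).
#' @export
nj_tree <- function(dm) {
  validate_distance_matrix(dm)
  n <- nrow(dm)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labs <- rownames(dm)
  frag_c <- stats::setNames(labs, labs)   # clamped newick fragments
  frag_p <- stats::setNames(labs, labs)   # pre-clamp newick fragments
  D <- dm
  active <- labs
  node_count <- 0L
  fmt <- function(x) sprintf("%.17g", x)
  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    node_count <- node_count + 1L
    u <- paste0("@", node_count)
    ai <- active[i]; aj <- active[j]
    frag_c[u] <- paste0("(", frag_c[ai], ":", fmt(max(0, vi)), ",",
                        frag_c[aj], ":", fmt(max(0, vj)), ")")
    frag_p[u] <- paste0("(", frag_p[ai], ":", fmt(vi), ",",
                        frag_p[aj], ":", fmt(vj), ")")
    duk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], duk[keep]),
                c(duk[keep], 0))
    active <- c(active[keep], u)
    dimnames(D2) <- list(active, active)
    D <- D2
  }
  # final three-taxon join (three-point formulas)
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  v <- c((d12 + d13 - d23) / 2, (d12 + d23 - d13) / 2, (d13 + d23 - d12) / 2)
  nw_c <- paste0("(", paste0(frag_c[active], ":", fmt(pmax(0, v)),
                             collapse = ","), ");")
  nw_p <- paste0("(", paste0(frag_p[active], ":", fmt(v),
                             collapse = ","), ");")
  tree <- ape::read.tree(text = nw_c)
  tree_p <- ape::read.tree(text = nw_p)
  attr(tree, "preclamp_edge_length") <- tree_p$edge.length
  attr(tree, "clamp_deficit") <- sum(pmin(tree_p$edge.length, 0))
  tree
}

# Canonical bipartition keys of all internal (non-trivial) edges of an
# unrooted tree: each key is the sorted tip set of the split side NOT
# containing the alphabetically first tip, collapsed with "|".
tree_splits <- function(tree) {
  tips <- tree$tip.label
  ref <- min(tips)
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    side <- tips[p]
    if (length(side) <= 1L || length(side) >= length(tips) - 1L) next
    if (ref %in% side) side <- setdiff(tips, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

split_key <- function(gene_set, tips) {
  ref <- min(tips)
  side <- if (ref %in% gene_set) setdiff(tips, gene_set) else gene_set
  paste(sort(side), collapse = "|")
}

#' Is a set of leaves monophyletic?
#'
#' True iff some edge bipartition of the (unrooted) tree isolates exactly
#' the given set. Singletons and the full leaf set are trivially
#' monophyletic.
#'
#' @param tree A "phylo" object.
#' @param gene_set Character vector of leaf labels.
#' @return Logical flag.
#' @export
is_monophyletic <- function(tree, gene_set) {
  tips <- tree$tip.label
  unknown <- setdiff(gene_set, tips)
  if (length(unknown) > 0L) {
    stop("unknown leaf id(s): ", paste(unknown, collapse = ", "))
  }
  gene_set <- unique(gene_set)
  if (length(gene_set) <= 1L || length(gene_set) >= length(tips) - 1L) {
    return(TRUE)
  }
  split_key(gene_set, tips) %in% tree_splits(tree)
}

#' Column-bootstrap supports for the neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' distance-plus-NJ tree per replicate, and reports for every internal
#' bipartition of the full-data tree the fraction of replicates containing
#' it. Replicates in which some pair has no shared non-gap column or a
#' saturated distance are redrawn (counted in the `"redraws"` attribute).
#' Deterministic under a fixed seed.
#'
#' @param msa A `lecfam_msa`.
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param correction See [protein_distance()].
#' @return The full-data NJ tree with `node.label` carrying supports;
#'   attribute `"supports"` maps split keys to support fractions,
#'   attribute `"redraws"` counts redrawn replicates.
#' @export
bootstrap_support <- function(msa, n_replicates = 1000, seed = 1,
                              correction = c("jukes_cantor_protein", "none")) {
  correction <- match.arg(correction)
  m <- unclass(msa)
  if (ncol(m) < 2L) stop("alignment must have at least 2 columns")
  full <- nj_tree(msa_distance_matrix(m, correction))
  keys <- tree_splits(full)
  counts <- stats::setNames(numeric(length(keys)), keys)
  set.seed(seed)
  redraws <- 0L
  for (rep in seq_len(n_replicates)) {
    repeat {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      Dr <- tryCatch(msa_distance_matrix(m[, cols, drop = FALSE], correction),
                     error = function(e) NULL)
      if (!is.null(Dr)) break
      redraws <- redraws + 1L
      if (redraws > 100L * n_replicates) {
        stop("bootstrap: too many degenerate replicates")
      }
    }
    rkeys <- tree_splits(nj_tree(Dr))
    hit <- keys %in% rkeys
    counts[hit] <- counts[hit] + 1
  }
  supports <- counts / n_replicates
  full <- annotate_supports(full, supports)
  attr(full, "supports") <- supports
  attr(full, "redraws") <- redraws
  full
}

annotate_supports <- function(tree, supports) {
  tips <- tree$tip.label
  parts <- ape::prop.part(tree)
  labs <- character(tree$Nnode)
  for (k in seq_along(parts)) {
    side <- tips[parts[[k]]]
    if (length(side) <= 1L || length(side) >= length(tips) - 1L) {
      labs[k] <- ""
      next
    }
    key <- split_key(side, tips)
    labs[k] <- if (key %in% names(supports))
      format(supports[[key]], digits = 3) else ""
  }
  tree$node.label <- labs
  tree
}

#' Export a distance matrix in square PHYLIP format
#' @param dm Distance matrix.
#' @param path Output path.
#' @export
write_phylip_dist <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dm)), con)
  for (i in seq_len(nrow(dm))) {
    writeLines(paste(sprintf("%-10s", rownames(dm)[i]),
                     paste(sprintf("%.6f", dm[i, ]), collapse = " ")), con)
  }
  invisible(path)
}
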