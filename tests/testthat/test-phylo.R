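test_that("progressive MSA handles identical, gapped and reordered inputs", {
  m <- progressive_msa(c(a = "MKVLW", b = "MKVLW"))
  expect_false(any(m == "-"))
  expect_equal(paste(m["a", ], collapse = ""), "MKVLW")

  m2 <- progressive_msa(c(x = "ACDEF", y = "ACEF"))
  expect_equal(ncol(m2), 5L)
  expect_equal(sum(m2 == "-"), 1L)
  # ungapping recovers the inputs
  expect_equal(paste(m2["y", m2["y", ] != "-"], collapse = ""), "ACEF")
  # the merged score equals the pairwise DP optimum
  pw <- align("ACDEF", "ACEF", mode = "global")
  sch <- scoring_scheme()
  msa_score <- sum(vapply(seq_len(ncol(m2)), function(j) {
    if (any(m2[, j] == "-")) return(NA_real_)
    sch$matrix[m2[1, j], m2[2, j]]
  }, numeric(1)), na.rm = TRUE) - (sch$gap_open + sch$gap_extend)
  expect_equal(msa_score, pw$score)

  set.seed(3)
  seqs <- setNames(vapply(1:5, function(k) random_peptide(40), character(1)),
                   paste0("s", 1:5))
  m3 <- progressive_msa(seqs)
  m4 <- progressive_msa(seqs[c(4, 2, 5, 1, 3)])
  expect_equal(unclass(m3)[rownames(m4), ], unclass(m4))
  for (id in names(seqs)) {
    expect_equal(paste(m3[id, m3[id, ] != "-"], collapse = ""), seqs[[id]])
  }
})

test_that("protein distances follow the 20-state Jukes-Cantor form", {
  expect_equal(protein_distance("MKVLW", "MKVLW"), 0)
  expect_equal(protein_distance("MKVLW", "MKVLW", "none"), 0)
  # p = 0.1 over 10 shared columns
  a <- "AAAAAAAAAA"
  b <- "CAAAAAAAAA"
  expect_equal(protein_distance(a, b, "none"), 0.1)
  expect_equal(protein_distance(a, b), -0.95 * log(1 - 0.10 / 0.95))
  # gaps shrink the shared-column denominator
  expect_equal(protein_distance("-AAAA", "CAAAA", "none"), 0)
  expect_error(protein_distance("-----", "AAAAA"), "shared")
  # saturation at p >= 19/20
  a20 <- strrep("A", 20)
  b20 <- paste0(strrep("C", 19), "A")
  expect_equal(protein_distance(a20, b20, "none"), 0.95)
  expect_error(protein_distance(a20, b20), "saturated")
})

test_that("NJ solves the three-taxon case by the closed-form formulas", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  v <- edge_lengths_by_split(tr)
  expect_equal(unname(v[["b"]]), (3 + 5 - 4) / 2)  # 2
  expect_equal(unname(v[["c"]]), (4 + 5 - 3) / 2)  # 3
  # a's edge appears as the complement side {b,c}
  expect_equal(unname(v[["b|c"]]), (3 + 4 - 5) / 2)  # 1
})

test_that("NJ recovers random additive trees exactly (pre-clamp)", {
  skip_if_not_installed("phangorn")
  set.seed(41)
  for (k in 1:25) {
    case <- random_additive_case(sample(4:12, 1))
    tr <- nj_tree(case$D)
    expect_equal(phangorn::RF.dist(ape::unroot(tr), case$tree), 0)
    got <- edge_lengths_by_split(tr, attr(tr, "preclamp_edge_length"))
    want <- edge_lengths_by_split(case$tree)
    expect_setequal(names(got), names(want))
    expect_equal(got[names(want)], want, tolerance = 1e-9)
    # independent implementation agrees on the topology
    expect_equal(phangorn::RF.dist(ape::unroot(ape::nj(case$D)),
                                   ape::unroot(tr)), 0)
  }
})

test_that("NJ validates its input and clamps negative branch estimates", {
  D <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(D), "at least 3")
  bad <- matrix(c(0, 1, 2, 1, 0, 1, 2.5, 1, 0), 3, 3,
                dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(bad), "symmetric")
  # a distance matrix violating the triangle structure produces a negative
  # three-point estimate, which is clamped with the deficit recorded
  D3 <- matrix(c(0, 10, 1, 10, 0, 2, 1, 2, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  tr <- nj_tree(D3)
  expect_true(all(tr$edge.length >= 0))
  expect_lt(attr(tr, "clamp_deficit"), 0)
})

test_that("bootstrap supports are deterministic, bounded, and saturate on strong signal", {
  aln <- strong_signal_alignment()
  tr1 <- bootstrap_support(aln, n_replicates = 50, seed = 7)
  tr2 <- bootstrap_support(aln, n_replicates = 50, seed = 7)
  expect_identical(attr(tr1, "supports"), attr(tr2, "supports"))
  s <- attr(tr1, "supports")
  expect_true(all(s >= 0 & s <= 1))
  expect_true(all(s >= 0.99))   # zero homoplasy: every split in every replicate

  one <- bootstrap_support(aln, n_replicates = 1, seed = 3)
  expect_true(all(attr(one, "supports") %in% c(0, 1)))
})

test_that("monophyly checks match exhaustive bipartition enumeration", {
  set.seed(13)
  case <- random_additive_case(8)
  tr <- case$tree
  tips <- tr$tip.label
  # oracle: enumerate every internal bipartition from the tree structure
  all_splits <- lapply(which(tr$edge[, 2] > length(tips)), function(e) {
    sort(tips[phangorn::Descendants(tr, tr$edge[e, 2], "tips")[[1]]])
  })
  is_mono_oracle <- function(set) {
    set <- sort(set)
    comp <- sort(setdiff(tips, set))
    length(set) <= 1 || length(comp) <= 1 ||
      any(vapply(all_splits, function(s) identical(s, set) ||
                   identical(s, comp), logical(1)))
  }
  expect_true(is_monophyletic(tr, tips))
  expect_true(is_monophyletic(tr, tips[3]))
  expect_error(is_monophyletic(tr, "nope"), "unknown leaf")
  for (k in 1:40) {
    set <- sample(tips, sample(2:6, 1))
    expect_equal(is_monophyletic(tr, set), is_mono_oracle(set),
                 label = paste(sort(set), collapse = ","))
  }
})

test_that("tandem-cluster members diverged from one ancestor form a clade", {
  set.seed(19)
  root <- random_peptide(150)
  # each cluster descends from its own diverged ancestor, so its members
  # share a long internal edge; singletons hang off the root
  anc1 <- mutate_family(root, 1, 0.3, seed = 49)
  anc2 <- mutate_family(root, 1, 0.3, seed = 50)
  cl1 <- mutate_family(anc1, 4, 0.03, seed = 51)
  cl2 <- mutate_family(anc2, 4, 0.03, seed = 52)
  lone <- mutate_family(root, 2, 0.1, seed = 53)
  seqs <- setNames(c(cl1, cl2, lone),
                   c(paste0("c1_", 1:4), paste0("c2_", 1:4), paste0("x", 1:2)))
  msa <- progressive_msa(seqs)
  tr <- nj_tree(msa_distance_matrix(msa))
  expect_true(is_monophyletic(tr, paste0("c1_", 1:4)))
  expect_true(is_monophyletic(tr, paste0("c2_", 1:4)))
})
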