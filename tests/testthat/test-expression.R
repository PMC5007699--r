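std_grouping <- function() {
  tissue_grouping(
    c("root.1", "root.2", "leaf.1", "leaf.2", "leaf.3", "stem.1", "stem.2",
      "bud.1", "bud.2", "bud.3", "bud.4", "bud.5"),
    c("root", "root", "leaf", "leaf", "leaf", "stem", "stem",
      "bud", "bud", "bud", "bud", "bud"))
}

mk_matrix <- function(values) {
  g <- std_grouping()
  m <- matrix(0, nrow = length(values), ncol = length(g),
              dimnames = list(names(values), names(g)))
  for (gene in names(values)) {
    for (tt in names(values[[gene]])) {
      m[gene, unname(g) == tt] <- values[[gene]][[tt]]
    }
  }
  m
}

test_that("the FPKM >= 1 detection boundary is exact", {
  g <- std_grouping()
  m <- mk_matrix(list(a = c(root = 0), b = c(root = 0), c = c(root = 0.99)))
  m["b", "root.1"] <- 1.0   # exactly at the cutoff, single sample
  expect_false(expressed_in_type(m, "a", "root", g))
  expect_true(expressed_in_type(m, "b", "root", g))
  expect_false(expressed_in_type(m, "c", "root", g))   # 0.99 in all samples
  # strict all-samples variant
  expect_false(expressed_in_type(m, "b", "root", g, all_samples = TRUE))
  m["b", c("root.1", "root.2")] <- 1.0
  expect_true(expressed_in_type(m, "b", "root", g, all_samples = TRUE))
  expect_error(expressed_in_type(m, "zz", "root", g), "unknown gene")
  expect_error(expressed_in_type(m, "a", "petal", g), "tissue type")
})

test_that("zones follow the undetectable/all/root-only/bud-only definitions", {
  g <- std_grouping()
  m <- mk_matrix(list(
    z1 = c(),                                              # all zero
    z2 = c(root = 5, leaf = 3, stem = 2, bud = 8),
    z3 = c(root = 4),
    z4 = c(bud = 2),
    z5 = c(root = 2, stem = 6),                            # two tissues
    z6 = c(leaf = 3)))                                     # leaf only
  expect_equal(assign_zone(m, "z1", g), "I")
  expect_equal(assign_zone(m, "z2", g), "II")
  expect_equal(assign_zone(m, "z3", g), "III")
  expect_equal(assign_zone(m, "z4", g), "IV")
  expect_equal(assign_zone(m, "z5", g), "other")
  expect_equal(assign_zone(m, "z6", g), "other")
  # raising the cutoff never moves a gene out of zone I
  for (gene in rownames(m)) {
    if (assign_zone(m, gene, g) == "I") {
      expect_equal(assign_zone(m, gene, g, cutoff = 5), "I")
    }
  }
})

test_that("the specificity table partitions genes with consistent marginals", {
  g <- std_grouping()
  m <- mk_matrix(list(
    a = c(root = 5), b = c(bud = 2), c = c(root = 2, leaf = 2, stem = 2, bud = 2),
    d = c(root = 2, stem = 6), e = c(root = 2, stem = 6, leaf = 1.5),
    f = c(), h = c(stem = 3)))
  types <- c(a = "G", b = "G", c = "L", d = "L", e = "G", f = "G", h = "C")
  tab <- specificity_table(m, g, types)
  expect_equal(tab["G", "root_only"], 1L)
  expect_equal(tab["G", "bud_only"], 1L)
  expect_equal(tab["L", "all_four"], 1L)
  expect_equal(tab["L", "two_tissues"], 1L)
  expect_equal(tab["G", "three_tissues"], 1L)
  expect_equal(tab["G", "low_or_no"], 1L)
  expect_equal(tab["C", "stem_only"], 1L)
  expect_equal(unname(tab["Total", "total"]), 7L)
  expect_equal(unname(rowSums(tab[1:3, 1:8])), unname(tab[1:3, "total"]))
  expect_equal(attr(tab, "undetectable"), "f")
  expect_error(specificity_table(m, g, types[-1]), "unlabeled")
  # empty gene set: all-zero table
  tab0 <- specificity_table(m[0, , drop = FALSE], g, character(0))
  expect_true(all(tab0 == 0L))
})

test_that("sex-specific labels use the reproductive tissue types only", {
  g <- tissue_grouping(c("f.1", "f.2", "m.1", "m.2", "root.1"),
                       c("female", "female", "male", "male", "root"))
  m <- matrix(0, 4, 5, dimnames = list(c("a", "b", "c", "d"), names(g)))
  m["a", c("f.1", "f.2")] <- 3
  m["b", "m.2"] <- 1.0
  m["c", c("f.1", "m.1")] <- 2
  m["d", "root.1"] <- 9   # expressed, but not in reproductive tissue
  lab <- sex_specific_expression(m, g)
  expect_equal(unname(lab[c("a", "b", "c", "d")]),
               c("female_only", "male_only", "both", "neither"))
  g2 <- tissue_grouping("root.1", "root")
  expect_error(sex_specific_expression(m[, "root.1", drop = FALSE], g2),
               "female and male")
})

test_that("FPKM matrices round-trip through TSV", {
  catl <- generate_catalogue(small_sim_config())
  tmp <- tempfile(fileext = ".tsv")
  write_fpkm_matrix(catl$fpkm, tmp)
  back <- read_fpkm_matrix(tmp)
  expect_equal(dim(back), dim(catl$fpkm))
  expect_equal(back, catl$fpkm, tolerance = 1e-8)
  expect_error(lecfam:::validate_fpkm_matrix(matrix(c(1, -1), 1)),
               "non-negative")
})
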