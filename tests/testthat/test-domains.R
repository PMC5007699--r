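mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(protein_id = r[[1]], accession = r[[2]], role = r[[3]],
               start = as.integer(r[[4]]), end = as.integer(r[[5]]),
               score = 50, stringsAsFactors = FALSE)))
}

test_that("dual-domain filter keeps lectin+kinase proteins and explains rejections", {
  hits <- mk_hits(
    list("p1", "B_lectin", "lectin_bulb", 30, 139),          # lectin only
    list("p2", "Lectin_legB", "lectin_legume", 25, 254),
    list("p2", "Pkinase", "kinase", 400, 649),
    list("p3", "Pkinase", "kinase", 10, 259),                # kinase only
    list("p4", "EGF", "egf", 5, 44))                          # neither
  res <- filter_lecrlk(hits, protein_ids = c("p1", "p2", "p3", "p4", "p5"))
  expect_equal(res$members$protein_id, "p2")
  expect_equal(res$members$lec_type, "L")
  rej <- setNames(res$rejected$reason, res$rejected$protein_id)
  expect_equal(rej[["p1"]], "no_kinase")
  expect_equal(rej[["p3"]], "no_lectin")
  expect_equal(rej[["p4"]], "neither")
  expect_equal(rej[["p5"]], "neither")
  # partition: members and rejected cover the inputs exactly, no overlap
  expect_setequal(c(res$members$protein_id, res$rejected$protein_id),
                  c("p1", "p2", "p3", "p4", "p5"))
  expect_length(intersect(res$members$protein_id, res$rejected$protein_id), 0)
})

test_that("duplicate hits are deduplicated with a warning", {
  hits <- mk_hits(list("p1", "B_lectin", "lectin_bulb", 30, 139),
                  list("p1", "B_lectin", "lectin_bulb", 30, 139),
                  list("p1", "Pkinase", "kinase", 300, 549))
  expect_warning(res <- filter_lecrlk(hits), "deduplicated")
  expect_equal(nrow(res$members), 1L)
})

test_that("lectin typing follows the lectin role and surfaces ambiguity", {
  g <- mk_hits(list("p", "B_lectin", "lectin_bulb", 30, 139),
               list("p", "S_locus_glycop", "s_locus", 150, 269),
               list("p", "EGF", "egf", 280, 319),
               list("p", "PAN_1", "pan", 330, 414),
               list("p", "Pkinase", "kinase", 460, 709),
               list("p", "DUF3403", "duf3403", 720, 799))
  expect_equal(assign_type(g), "G")
  expect_equal(assign_type(mk_hits(list("p", "Lectin_C", "lectin_C", 1, 110),
                                   list("p", "Pkinase", "kinase", 150, 399))),
               "C")
  amb <- mk_hits(list("p", "B_lectin", "lectin_bulb", 1, 110),
                 list("p", "Lectin_legB", "lectin_legume", 120, 349),
                 list("p", "Pkinase", "kinase", 400, 649))
  expect_error(assign_type(amb), "ambiguous_type")
  expect_warning(res <- filter_lecrlk(amb), "ambiguous_type")
  expect_true(res$members$ambiguous)
  # typing ignores hit order and non-lectin hits
  expect_equal(assign_type(g[sample(nrow(g)), ]), "G")
})

test_that("architecture strings are coordinate-ordered with multiplicities", {
  fusion <- mk_hits(list("p", "B_lectin", "lectin_bulb", 30, 139),
                    list("p", "Pkinase", "kinase", 200, 449),
                    list("p", "B_lectin", "lectin_bulb", 500, 609),
                    list("p", "Pkinase", "kinase", 700, 949))
  expect_equal(architecture_string(fusion),
               c("lectin_bulb", "kinase", "lectin_bulb", "kinase"))
  shuffled <- fusion[c(3, 1, 4, 2), ]
  expect_equal(architecture_string(shuffled), architecture_string(fusion))
  expect_equal(architecture_string(fusion[1, ]), "lectin_bulb")
  expect_equal(architecture_string(fusion, collapse = "+"),
               "lectin_bulb+kinase+lectin_bulb+kinase")
})

test_that("truncation flags hits lacking at least 10 residues of the model", {
  vocab <- default_domain_vocabulary()
  ml <- vocab$model_length[vocab$accession == "B_lectin"]
  at_len <- function(len) data.frame(accession = "B_lectin", start = 1L,
                                     end = len, stringsAsFactors = FALSE)
  expect_false(detect_truncation(at_len(ml), vocab))          # full length
  expect_true(detect_truncation(at_len(ml - 10L), vocab))     # boundary
  expect_false(detect_truncation(at_len(ml - 9L), vocab))     # complement
  expect_error(detect_truncation(
    data.frame(accession = "NOPE", start = 1, end = 50), vocab), "unknown")
})

test_that("planted members and decoys are separated exactly", {
  cfg <- small_sim_config(background_domain_fraction = 0.5)
  catl <- generate_catalogue(cfg)
  pro <- select_longest_isoform(catl$proteome)
  res <- filter_lecrlk(catl$domain_hits, protein_ids = pro$id)
  expect_setequal(res$members$protein_id, catl$truth$proteins$protein_id)
  # per-type counts equal the apportioned design exactly
  expect_equal(sort(table(res$members$lec_type), decreasing = TRUE),
               sort(table(catl$truth$proteins$lec_type), decreasing = TRUE))
  # background proteins never combine a lectin with a kinase
  bg <- catl$domain_hits[!catl$domain_hits$protein_id %in%
                           catl$truth$proteins$protein_id, ]
  for (p in unique(bg$protein_id)) {
    roles <- bg$role[bg$protein_id == p]
    expect_false(any(roles %in% c("lectin_bulb", "lectin_legume", "lectin_C")) &&
                   any(roles == "kinase"))
  }
})

test_that("domain vocabulary validates roles and model lengths", {
  expect_error(domain_vocabulary("X1", "kinase", 250), "lectin")
  expect_error(domain_vocabulary(c("a", "b", "c", "d"),
                                 c("lectin_bulb", "lectin_legume", "lectin_C",
                                   "weird"), c(110, 230, 110, 50)),
               "unknown role")
  expect_error(domain_vocabulary(c("a", "b", "c"),
                                 c("lectin_bulb", "lectin_legume", "lectin_C"),
                                 c(110, 230, 5)), "model_length")
})
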