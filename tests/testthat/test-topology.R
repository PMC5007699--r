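seg_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(label = r[[1]], start = as.integer(r[[2]]),
               end = as.integer(r[[3]]), score = r[[4]],
               stringsAsFactors = FALSE)))
}

test_that("TM acceptance applies the 0.8 boundary exactly", {
  m1 <- topology_model("p", seg_df(list("outside", 1, 100, 1),
                                   list("membrane", 101, 121, 0.95),
                                   list("inside", 122, 400, 1)))
  expect_equal(sum(accept_tm_segments(m1)$segments$label == "membrane"), 1L)
  m2 <- topology_model("p", seg_df(list("outside", 1, 100, 1),
                                   list("membrane", 101, 121, 0.80),
                                   list("inside", 122, 400, 1)))
  expect_equal(sum(accept_tm_segments(m2)$segments$label == "membrane"), 1L)
  m3 <- topology_model("p", seg_df(list("outside", 1, 100, 1),
                                   list("membrane", 101, 121, 0.79),
                                   list("inside", 122, 400, 1)))
  f3 <- accept_tm_segments(m3)
  expect_equal(sum(f3$segments$label == "membrane"), 0L)
  expect_equal(nrow(f3$segments), 1L)   # flanks merged into one side region
  expect_equal(classify_orientation(0, NA, NA), "NO_TM")
})

test_that("sub-threshold TM removal keeps sides alternating", {
  m <- topology_model("p", seg_df(list("outside", 1, 80, 1),
                                  list("membrane", 81, 101, 0.9),
                                  list("inside", 102, 180, 1),
                                  list("membrane", 181, 201, 0.5),
                                  list("outside", 202, 300, 1),
                                  list("membrane", 301, 321, 0.85),
                                  list("inside", 322, 400, 1)))
  f <- accept_tm_segments(m)
  expect_equal(sum(f$segments$label == "membrane"), 2L)
  sides <- f$segments$label[f$segments$label != "membrane"]
  expect_equal(sides, c("outside", "inside", "outside"))
  expect_false(f$contradictory)
})

test_that("signal-peptide priority removes an overlapping first TM", {
  m <- topology_model("p", seg_df(list("inside", 1, 5, 1),
                                  list("membrane", 6, 26, 0.92),
                                  list("outside", 27, 200, 1),
                                  list("membrane", 201, 221, 0.9),
                                  list("inside", 222, 500, 1)),
                      sp_score = 0.9, sp_end = 24L)
  r <- resolve_signal_peptide(m)
  expect_equal(sum(r$segments$label == "membrane"), 1L)
  # mature chain starts extracellular
  expect_equal(r$segments$label[1], "outside")

  low <- resolve_signal_peptide(topology_model("p", m$segments,
                                               sp_score = 0.69, sp_end = 24L))
  expect_equal(sum(low$segments$label == "membrane"), 2L)
  # boundary: 0.70 applies
  at <- resolve_signal_peptide(topology_model("p", m$segments,
                                              sp_score = 0.70, sp_end = 24L))
  expect_equal(sum(at$segments$label == "membrane"), 1L)

  no_tm <- topology_model("p", seg_df(list("outside", 1, 400, 1)),
                          sp_score = 0.95, sp_end = 20L)
  expect_identical(resolve_signal_peptide(no_tm)$segments, no_tm$segments)
})

test_that("domain side follows the strict-majority rule", {
  m <- topology_model("p", seg_df(list("outside", 1, 100, 1),
                                  list("membrane", 101, 120, 0.9),
                                  list("inside", 121, 400, 1)))
  expect_equal(domain_side(10, 90, m), "extracellular")
  expect_equal(domain_side(150, 350, m), "intracellular")
  # 60 % inside / 40 % outside (spanning, majority inside):
  # domain 81..180 = 100 residues: 20 outside, 20 membrane, 60 inside
  expect_equal(domain_side(81, 180, m), "intracellular")
  # exact 50/50 split across the membrane -> membrane_spanning
  expect_equal(domain_side(91, 130, m), "membrane_spanning")
  expect_error(domain_side(390, 410, m), "bounds")
})

test_that("orientation classification is total and matches the eight patterns", {
  sides <- c("extracellular", "intracellular", "membrane_spanning")
  labels <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "NO_TM",
              "UNCLASSIFIED")
  for (n_tm in 0:4) {
    for (ls in sides) {
      for (ks in sides) {
        cls <- classify_orientation(n_tm, ls, ks)
        expect_length(cls, 1L)
        expect_true(cls %in% labels)
      }
    }
  }
  expect_equal(classify_orientation(1, "extracellular", "intracellular"), "I")
  expect_equal(classify_orientation(1, "intracellular", "extracellular"), "II")
  expect_equal(classify_orientation(1, "extracellular", "extracellular"), "III")
  expect_equal(classify_orientation(2, "extracellular", "extracellular"), "IV")
  expect_equal(classify_orientation(2, "intracellular", "extracellular"), "V")
  expect_equal(classify_orientation(2, "extracellular", "intracellular"), "VI")
  expect_equal(classify_orientation(3, "extracellular", "intracellular"), "VII")
  expect_equal(classify_orientation(3, "intracellular", "extracellular"), "VIII")
  expect_equal(classify_orientation(0, "extracellular", "intracellular"), "NO_TM")
  expect_equal(classify_orientation(1, "intracellular", "intracellular"),
               "UNCLASSIFIED")
  expect_equal(classify_orientation(4, "extracellular", "intracellular"),
               "UNCLASSIFIED")
  expect_equal(classify_orientation(1, "membrane_spanning", "intracellular"),
               "UNCLASSIFIED")
})

test_that("generator archetypes classify to their designed classes", {
  for (cls in c("I", "II", "III", "IV", "V", "VI", "NO_TM")) {
    arc <- lecfam:::build_archetype("L", cls)
    hits <- data.frame(protein_id = "p", arc$hits, score = 50)
    model <- topology_model("p", arc$segments)
    expect_equal(classify_protein(hits, model)$class, cls, label = cls)
  }
  for (cls in c("VII", "VIII")) {
    arc <- lecfam:::build_archetype("G", cls)
    hits <- data.frame(protein_id = "p", arc$hits, score = 50)
    expect_equal(classify_protein(hits, topology_model("p", arc$segments))$class,
                 cls, label = cls)
  }
})

test_that("fallback hydropathy predictor finds planted TM segments", {
  charged <- strrep("DEKR", 15)
  tm <- strrep("L", 25)
  one <- paste0(charged, tm, charged)
  m1 <- predict_tm_fallback(one)
  expect_equal(sum(m1$segments$label == "membrane"), 1L)
  expect_true(all(m1$segments$score[m1$segments$label == "membrane"] >= 0.8))

  expect_equal(sum(predict_tm_fallback(strrep("D", 80))$segments$label ==
                     "membrane"), 0L)

  sepr <- strrep("DEKRSTNQ", 4)   # 32 hydrophilic residues between stretches
  two <- paste0(charged, tm, sepr, tm, charged)
  m2 <- predict_tm_fallback(two)
  expect_equal(sum(m2$segments$label == "membrane"), 2L)
  sides <- m2$segments$label[m2$segments$label != "membrane"]
  expect_equal(length(unique(sides[c(1, 2)])), 2L)  # alternating sides

  expect_error(predict_tm_fallback("MKV"), "window")
})

test_that("topology models validate tiling and read/write round-trips", {
  expect_error(topology_model("p", seg_df(list("outside", 2, 10, 1))),
               "position 1")
  expect_error(topology_model("p", seg_df(list("outside", 1, 10, 1),
                                          list("inside", 15, 20, 1))),
               "tile")
  models <- list(
    a = topology_model("a", seg_df(list("outside", 1, 50, 1),
                                   list("membrane", 51, 71, 0.9),
                                   list("inside", 72, 150, 1)),
                       sp_score = 0.8, sp_end = 22L),
    b = topology_model("b", seg_df(list("inside", 1, 200, 1))))
  tmp <- tempfile(fileext = ".tsv")
  write_topology_table(models, tmp)
  back <- read_topology_table(tmp)
  expect_equal(back$a$segments, models$a$segments)
  expect_equal(back$a$sp_score, models$a$sp_score)
  expect_equal(back$b$segments, models$b$segments)
})
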