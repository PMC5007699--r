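test_that("config invariants are enforced", {
  expect_error(family_sim_config(type_proportions = c(G = 0.5, L = 0.5, C = 0.1)),
               "sum to 1")
  expect_error(family_sim_config(fpkm_expressed_range = c(0.5, 10)),
               "lower bound")
  expect_error(family_sim_config(divergence_rate = 0.95), "divergence_rate")
  expect_error(family_sim_config(n_family_members = 0), "zero family members")
  expect_error(family_sim_config(n_family_members = 10,
                                 super_cluster_size = 21), "exceed")
})

test_that("an empty family yields a background-only proteome", {
  cfg <- family_sim_config(n_family_members = 0, n_background_proteins = 15,
                           tandem_cluster_sizes = integer(0),
                           tandem_cluster_types = character(0),
                           super_cluster_size = 0, n_scaffold_genes = 0,
                           sex_female_only = c(G = 0, L = 0),
                           sex_male_only = c(G = 0, L = 0), seed = 3)
  catl <- generate_catalogue(cfg)
  expect_equal(nrow(catl$proteome), 15L)
  expect_equal(nrow(catl$truth$proteins), 0L)
  expect_equal(nrow(catl$truth$genes), 0L)
  expect_equal(nrow(catl$fpkm), 0L)
  expect_true(all(grepl("^BG", catl$proteome$id)))
})

test_that("a planted 21-member cluster is the unique super cluster", {
  cfg <- small_sim_config(n_family_members = 40,
                          type_proportions = c(G = 30, L = 9, C = 1) / 40,
                          class_distribution = c(I = 8, II = 14, III = 1,
                                                 IV = 3, V = 1, VI = 3,
                                                 VII = 1, VIII = 1,
                                                 NO_TM = 8) / 40,
                          tandem_cluster_sizes = c(5L),
                          tandem_cluster_types = "G",
                          super_cluster_size = 21L)
  catl <- generate_catalogue(cfg)
  g <- catl$truth$genes
  super_ids <- unique(g$cluster_id[g$is_super])
  expect_length(super_ids[!is.na(super_ids)], 1L)
  expect_equal(sum(g$is_super), 21L)
})

test_that("an all-zone-II design at zero noise is expressed everywhere", {
  cfg <- small_sim_config(zone_distribution = c(I = 0, II = 1, III = 0,
                                                IV = 0, other = 0))
  catl <- generate_catalogue(cfg)
  std <- names(catl$grouping)[unname(catl$grouping) %in%
                                c("root", "leaf", "stem", "bud")]
  expect_true(all(catl$fpkm[, std] >= 1))
})

test_that("classes VII/VIII are rejected when no G-type member can carry them", {
  cfg <- family_sim_config(
    n_family_members = 10,
    type_proportions = c(G = 0, L = 1, C = 0),
    class_distribution = c(I = 0.8, II = 0, III = 0, IV = 0, V = 0, VI = 0,
                           VII = 0.1, VIII = 0.1, NO_TM = 0),
    tandem_cluster_sizes = integer(0), tandem_cluster_types = character(0),
    super_cluster_size = 0, n_scaffold_genes = 0)
  expect_error(generate_catalogue(cfg), "VII")
})

test_that("mutate_family matches its closed-form expectation", {
  seedseq <- strrep("ACDEFGHIKLMNPQRSTVWY", 50)  # 1000 residues
  expect_equal(mutate_family(seedseq, 3, 0, seed = 1),
               rep(seedseq, 3))
  one <- mutate_family(seedseq, 1, 0.3, seed = 2)
  expect_equal(nchar(one), 1000L)
  # E[p-hat] = rate exactly; 10 replicates at rate 0.1 over 1000 sites
  reps <- mutate_family(seedseq, 10, 0.1, seed = 7)
  p <- vapply(reps, function(s)
    protein_distance(seedseq, s, "none"), numeric(1))
  se <- sqrt(0.1 * 0.9 / 1000 / 10)
  expect_lt(abs(mean(p) - 0.1), 3 * se)
  # monotone divergence
  p_lo <- mean(vapply(mutate_family(seedseq, 5, 0.05, seed = 8), function(s)
    protein_distance(seedseq, s, "none"), numeric(1)))
  p_hi <- mean(vapply(mutate_family(seedseq, 5, 0.4, seed = 8), function(s)
    protein_distance(seedseq, s, "none"), numeric(1)))
  expect_lt(p_lo, p_hi)
  expect_error(mutate_family("", 1, 0.1), "nonempty")
})

test_that("identical config and seed give byte-identical written catalogues", {
  cfg <- small_sim_config(divergence_rate = 0.05, fpkm_noise_sd = 0.1)
  d1 <- file.path(tempdir(), "cat_a")
  d2 <- file.path(tempdir(), "cat_b")
  write_catalogue(generate_catalogue(cfg), d1)
  write_catalogue(generate_catalogue(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("written catalogues parse with the standard-format readers", {
  cfg <- small_sim_config()
  catl <- generate_catalogue(cfg)
  dir <- file.path(tempdir(), "cat_rt")
  write_catalogue(catl, dir)
  pro <- read_proteome(file.path(dir, "proteome.fasta"))
  expect_equal(pro$sequence, catl$proteome$sequence)
  expect_equal(pro$isoform_group, catl$proteome$isoform_group)
  hits <- read_domain_table(file.path(dir, "domains.tsv"))
  expect_equal(nrow(hits), nrow(catl$domain_hits))
  topo <- read_topology_table(file.path(dir, "topology.tsv"))
  expect_equal(length(topo), length(catl$topology))
  expect_equal(topo[[1]]$segments, catl$topology[[1]]$segments)
  m <- read_fpkm_matrix(file.path(dir, "fpkm.tsv"))
  expect_equal(m, catl$fpkm, tolerance = 1e-8)
  g <- read_tissue_grouping(file.path(dir, "grouping.tsv"))
  expect_equal(unname(unclass(g)), unname(unclass(catl$grouping)))
  cfg2 <- read_sim_config(file.path(dir, "config.yaml"))
  expect_equal(cfg2$n_family_members, cfg$n_family_members)
  expect_equal(cfg2$zone_distribution, cfg$zone_distribution)
  unlink(dir, recursive = TRUE)
})

test_that("generated tables are internally consistent with the ground truth", {
  cfg <- small_sim_config()
  catl <- generate_catalogue(cfg)
  tp <- catl$truth$proteins
  # planted domain architectures match the recorded truth
  for (k in seq_len(nrow(tp))) {
    h <- catl$domain_hits[catl$domain_hits$protein_id == tp$protein_id[k], ]
    expect_equal(architecture_string(h, collapse = "+"), tp$architecture[k])
  }
  # per-type counts equal the apportioned proportions exactly
  want <- lecfam:::apportion_counts(cfg$n_family_members,
                                    cfg$type_proportions[c("G", "L", "C")])
  got <- table(factor(tp$lec_type, levels = c("G", "L", "C")))
  expect_equal(as.integer(got), as.integer(want))
  # topology segments tile each protein exactly
  for (pid in names(catl$topology)[1:5]) {
    segs <- catl$topology[[pid]]$segments
    L <- nchar(catl$proteome$sequence[catl$proteome$id == pid])
    expect_equal(segs$end[nrow(segs)], L)
  }
})
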