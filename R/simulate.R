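#' Configuration for the synthetic catalogue generator
#'
#' The generator emits a complete, internally consistent set of study
#' inputs — proteome FASTA, domain-hit table, topology table, GFF3 gene
#' annotation and FPKM matrix — together with the ground truth used to
#' plant them. Defaults mirror a Populus-scale LecRLK catalogue: 231 family
#' members split 180 G / 50 L / 1 C, the observed orientation-class mix
#' (including 45 members without a predicted TM), a 21-member super tandem
#' cluster plus an 8-member L-type cluster and smaller G clusters, 36
#' scaffold-placed genes, and a 12-sample standard tissue panel
#' (2 root, 3 leaf, 2 stem, 5 bud) plus 2 female and 2 male reproductive
#' samples.
#'
#' @param n_family_members Number of family proteins.
#' @param type_proportions Named fractions over G/L/C (sum 1).
#' @param class_distribution Named fractions over orientation classes
#'   I..VIII plus NO_TM (sum 1). Classes VII/VIII can only be realised by
#'   G-type members.
#' @param n_background_proteins Number of non-family proteins.
#' @param background_domain_fraction Fraction of background proteins given
#'   a single decoy domain (a lectin OR a kinase, never both).
#' @param tandem_cluster_sizes Integer sizes of ordinary planted tandem
#'   clusters.
#' @param tandem_cluster_types Lectin type of each ordinary cluster
#'   (parallel to `tandem_cluster_sizes`).
#' @param super_cluster_size Size of the planted super tandem repeat region
#'   (G-type; flagged super when more than 20 members). Set to 0 to plant
#'   none.
#' @param n_scaffold_genes Family genes placed on unanchored scaffolds
#'   (excluded from clustering).
#' @param isoform_fraction Fraction of family genes that also get a second,
#'   shorter isoform.
#' @param divergence_rate Per-site substitution probability applied to each
#'   family member relative to its type/class archetype, in [0, 0.95).
#' @param tissue_types Named integer vector: samples per tissue type. Must
#'   contain root, leaf, stem and bud; female/male enable the sex-specific
#'   design.
#' @param zone_distribution Named fractions over expression zones
#'   I/II/III/IV/other (sum 1).
#' @param sex_female_only,sex_male_only Named counts (G/L) of genes
#'   designed to be expressed only in female / only in male reproductive
#'   samples.
#' @param fpkm_expressed_range Interval for designed-expressed FPKM means;
#'   lower bound must be >= 1 so designed "expressed" states satisfy the
#'   detection cutoff.
#' @param fpkm_noise_sd SD of the multiplicative log-normal replicate noise
#'   applied to designed-expressed values. Designed-not-expressed samples
#'   are uniform draws on [0, 1) (the sub-detection noise floor) and
#'   undetectable states are exactly 0.
#' @param seed Integer seed; all outputs are byte-identical under a fixed
#'   config + seed.
#' @return Validated config of class `lecfam_sim_config`.
#' @export
family_sim_config <- function(
    n_family_members = 231L,
    type_proportions = c(G = 180, L = 50, C = 1) / 231,
    class_distribution = c(I = 39, II = 115, III = 2, IV = 11, V = 6,
                           VI = 11, VII = 1, VIII = 1, NO_TM = 45) / 231,
    n_background_proteins = 300L,
    background_domain_fraction = 0.2,
    tandem_cluster_sizes = c(8L, 5L, 3L),
    tandem_cluster_types = c("L", "G", "G"),
    super_cluster_size = 21L,
    n_scaffold_genes = 36L,
    isoform_fraction = 0.2,
    divergence_rate = 0.05,
    tissue_types = c(root = 2L, leaf = 3L, stem = 2L, bud = 5L,
                     female = 2L, male = 2L),
    zone_distribution = c(I = 78, II = 28, III = 22, IV = 45,
                          other = 58) / 231,
    sex_female_only = c(G = 21L, L = 9L),
    sex_male_only = c(G = 9L, L = 1L),
    fpkm_expressed_range = c(5, 100),
    fpkm_noise_sd = 0.1,
    seed = 1L) {
  cfg <- list(n_family_members = as.integer(n_family_members),
              type_proportions = type_proportions,
              class_distribution = class_distribution,
              n_background_proteins = as.integer(n_background_proteins),
              background_domain_fraction = background_domain_fraction,
              tandem_cluster_sizes = as.integer(tandem_cluster_sizes),
              tandem_cluster_types = tandem_cluster_types,
              super_cluster_size = as.integer(super_cluster_size),
              n_scaffold_genes = as.integer(n_scaffold_genes),
              isoform_fraction = isoform_fraction,
              divergence_rate = divergence_rate,
              tissue_types = tissue_types,
              zone_distribution = zone_distribution,
              sex_female_only = sex_female_only,
              sex_male_only = sex_male_only,
              fpkm_expressed_range = fpkm_expressed_range,
              fpkm_noise_sd = fpkm_noise_sd,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "lecfam_sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_family_members >= 0, cfg$n_background_proteins >= 0,
            cfg$n_scaffold_genes >= 0, all(cfg$tandem_cluster_sizes >= 0),
            cfg$super_cluster_size >= 0, cfg$fpkm_noise_sd >= 0,
            cfg$isoform_fraction >= 0, cfg$isoform_fraction <= 1,
            cfg$background_domain_fraction >= 0,
            cfg$background_domain_fraction <= 1)
  if (!identical(sort(names(cfg$type_proportions)), c("C", "G", "L"))) {
    stop("type_proportions must be named over G, L, C")
  }
  if (!setequal(names(cfg$class_distribution),
                c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "NO_TM"))) {
    stop("class_distribution must be named over classes I..VIII and NO_TM")
  }
  if (!setequal(names(cfg$zone_distribution), ZONES)) {
    stop("zone_distribution must be named over zones I..IV and other")
  }
  for (p in c("type_proportions", "class_distribution", "zone_distribution")) {
    if (abs(sum(cfg[[p]]) - 1) > 1e-9) stop(p, " must sum to 1")
    if (any(cfg[[p]] < 0)) stop(p, " must be non-negative")
  }
  if (!(cfg$divergence_rate >= 0 && cfg$divergence_rate < 0.95)) {
    stop("divergence_rate must lie in [0, 0.95)")
  }
  if (cfg$fpkm_expressed_range[1] < 1) {
    stop("fpkm_expressed_range lower bound must be >= 1 so designed ",
         "'expressed' states satisfy the FPKM >= 1 cutoff")
  }
  if (cfg$fpkm_expressed_range[1] > cfg$fpkm_expressed_range[2]) {
    stop("fpkm_expressed_range must be an interval")
  }
  if (length(cfg$tandem_cluster_types) != length(cfg$tandem_cluster_sizes)) {
    stop("tandem_cluster_types must parallel tandem_cluster_sizes")
  }
  if (!all(cfg$tandem_cluster_types %in% c("G", "L", "C"))) {
    stop("tandem cluster types must be G, L or C")
  }
  if (!all(STANDARD_TISSUES %in% names(cfg$tissue_types))) {
    stop("tissue_types must contain root, leaf, stem and bud")
  }
  n_clustered <- sum(cfg$tandem_cluster_sizes) + cfg$super_cluster_size
  if (cfg$n_family_members == 0 && n_clustered > 0) {
    stop("zero family members cannot carry nonzero tandem cluster sizes")
  }
  if (n_clustered + cfg$n_scaffold_genes > cfg$n_family_members) {
    stop("clusters plus scaffold genes exceed the family size")
  }
  invisible(cfg)
}

#' Read / write a generator config as YAML
#' @param path YAML file.
#' @return A [family_sim_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (nm in c("type_proportions", "class_distribution", "zone_distribution",
               "tissue_types", "sex_female_only", "sex_male_only")) {
    if (!is.null(y[[nm]])) y[[nm]] <- unlist(y[[nm]])
  }
  do.call(family_sim_config, y)
}

#' @rdname read_sim_config
#' @param config A [family_sim_config()].
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (!is.null(names(x))) as.list(x) else x), path, precision = 15L)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Fixed synthetic signature blocks: one block per domain role with a
# distinct residue composition, generated once from hard-wired seeds so the
# blocks are stable across configs (and findable by the homology search).

run_with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

ROLE_BLOCK_SPECS <- list(
  lectin_bulb   = list(len = 110L, fav = c("N", "D", "G", "S", "T", "W", "Y")),
  lectin_legume = list(len = 230L, fav = c("A", "V", "T", "S", "N", "F")),
  lectin_C      = list(len = 110L, fav = c("C", "E", "D", "K", "R", "W")),
  kinase        = list(len = 250L, fav = c("K", "E", "D", "G", "L", "I", "R")),
  s_locus       = list(len = 120L, fav = c("S", "T", "P", "N", "G", "Y")),
  egf           = list(len = 40L,  fav = c("C", "G", "S", "D")),
  pan           = list(len = 85L,  fav = c("C", "P", "G", "Y", "W")),
  duf3403       = list(len = 80L,  fav = c("Q", "E", "L", "K", "H")))

ROLE_ACCESSION <- c(lectin_bulb = "B_lectin", lectin_legume = "Lectin_legB",
                    lectin_C = "Lectin_C", kinase = "Pkinase",
                    s_locus = "S_locus_glycop", egf = "EGF", pan = "PAN_1",
                    duf3403 = "DUF3403")

.block_cache <- new.env(parent = emptyenv())

biased_block <- function(len, fav, seed) {
  run_with_seed(seed, {
    w <- stats::setNames(rep(0.3 / 20, 20), AA_ALPHABET20)
    w[fav] <- w[fav] + 0.7 / length(fav)
    paste(sample(AA_ALPHABET20, len, replace = TRUE, prob = w), collapse = "")
  })
}

role_block <- function(role) {
  if (!is.null(.block_cache[[role]])) return(.block_cache[[role]])
  spec <- ROLE_BLOCK_SPECS[[role]]
  b <- biased_block(spec$len, spec$fav, 816000 + match(role, names(ROLE_BLOCK_SPECS)))
  assign(role, b, envir = .block_cache)
  b
}

# Hydrophobic transmembrane block (21 residues) and hydrophilic linkers.
tm_block <- function() {
  if (!is.null(.block_cache[["..tm"]])) return(.block_cache[["..tm"]])
  b <- run_with_seed(816100, paste(
    sample(c("L", "I", "V", "F", "A"), 21, replace = TRUE,
           prob = c(0.4, 0.2, 0.2, 0.1, 0.1)), collapse = ""))
  assign("..tm", b, envir = .block_cache)
  b
}

linker_block <- function(len, salt) {
  key <- paste0("..link", len, "_", salt)
  if (!is.null(.block_cache[[key]])) return(.block_cache[[key]])
  b <- run_with_seed(816200 + 137L * salt + len, paste(
    sample(c("D", "E", "K", "R", "S", "T", "G", "P", "N", "Q"), len,
           replace = TRUE), collapse = ""))
  assign(key, b, envir = .block_cache)
  b
}

# ---------------------------------------------------------------------------
# Archetype assembly: a (type, class) pair fixes the block layout, the
# domain-hit coordinates and the topology segments.

lectin_parts <- function(type) {
  switch(type,
         G = c("lectin_bulb", "s_locus", "egf", "pan"),
         L = "lectin_legume",
         C = "lectin_C")
}

kinase_parts <- function(type) if (type == "G") c("kinase", "duf3403") else "kinase"

# Layout element helpers: each element is list(kind, role = NA, len).
el_link <- function(len, salt) list(kind = "linker", len = len, salt = salt)
el_dom <- function(role) list(kind = "domain", role = role,
                              len = ROLE_BLOCK_SPECS[[role]]$len)
el_tm <- function() list(kind = "tm", len = 21L)

class_layout <- function(type, class) {
  LP <- lapply(lectin_parts(type), el_dom)
  KP <- lapply(kinase_parts(type), el_dom)
  bulb <- list(el_dom("lectin_bulb"))
  kin <- list(el_dom("kinase"))
  side <- function(...) list(...)
  # Returned as list(elements, sides): `sides` gives the label of each
  # inter-membrane region in order (first region first).
  switch(class,
    NO_TM = list(elements = c(side(el_link(25, 1)), LP, side(el_link(5, 2)),
                              KP, side(el_link(30, 3))),
                 sides = "outside"),
    I = list(elements = c(side(el_link(25, 1)), LP, side(el_link(5, 2), el_tm(),
                          el_link(5, 3)), KP, side(el_link(30, 4))),
             sides = c("outside", "inside")),
    II = list(elements = c(side(el_link(25, 1)), LP, side(el_link(5, 2), el_tm(),
                           el_link(5, 3)), KP, side(el_link(30, 4))),
              sides = c("inside", "outside")),
    III = list(elements = c(side(el_link(25, 1)), LP, side(el_link(5, 2)), KP,
                            side(el_link(5, 3), el_tm(), el_link(30, 4))),
               sides = c("outside", "inside")),
    IV = list(elements = c(side(el_link(25, 1)), LP, side(el_link(5, 2), el_tm(),
                           el_link(10, 3), el_tm(), el_link(5, 4)), KP,
                           side(el_link(30, 5))),
              sides = c("outside", "inside", "outside")),
    V = list(elements = c(side(el_link(25, 1)), LP, side(el_link(5, 2), el_tm(),
                          el_link(5, 3)), KP, side(el_link(5, 4), el_tm(),
                          el_link(30, 5))),
             sides = c("inside", "outside", "inside")),
    VI = list(elements = c(side(el_link(25, 1)), LP, side(el_link(5, 2), el_tm(),
                           el_link(5, 3)), KP, side(el_link(5, 4), el_tm(),
                           el_link(30, 5))),
              sides = c("outside", "inside", "outside")),
    VII = list(elements = c(side(el_link(25, 1)), bulb, side(el_link(5, 2),
                            el_tm(), el_link(5, 3)), kin, side(el_link(5, 4),
                            el_tm(), el_link(5, 5)), bulb, side(el_link(5, 6),
                            el_tm(), el_link(5, 7)), kin, side(el_link(30, 8))),
               sides = c("outside", "inside", "outside", "inside")),
    VIII = list(elements = c(side(el_link(25, 1)), LP, side(el_link(5, 2),
                             el_tm(), el_link(5, 3)), KP, side(el_link(5, 4),
                             el_tm(), el_link(10, 5), el_tm(), el_link(30, 6))),
                sides = c("inside", "outside", "inside", "outside")),
    stop("unknown orientation class: ", class))
}

# Assemble an archetype: sequence string, domain hits and topology model.
build_archetype <- function(type, class) {
  lay <- class_layout(type, class)
  seq_parts <- character(0)
  pos <- 1L
  hits <- list()
  segs <- list()
  side_idx <- 1L
  side_start <- 1L
  for (e in lay$elements) {
    if (e$kind == "tm") {
      # close the running side region
      if (pos > side_start) {
        segs[[length(segs) + 1L]] <- data.frame(
          label = lay$sides[side_idx], start = side_start, end = pos - 1L,
          score = 1)
      }
      segs[[length(segs) + 1L]] <- data.frame(label = "membrane", start = pos,
                                              end = pos + e$len - 1L,
                                              score = 0.9)
      seq_parts <- c(seq_parts, tm_block())
      pos <- pos + e$len
      side_start <- pos
      side_idx <- side_idx + 1L
    } else {
      if (e$kind == "domain") {
        hits[[length(hits) + 1L]] <- data.frame(
          accession = ROLE_ACCESSION[[e$role]], role = e$role, start = pos,
          end = pos + e$len - 1L, stringsAsFactors = FALSE)
        seq_parts <- c(seq_parts, role_block(e$role))
      } else {
        seq_parts <- c(seq_parts, linker_block(e$len, e$salt))
      }
      pos <- pos + e$len
    }
  }
  L <- pos - 1L
  if (side_start <= L) {
    segs[[length(segs) + 1L]] <- data.frame(label = lay$sides[side_idx],
                                            start = side_start, end = L,
                                            score = 1)
  }
  list(sequence = paste(seq_parts, collapse = ""),
       hits = do.call(rbind, hits),
       segments = do.call(rbind, segs),
       length = L)
}

# Point substitution using the ambient RNG: each site mutates with
# probability `rate` to a uniformly chosen different residue.
mutate_once <- function(sequence, rate) {
  if (rate == 0) return(sequence)
  chars <- strsplit(sequence, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit) > 0L) {
    for (k in hit) {
      chars[k] <- sample(setdiff(AA_ALPHABET20, chars[k]), 1L)
    }
  }
  paste(chars, collapse = "")
}

#' Generate diverged copies of a seed sequence
#'
#' Each copy mutates every site independently with probability
#' `divergence_rate`, replacing the residue by a uniform draw over the 19
#' other standard amino acids, so the expected p-distance of a copy to the
#' seed equals `divergence_rate` exactly.
#'
#' @param seed_sequence Nonempty amino-acid string.
#' @param n_copies Number of copies.
#' @param divergence_rate Per-site substitution probability in [0, 0.95).
#' @param seed Integer seed (deterministic output).
#' @return Character vector of `n_copies` mutated sequences.
#' @export
mutate_family <- function(seed_sequence, n_copies, divergence_rate, seed = 1) {
  check_aa_sequence(seed_sequence, "seed_sequence")
  if (!(divergence_rate >= 0 && divergence_rate < 0.95)) {
    stop("divergence_rate must lie in [0, 0.95)")
  }
  stopifnot(n_copies >= 1)
  run_with_seed(seed,
                vapply(seq_len(n_copies),
                       function(k) mutate_once(seed_sequence, divergence_rate),
                       character(1)))
}

# ---------------------------------------------------------------------------

ZONE_TISSUES <- list(I = character(0),
                     II = c("root", "leaf", "stem", "bud"),
                     III = "root", IV = "bud", other = c("root", "stem"))

#' Generate a complete synthetic LecRLK catalogue with ground truth
#'
#' Produces a proteome (family members built from fixed per-role signature
#' blocks and diverged at `divergence_rate`; background proteins with at
#' most one decoy domain), the matching domain-hit and topology tables, a
#' GFF3-style locus table with planted tandem clusters and scaffold genes,
#' and an FPKM matrix realising the designed expression zones. All outputs
#' are deterministic under the config seed.
#'
#' @param config A [family_sim_config()].
#' @return List with elements `proteome` (protein records), `domain_hits`,
#'   `topology` (list of [topology_model()]), `loci` (gene locus table,
#'   spacer loci included), `fpkm` (matrix), `grouping`
#'   ([tissue_grouping()]), `truth` (ground-truth tables) and `config`.
#' @export
generate_catalogue <- function(config = family_sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)

  nfam <- config$n_family_members
  type_counts <- apportion_counts(nfam, config$type_proportions[c("G", "L", "C")])
  class_counts <- apportion_counts(nfam, config$class_distribution)
  if (sum(class_counts[c("VII", "VIII")]) > type_counts[["G"]]) {
    stop("infeasible config: orientation classes VII and VIII carry three ",
         "TM domains with duplicated/reversed architectures observed only ",
         "in G-type members; requested ", sum(class_counts[c("VII", "VIII")]),
         " such members but only ", type_counts[["G"]], " G-type members")
  }

  # --- member tables -------------------------------------------------------
  types <- rep(c("G", "L", "C"), times = type_counts[c("G", "L", "C")])
  classes <- character(nfam)
  if (nfam > 0) {
    # VII/VIII go to G members (the first ones), everything else is dealt
    # out in order over the remaining members
    pool <- rep(names(class_counts), times = class_counts)
    special <- pool[pool %in% c("VII", "VIII")]
    rest <- pool[!pool %in% c("VII", "VIII")]
    classes[seq_along(special)] <- special
    if (length(rest) > 0) classes[length(special) + seq_along(rest)] <- rest
  }
  gene_ids <- sprintf("FAM.%04d", seq_len(nfam))
  zones <- rep(names(config$zone_distribution),
               times = apportion_counts(nfam, config$zone_distribution))

  # sex-specific design: first k G genes and first k L genes per label
  sex <- rep("neither", nfam)
  has_repro <- all(c("female", "male") %in% names(config$tissue_types))
  if (has_repro && nfam > 0) {
    for (lbl in c("female_only", "male_only")) {
      cnt <- if (lbl == "female_only") config$sex_female_only else config$sex_male_only
      for (ty in names(cnt)) {
        idx <- which(types == ty & sex == "neither")
        take <- min(cnt[[ty]], length(idx))
        sex[idx[seq_len(take)]] <- lbl
      }
    }
  }

  # --- sequences, domain hits, topology ------------------------------------
  proteome <- list()
  domain_hits <- list()
  topology <- list()
  truth_proteins <- list()
  archetypes <- new.env(parent = emptyenv())
  iso_every <- if (config$isoform_fraction > 0)
    max(1L, round(1 / config$isoform_fraction)) else 0L

  for (k in seq_len(nfam)) {
    key <- paste(types[k], classes[k])
    if (is.null(archetypes[[key]])) {
      archetypes[[key]] <- build_archetype(types[k], classes[k])
    }
    arc <- archetypes[[key]]
    pid <- paste0(gene_ids[k], ".1")
    seqk <- mutate_once(arc$sequence, config$divergence_rate)
    proteome[[length(proteome) + 1L]] <- data.frame(
      id = pid, sequence = seqk, isoform_group = gene_ids[k],
      stringsAsFactors = FALSE)
    if (iso_every > 0L && k %% iso_every == 0L) {
      short <- substr(seqk, 1L, max(30L, floor(arc$length * 0.6)))
      proteome[[length(proteome) + 1L]] <- data.frame(
        id = paste0(gene_ids[k], ".2"), sequence = short,
        isoform_group = gene_ids[k], stringsAsFactors = FALSE)
    }
    h <- arc$hits
    h <- data.frame(protein_id = pid, h, score = 100,
                    stringsAsFactors = FALSE)
    domain_hits[[length(domain_hits) + 1L]] <- h
    topology[[pid]] <- topology_model(pid, arc$segments)
    truth_proteins[[k]] <- data.frame(
      protein_id = pid, gene_id = gene_ids[k], is_family = TRUE,
      lec_type = types[k], class = classes[k],
      architecture = paste(h$role[order(h$start)], collapse = "+"),
      truncated_lectin = FALSE, truncated_kinase = FALSE,
      stringsAsFactors = FALSE)
  }

  # background proteins; a fraction carries one decoy domain (never a
  # lectin AND a kinase)
  nbg <- config$n_background_proteins
  bg_gene_ids <- sprintf("BG.%04d", seq_len(nbg))
  decoy_roles <- c("lectin_bulb", "kinase", "lectin_legume")
  n_decoy <- floor(nbg * config$background_domain_fraction)
  for (k in seq_len(nbg)) {
    pid <- paste0(bg_gene_ids[k], ".1")
    len <- sample(250:500, 1L)
    s <- paste(sample(AA_ALPHABET20, len, replace = TRUE), collapse = "")
    if (k <= n_decoy) {
      role <- decoy_roles[((k - 1L) %% length(decoy_roles)) + 1L]
      block <- role_block(role)
      at <- sample(30:80, 1L)
      s <- paste0(substr(s, 1, at - 1), block,
                  substr(s, at, nchar(s)))
      domain_hits[[length(domain_hits) + 1L]] <- data.frame(
        protein_id = pid, accession = ROLE_ACCESSION[[role]], role = role,
        start = at, end = at + nchar(block) - 1L, score = 80,
        stringsAsFactors = FALSE)
    }
    proteome[[length(proteome) + 1L]] <- data.frame(
      id = pid, sequence = s, isoform_group = bg_gene_ids[k],
      stringsAsFactors = FALSE)
  }

  proteome <- do.call(rbind, c(proteome, list(make.row.names = FALSE)))
  domain_hits <- if (length(domain_hits)) {
    do.call(rbind, c(domain_hits, list(make.row.names = FALSE)))
  } else {
    data.frame(protein_id = character(0), accession = character(0),
               role = character(0), start = integer(0), end = integer(0),
               score = numeric(0), stringsAsFactors = FALSE)
  }

  # --- gene loci: clusters, isolated genes, scaffolds, spacers -------------
  cluster_sizes <- c(if (config$super_cluster_size > 0) config$super_cluster_size,
                     config$tandem_cluster_sizes)
  cluster_types <- c(if (config$super_cluster_size > 0) "G",
                     config$tandem_cluster_types)
  keep <- cluster_sizes > 0
  cluster_sizes <- cluster_sizes[keep]
  cluster_types <- cluster_types[keep]
  for (ty in c("G", "L", "C")) {
    need <- sum(cluster_sizes[cluster_types == ty])
    if (need > type_counts[[ty]]) {
      stop("infeasible config: ", need, " clustered ", ty,
           "-type genes requested but only ", type_counts[[ty]], " exist")
    }
  }

  unused <- split(seq_len(nfam), types)
  cluster_of <- rep(NA_character_, nfam)
  cluster_members <- list()
  for (ci in seq_along(cluster_sizes)) {
    ty <- cluster_types[ci]
    take <- unused[[ty]][seq_len(cluster_sizes[ci])]
    unused[[ty]] <- unused[[ty]][-seq_len(cluster_sizes[ci])]
    cid <- sprintf("CL%02d", ci)
    cluster_of[take] <- cid
    cluster_members[[cid]] <- take
  }
  remaining <- sort(unlist(unused, use.names = FALSE))
  # scaffold genes drawn from the remaining pool, spread over types
  scaffold_idx <- integer(0)
  if (config$n_scaffold_genes > 0 && length(remaining) > 0) {
    n_sc <- min(config$n_scaffold_genes, length(remaining))
    rem_types <- types[remaining]
    sc_counts <- apportion_counts(n_sc, table(rem_types)[unique(rem_types)] /
                                    length(rem_types))
    for (ty in names(sc_counts)) {
      pool <- remaining[rem_types == ty]
      scaffold_idx <- c(scaffold_idx, utils::tail(pool, sc_counts[[ty]]))
    }
    remaining <- setdiff(remaining, scaffold_idx)
  }

  chroms <- sprintf("Chr%02d", 1:19)
  gene_len <- 3000L
  spacer_gap <- 13000L
  n_spacers_between <- 8L
  cursor <- stats::setNames(rep(1L, length(chroms)), chroms)
  loci_rows <- list()
  spacer_count <- 0L
  add_locus <- function(gene_id, chrom, start) {
    loci_rows[[length(loci_rows) + 1L]] <<- data.frame(
      gene_id = gene_id, chromosome = chrom, start = start,
      end = start + gene_len - 1L, strand = "+",
      is_scaffold = FALSE, stringsAsFactors = FALSE)
  }
  add_spacers <- function(chrom, n = n_spacers_between) {
    for (s in seq_len(n)) {
      spacer_count <<- spacer_count + 1L
      gid <- if (spacer_count <= nbg) bg_gene_ids[spacer_count] else
        sprintf("SP.%05d", spacer_count - nbg)
      add_locus(gid, chrom, cursor[[chrom]])
      cursor[[chrom]] <<- cursor[[chrom]] + gene_len + spacer_gap
    }
  }
  # clusters: one per chromosome, round-robin
  for (ci in seq_along(cluster_sizes)) {
    chrom <- chroms[((ci - 1L) %% length(chroms)) + 1L]
    add_spacers(chrom)
    for (k in cluster_members[[sprintf("CL%02d", ci)]]) {
      add_locus(gene_ids[k], chrom, cursor[[chrom]])
      cursor[[chrom]] <- cursor[[chrom]] + gene_len + 2000L
    }
    add_spacers(chrom)
  }
  # isolated family genes, round-robin over chromosomes with spacer belts
  for (pos in seq_along(remaining)) {
    k <- remaining[pos]
    chrom <- chroms[((pos - 1L) %% length(chroms)) + 1L]
    add_spacers(chrom)
    add_locus(gene_ids[k], chrom, cursor[[chrom]])
    cursor[[chrom]] <- cursor[[chrom]] + gene_len + spacer_gap
  }
  # leftover background genes become spacers too
  while (spacer_count < nbg) {
    chrom <- chroms[(spacer_count %% length(chroms)) + 1L]
    add_spacers(chrom, 1L)
  }
  # scaffold genes, one scaffold each
  for (s in seq_along(scaffold_idx)) {
    k <- scaffold_idx[s]
    loci_rows[[length(loci_rows) + 1L]] <- data.frame(
      gene_id = gene_ids[k], chromosome = sprintf("scaffold_%05d", s),
      start = 1000L, end = 1000L + gene_len - 1L, strand = "+",
      is_scaffold = TRUE, stringsAsFactors = FALSE)
  }
  loci <- rank_loci(do.call(rbind, c(loci_rows, list(make.row.names = FALSE))))

  # --- FPKM matrix ---------------------------------------------------------
  samples <- unlist(lapply(names(config$tissue_types), function(tt)
    sprintf("%s.%d", tt, seq_len(config$tissue_types[[tt]]))))
  sample_type <- unlist(lapply(names(config$tissue_types), function(tt)
    rep(tt, config$tissue_types[[tt]])))
  grouping <- tissue_grouping(samples, sample_type)
  fpkm <- matrix(0, nrow = nfam, ncol = length(samples),
                 dimnames = list(gene_ids, samples))
  rng <- config$fpkm_expressed_range
  draw_expressed <- function(n) {
    mu <- stats::runif(1, rng[1], rng[2])
    mu * exp(stats::rnorm(n, 0, config$fpkm_noise_sd))
  }
  for (k in seq_len(nfam)) {
    on_tissues <- ZONE_TISSUES[[zones[k]]]
    for (tt in STANDARD_TISSUES) {
      smp <- samples[sample_type == tt]
      if (tt %in% on_tissues) {
        fpkm[k, smp] <- draw_expressed(length(smp))
      } else if (zones[k] != "I") {
        fpkm[k, smp] <- stats::runif(length(smp), 0, 1 - 1e-9)
      }  # zone I stays exactly 0: undetectable in all tissues
    }
    if (has_repro) {
      fem <- samples[sample_type == "female"]
      mal <- samples[sample_type == "male"]
      if (sex[k] == "female_only") {
        fpkm[k, fem] <- draw_expressed(length(fem))
      } else if (sex[k] == "male_only") {
        fpkm[k, mal] <- draw_expressed(length(mal))
      }
    }
  }

  # --- ground truth --------------------------------------------------------
  truth_proteins <- if (length(truth_proteins)) {
    do.call(rbind, c(truth_proteins, list(make.row.names = FALSE)))
  } else {
    data.frame(protein_id = character(0), gene_id = character(0),
               is_family = logical(0), lec_type = character(0),
               class = character(0), architecture = character(0),
               truncated_lectin = logical(0), truncated_kinase = logical(0),
               stringsAsFactors = FALSE)
  }
  truth_genes <- data.frame(
    gene_id = gene_ids, lec_type = types, class = classes,
    cluster_id = cluster_of,
    is_super = !is.na(cluster_of) &
      cluster_of %in% names(cluster_members)[
        vapply(cluster_members, length, integer(1)) > 20],
    is_scaffold = seq_len(nfam) %in% scaffold_idx,
    zone = zones, sex = sex, stringsAsFactors = FALSE)
  seeds <- stats::setNames(rep(NA_character_, 3), c("G", "L", "C"))
  for (ty in c("G", "L", "C")) {
    idx <- which(types == ty)
    if (length(idx) > 0) seeds[ty] <- paste0(gene_ids[idx[1]], ".1")
  }
  truth <- list(proteins = truth_proteins, genes = truth_genes,
                seeds = seeds[!is.na(seeds)])

  list(proteome = proteome, domain_hits = domain_hits, topology = topology,
       loci = loci, fpkm = fpkm, grouping = grouping, truth = truth,
       config = config)
}

#' Write a generated catalogue to a directory of standard-format files
#'
#' Emits `proteome.fasta`, `domains.tsv`, `topology.tsv`, `genes.gff3`,
#' `fpkm.tsv`, `grouping.tsv`, `ground_truth.json` and `config.yaml`.
#'
#' @param cat Result of [generate_catalogue()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_catalogue <- function(cat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_proteome(cat$proteome, file.path(dir, "proteome.fasta"))
  utils::write.table(cat$domain_hits, file.path(dir, "domains.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_topology_table(cat$topology, file.path(dir, "topology.tsv"))
  write_gff3(cat$loci, file.path(dir, "genes.gff3"))
  write_fpkm_matrix(cat$fpkm, file.path(dir, "fpkm.tsv"))
  utils::write.table(data.frame(sample = names(cat$grouping),
                                type = unname(unclass(cat$grouping))),
                     file.path(dir, "grouping.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cat$truth, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", pretty = TRUE)
  write_sim_config(cat$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Write a locus table as GFF3 (gene features, 1-based inclusive)
#' @param loci Locus table (gene_id, chromosome, start, end, strand).
#' @param path Output path.
#' @export
write_gff3 <- function(loci, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\tlecfam_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     loci$chromosome, loci$start, loci$end, loci$strand,
                     loci$gene_id), con)
  invisible(path)
}
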