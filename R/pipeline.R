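CLASS_ROWS <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "NO_TM",
                "UNCLASSIFIED")

#' Catalogue count summary (type totals, class-by-type, specificity-by-type)
#'
#' Aggregates per-gene labels into the three standard count tables of a
#' family catalogue: per-type totals; orientation class by type (with
#' NO_TM and UNCLASSIFIED rows); and tissue-specificity categories by
#' type. Cross-table marginal consistency is asserted on every call: the
#' class table's per-type column sums equal the type totals, as do the
#' specificity table row totals when zones are supplied.
#'
#' @param types Named character vector: gene id -> lectin type (G/L/C).
#' @param classes Optional named vector: gene id -> orientation class
#'   (I..VIII, NO_TM, UNCLASSIFIED); must cover the same ids as `types`.
#' @param specificities Optional named vector: gene id -> specificity
#'   category (root_only, stem_only, leaf_only, bud_only, all_four,
#'   two_tissues, three_tissues, low_or_no).
#' @return Object of class `lecfam_summary`: list with `by_type`,
#'   `by_class` (matrix classes x G/L/C/Total), `by_specificity` (matrix
#'   G/L/C/Total x categories), `n_total`.
#' @export
summarize_counts <- function(types, classes = NULL, specificities = NULL) {
  stopifnot(!is.null(names(types)) || length(types) == 0)
  tlev <- c("G", "L", "C")
  if (length(types) > 0 && !all(types %in% tlev)) {
    stop("inconsistent label set: types must be G, L or C")
  }
  by_type <- vapply(tlev, function(t) sum(types == t), integer(1))
  by_type <- c(by_type, Total = sum(by_type))

  by_class <- NULL
  if (!is.null(classes)) {
    if (!setequal(names(classes), names(types))) {
      stop("inconsistent label sets: classes and types cover different genes")
    }
    if (length(classes) > 0 && !all(classes %in% CLASS_ROWS)) {
      stop("unknown orientation class label(s): ",
           paste(setdiff(classes, CLASS_ROWS), collapse = ", "))
    }
    by_class <- matrix(0L, nrow = length(CLASS_ROWS), ncol = 4,
                       dimnames = list(CLASS_ROWS, c(tlev, "Total")))
    for (g in names(classes)) {
      by_class[classes[[g]], types[[g]]] <- by_class[classes[[g]], types[[g]]] + 1L
    }
    by_class[, "Total"] <- as.integer(rowSums(by_class[, tlev, drop = FALSE]))
    stopifnot(identical(as.integer(colSums(by_class[, tlev, drop = FALSE])),
                        unname(by_type[tlev])))
  }

  by_spec <- NULL
  if (!is.null(specificities)) {
    if (!setequal(names(specificities), names(types))) {
      stop("inconsistent label sets: specificities and types cover different genes")
    }
    cols <- SPECIFICITY_COLS[1:8]
    if (length(specificities) > 0 && !all(specificities %in% cols)) {
      stop("unknown specificity label(s): ",
           paste(setdiff(specificities, cols), collapse = ", "))
    }
    by_spec <- matrix(0L, nrow = 4, ncol = length(SPECIFICITY_COLS),
                      dimnames = list(c(tlev, "Total"), SPECIFICITY_COLS))
    for (g in names(specificities)) {
      by_spec[types[[g]], specificities[[g]]] <-
        by_spec[types[[g]], specificities[[g]]] + 1L
    }
    by_spec[, "total"] <- as.integer(rowSums(by_spec[, cols, drop = FALSE]))
    by_spec["Total", ] <- as.integer(colSums(by_spec[tlev, , drop = FALSE]))
    stopifnot(identical(as.integer(by_spec[tlev, "total"]),
                        unname(by_type[tlev])),
              by_spec["Total", "total"] == by_type[["Total"]])
  }

  structure(list(by_type = by_type, by_class = by_class,
                 by_specificity = by_spec, n_total = by_type[["Total"]]),
            class = "lecfam_summary")
}

#' @export
print.lecfam_summary <- function(x, ...) {
  cat("Family catalogue summary\n")
  cat("  per type: ", paste(names(x$by_type), x$by_type, sep = "=",
                            collapse = ", "), "\n")
  if (!is.null(x$by_class)) {
    cat("  orientation classes x type:\n")
    print(x$by_class)
  }
  if (!is.null(x$by_specificity)) {
    cat("  tissue specificity x type:\n")
    print(x$by_specificity)
  }
  invisible(x)
}

read_catalogue_inputs <- function(paths, vocab = default_domain_vocabulary()) {
  need <- c("proteome", "domains", "topology", "gff3", "fpkm", "grouping")
  missing <- setdiff(need, names(paths))
  if (length(missing) > 0) {
    stop("missing input path(s): ", paste(missing, collapse = ", "))
  }
  list(proteome = read_proteome(paths$proteome),
       domain_hits = read_domain_table(paths$domains, vocab),
       topology = read_topology_table(paths$topology),
       loci = read_gene_loci(paths$gff3),
       fpkm = read_fpkm_matrix(paths$fpkm),
       grouping = read_tissue_grouping(paths$grouping))
}

#' Run the full cataloguing pipeline
#'
#' Stages, in order: longest-isoform selection; reciprocal homology
#' expansion from per-type seed proteins; dual-domain family filtering
#' with G/L/C typing; transmembrane-orientation classification;
#' tandem-cluster detection; neighbor-joining phylogeny (optionally with
#' bootstrap supports) of the family members; expression zoning and the
#' specificity table. One structured log line is emitted per stage; a
#' stage failure aborts with the stage name.
#'
#' @param catalogue A catalogue list as produced by [generate_catalogue()]
#'   (simulate mode), or `NULL` when `paths` is given.
#' @param paths Named list of input files (`proteome`, `domains`,
#'   `topology`, `gff3`, `fpkm`, `grouping`) read with the package readers.
#' @param seeds Named character vector of seed protein ids (one per
#'   expected lectin type); defaults to the ground-truth seeds in simulate
#'   mode.
#' @param similarity_threshold,min_coverage Homology screen parameters
#'   (defaults 0.30 and 0.5); see [reciprocal_expand()].
#' @param max_rounds Reciprocal expansion rounds per seed (default 5).
#' @param tm_threshold,sp_threshold Topology thresholds (defaults 0.8, 0.7).
#' @param fpkm_cutoff,all_samples Expression rule (defaults 1.0, any-sample).
#' @param max_intervening,max_gap_bp,super_threshold Tandem criterion
#'   (defaults 5 genes, 100 kb, super when > 20 members).
#' @param bootstrap_replicates Bootstrap replicates for the family tree
#'   (default 1000; 0 skips bootstrap).
#' @param phylo_max_taxa Cap on the number of members entering the tree
#'   stage (default 60; members are subsampled deterministically, spread
#'   over types, to keep the progressive alignment tractable).
#' @param run_phylo Set `FALSE` to skip the tree stage entirely.
#' @param scheme A [scoring_scheme()].
#' @param vocab A [domain_vocabulary()].
#' @param seed Integer seed for the bootstrap stage.
#' @return List of class `lecfam_run`: `summary` (a [summarize_counts()]
#'   result), `candidates`, `members`, `rejected`, `classes`
#'   (per-member class report), `clusters`, `scaffold_genes`, `tree`,
#'   `zones` (per-gene zone report), `sex` (reproductive labels when the
#'   grouping has female/male types), and `provenance` (thresholds, seed
#'   and input fingerprint sufficient to re-run bit-identically).
#' @export
run_pipeline <- function(catalogue = NULL, paths = NULL, seeds = NULL,
                         similarity_threshold = 0.30, min_coverage = 0.5,
                         max_rounds = 5, tm_threshold = 0.8,
                         sp_threshold = 0.7, fpkm_cutoff = 1.0,
                         all_samples = FALSE, max_intervening = 5,
                         max_gap_bp = 100000, super_threshold = 20,
                         bootstrap_replicates = 1000, phylo_max_taxa = 60,
                         run_phylo = TRUE, scheme = scoring_scheme(),
                         vocab = default_domain_vocabulary(), seed = 1) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (is.null(catalogue) && is.null(paths)) {
    stop("either a catalogue or input paths must be supplied")
  }
  if (is.null(catalogue)) {
    catalogue <- stage("read", read_catalogue_inputs(paths, vocab))
  }
  if (is.null(seeds)) {
    if (!is.null(catalogue$truth)) {
      seeds <- catalogue$truth$seeds
    } else {
      stop("seed protein ids are required when no ground truth is attached")
    }
  }

  # 1. isoform selection ----------------------------------------------------
  proteome <- stage("isoforms", select_longest_isoform(catalogue$proteome))
  message(sprintf("[lecfam] isoforms: %d proteins -> %d longest-per-locus",
                  nrow(catalogue$proteome), nrow(proteome)))

  # 2. homology -------------------------------------------------------------
  candidates <- stage("homology", {
    unique(unlist(lapply(seeds, function(s)
      reciprocal_expand(s, proteome, scheme, similarity_threshold,
                        max_rounds, min_coverage))))
  })
  message(sprintf("[lecfam] homology: %d seed(s) -> %d candidate protein(s)",
                  length(seeds), length(candidates)))

  # 3. dual-domain filter ----------------------------------------------------
  filt <- stage("domains", {
    hits <- catalogue$domain_hits
    filter_lecrlk(hits[hits$protein_id %in% candidates, , drop = FALSE],
                  protein_ids = candidates, vocab = vocab)
  })
  members <- filt$members
  members$gene_id <- proteome$isoform_group[match(members$protein_id,
                                                  proteome$id)]
  message(sprintf("[lecfam] domains: %d candidate(s) -> %d member(s), %d rejected",
                  length(candidates), nrow(members), nrow(filt$rejected)))

  # 4. topology classes ------------------------------------------------------
  classes <- stage("topology", {
    hits <- catalogue$domain_hits
    rows <- lapply(seq_len(nrow(members)), function(k) {
      pid <- members$protein_id[k]
      model <- catalogue$topology[[pid]]
      if (is.null(model)) {
        return(data.frame(protein_id = pid, gene_id = members$gene_id[k],
                          class = "UNCLASSIFIED", n_tm = NA_integer_,
                          lectin_side = NA_character_,
                          kinase_side = NA_character_,
                          stringsAsFactors = FALSE))
      }
      cl <- classify_protein(hits[hits$protein_id == pid, , drop = FALSE],
                             model, tm_threshold, sp_threshold)
      data.frame(protein_id = pid, gene_id = members$gene_id[k],
                 class = cl$class, n_tm = cl$n_tm,
                 lectin_side = as.character(cl$lectin_side),
                 kinase_side = as.character(cl$kinase_side),
                 stringsAsFactors = FALSE)
    })
    if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
  if (is.null(classes)) {
    classes <- data.frame(protein_id = character(0), gene_id = character(0),
                          class = character(0), n_tm = integer(0),
                          lectin_side = character(0),
                          kinase_side = character(0), stringsAsFactors = FALSE)
  }
  message(sprintf("[lecfam] topology: %d member(s) classified, %d without TM",
                  nrow(classes), sum(classes$class == "NO_TM")))

  # 5. tandem clusters --------------------------------------------------------
  fam_loci <- catalogue$loci[catalogue$loci$gene_id %in% members$gene_id, ,
                             drop = FALSE]
  fam_loci$lec_type <- members$lec_type[match(fam_loci$gene_id,
                                              members$gene_id)]
  clusters <- stage("tandem", find_clusters(fam_loci, catalogue$loci,
                                            max_intervening, max_gap_bp,
                                            super_threshold))
  message(sprintf(
    "[lecfam] tandem: %d chromosome-placed + %d scaffold gene(s); %d cluster(s), %d super",
    sum(!fam_loci$is_scaffold), length(attr(clusters, "scaffold_genes")),
    nrow(clusters), sum(clusters$is_super)))

  # 6. phylogeny --------------------------------------------------------------
  tree <- NULL
  if (run_phylo && nrow(members) >= 3) {
    tree <- stage("phylo", {
      ids <- members$protein_id
      if (length(ids) > phylo_max_taxa) {
        # deterministic subsample spread over types
        ord <- order(members$lec_type, members$protein_id)
        take <- sort(ord[unique(round(seq(1, length(ord),
                                          length.out = phylo_max_taxa)))])
        ids <- members$protein_id[take]
      }
      seqs <- stats::setNames(
        proteome$sequence[match(ids, proteome$id)], ids)
      msa <- progressive_msa(seqs, scheme)
      if (bootstrap_replicates > 0) {
        bootstrap_support(msa, bootstrap_replicates, seed = seed)
      } else {
        nj_tree(msa_distance_matrix(msa))
      }
    })
    message(sprintf("[lecfam] phylo: NJ tree over %d member(s), %d bootstrap replicate(s)",
                    length(tree$tip.label), bootstrap_replicates))
  }

  # 7. expression --------------------------------------------------------------
  zones <- NULL
  sex <- NULL
  types_by_gene <- stats::setNames(members$lec_type, members$gene_id)
  spec_by_gene <- NULL
  if (!is.null(catalogue$fpkm)) {
    zones <- stage("expression", {
      m <- catalogue$fpkm
      present <- intersect(members$gene_id, rownames(m))
      if (length(present) < nrow(members)) {
        warning(nrow(members) - length(present),
                " member gene(s) absent from the FPKM matrix")
      }
      zone_report(m[present, , drop = FALSE], catalogue$grouping,
                  fpkm_cutoff, all_samples)
    })
    spec_by_gene <- stats::setNames(zones$specificity, zones$gene_id)
    if (all(c("female", "male") %in% unname(catalogue$grouping))) {
      sex <- sex_specific_expression(
        catalogue$fpkm[zones$gene_id, , drop = FALSE], catalogue$grouping,
        fpkm_cutoff, all_samples)
    }
    message(sprintf("[lecfam] expression: %d gene(s) zoned (%s)",
                    nrow(zones),
                    paste(names(table(zones$zone)), table(zones$zone),
                          sep = "=", collapse = ", ")))
  }

  # 8. summary ------------------------------------------------------------------
  summary <- stage("summary", {
    cls <- stats::setNames(classes$class, classes$gene_id)
    sp <- if (!is.null(spec_by_gene) &&
              setequal(names(spec_by_gene), names(types_by_gene)))
      spec_by_gene else NULL
    summarize_counts(types_by_gene, cls, sp)
  })

  provenance <- list(
    seed = seed,
    thresholds = list(similarity_threshold = similarity_threshold,
                      min_coverage = min_coverage, max_rounds = max_rounds,
                      tm_threshold = tm_threshold,
                      sp_threshold = sp_threshold,
                      fpkm_cutoff = fpkm_cutoff, all_samples = all_samples,
                      max_intervening = max_intervening,
                      max_gap_bp = max_gap_bp,
                      super_threshold = super_threshold,
                      bootstrap_replicates = bootstrap_replicates,
                      phylo_max_taxa = phylo_max_taxa,
                      gap_open = scheme$gap_open,
                      gap_extend = scheme$gap_extend),
    seeds = seeds,
    input_fingerprint = fingerprint(list(catalogue$proteome,
                                         catalogue$domain_hits)))
  structure(list(summary = summary, candidates = candidates,
                 members = members, rejected = filt$rejected,
                 classes = classes, clusters = clusters,
                 scaffold_genes = attr(clusters, "scaffold_genes"),
                 tree = tree, zones = zones, sex = sex,
                 provenance = provenance),
            class = "lecfam_run")
}

# Cheap stable fingerprint of a serialized object (vectorised weighted
# checksum; enough to detect input changes in provenance records).
fingerprint <- function(x) {
  raw <- as.double(serialize(x, NULL, version = 2))
  w <- (seq_along(raw) - 1) %% 251 + 1
  sprintf("%d-%.0f", length(raw), sum(raw * w) %% 2^48)
}

#' @export
print.lecfam_run <- function(x, ...) {
  cat("lecfam pipeline run\n")
  print(x$summary)
  cat(sprintf("  clusters: %d (%d super); scaffold members: %d\n",
              nrow(x$clusters), sum(x$clusters$is_super),
              length(x$scaffold_genes)))
  invisible(x)
}
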