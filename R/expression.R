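STANDARD_TISSUES <- c("root", "leaf", "stem", "bud")
ZONES <- c("I", "II", "III", "IV", "other")
SPECIFICITY_COLS <- c("root_only", "stem_only", "leaf_only", "bud_only",
                      "all_four", "two_tissues", "three_tissues",
                      "low_or_no", "total")

#' Read an FPKM matrix (genes x samples, TSV with header)
#'
#' @param path TSV file; first column holds gene ids.
#' @return Numeric matrix, genes in rows.
#' @export
read_fpkm_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  validate_fpkm_matrix(m)
}

validate_fpkm_matrix <- function(m) {
  if (anyNA(m) || any(!is.finite(m))) stop("FPKM matrix has missing or non-finite cells")
  if (any(m < 0)) stop("FPKM values must be non-negative")
  m
}

#' Write an FPKM matrix as TSV
#' @param m Numeric matrix (genes x samples).
#' @param path Output path.
#' @export
write_fpkm_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tissue grouping: sample to tissue type
#'
#' @param samples Character vector of sample ids.
#' @param types Character vector of tissue types, parallel to `samples`.
#' @return Named character vector (sample -> type) of class
#'   `lecfam_grouping`.
#' @export
tissue_grouping <- function(samples, types) {
  stopifnot(length(samples) == length(types))
  if (anyDuplicated(samples)) stop("duplicate sample ids in grouping")
  structure(stats::setNames(as.character(types), samples),
            class = "lecfam_grouping")
}

#' Read a tissue grouping from TSV (columns sample, type) or YAML
#' @param path File path (.yml/.yaml or TSV).
#' @return A [tissue_grouping()].
#' @export
read_tissue_grouping <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    tissue_grouping(names(y), unlist(y))
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    tissue_grouping(df$sample, df$type)
  }
}

check_grouping <- function(m, grouping) {
  missing <- setdiff(colnames(m), names(grouping))
  if (length(missing) > 0L) {
    stop("samples without tissue type: ", paste(missing, collapse = ", "))
  }
  invisible(grouping)
}

#' Is a gene expressed in a tissue type?
#'
#' A gene counts as expressed in a tissue type when its FPKM reaches the
#' cutoff (default 1.0) in at least one sample of that type (any-sample
#' rule). The strict variant (`all_samples = TRUE`) requires every sample
#' of the type to reach the cutoff.
#'
#' @param m FPKM matrix.
#' @param gene Gene id.
#' @param tissue_type Tissue type name.
#' @param grouping A [tissue_grouping()].
#' @param cutoff Detection cutoff (default 1.0; expressed iff FPKM >= cutoff).
#' @param all_samples Use the all-samples rule instead of any-sample.
#' @return Logical flag.
#' @export
expressed_in_type <- function(m, gene, tissue_type, grouping, cutoff = 1.0,
                              all_samples = FALSE) {
  if (!gene %in% rownames(m)) stop("unknown gene: ", gene)
  check_grouping(m, grouping)
  smp <- colnames(m)[grouping[colnames(m)] == tissue_type]
  if (length(smp) == 0L) stop("unknown or empty tissue type: ", tissue_type)
  v <- m[gene, smp] >= cutoff
  if (all_samples) all(v) else any(v)
}

expressed_set <- function(m, gene, grouping, cutoff = 1.0,
                          all_samples = FALSE,
                          tissues = STANDARD_TISSUES) {
  tissues[vapply(tissues, function(tt)
    expressed_in_type(m, gene, tt, grouping, cutoff, all_samples),
    logical(1))]
}

#' Expression zone of a gene
#'
#' Zones over the four standard tissue types: Zone I, no type expressed
#' (low or undetectable everywhere); Zone II, expressed in all four types;
#' Zone III, root only; Zone IV, bud only; everything else is "other"
#' (expressed in exactly one non-root/non-bud tissue, or in two or three
#' tissues).
#'
#' @inheritParams expressed_in_type
#' @return One of `"I"`, `"II"`, `"III"`, `"IV"`, `"other"`.
#' @export
assign_zone <- function(m, gene, grouping, cutoff = 1.0,
                        all_samples = FALSE) {
  present <- unique(unname(grouping[colnames(m)]))
  if (!all(STANDARD_TISSUES %in% present)) {
    stop("zoning requires the four standard tissue types: ",
         paste(STANDARD_TISSUES, collapse = ", "))
  }
  e <- expressed_set(m, gene, grouping, cutoff, all_samples)
  if (length(e) == 0L) return("I")
  if (length(e) == 4L) return("II")
  if (identical(e, "root")) return("III")
  if (identical(e, "bud")) return("IV")
  "other"
}

specificity_category <- function(e) {
  if (length(e) == 0L) return("low_or_no")
  if (length(e) == 4L) return("all_four")
  if (length(e) == 1L) return(paste0(e, "_only"))
  if (length(e) == 2L) return("two_tissues")
  "three_tissues"
}

#' Tissue-specificity count matrix (types x specificity categories)
#'
#' Counts genes per lectin type in mutually exclusive specificity
#' categories: expressed only in root / stem / leaf / bud, in all four
#' tissue types, in exactly two, in exactly three, or with low/no
#' expression (FPKM < 1 in every sample; this equals Zone I). Every gene
#' falls in exactly one column; row totals equal family sizes, and the
#' Total row equals the column sums (asserted).
#'
#' @param m FPKM matrix.
#' @param grouping A [tissue_grouping()].
#' @param type_labels Named character vector gene -> lectin type (G/L/C).
#' @param cutoff,all_samples See [expressed_in_type()].
#' @return Integer matrix with rows G, L, C, Total. Attribute
#'   `"undetectable"` lists genes with FPKM 0 in every sample.
#' @export
specificity_table <- function(m, grouping, type_labels, cutoff = 1.0,
                              all_samples = FALSE) {
  genes <- rownames(m)
  unlabeled <- setdiff(genes, names(type_labels))
  if (length(unlabeled) > 0L) {
    stop("unlabeled gene(s): ", paste(unlabeled, collapse = ", "))
  }
  types <- c("G", "L", "C")
  tab <- matrix(0L, nrow = length(types) + 1L, ncol = length(SPECIFICITY_COLS),
                dimnames = list(c(types, "Total"), SPECIFICITY_COLS))
  undetectable <- character(0)
  std_samples <- colnames(m)[grouping[colnames(m)] %in% STANDARD_TISSUES]
  for (g in genes) {
    e <- expressed_set(m, g, grouping, cutoff, all_samples)
    cat_ <- specificity_category(e)
    ty <- type_labels[[g]]
    tab[ty, cat_] <- tab[ty, cat_] + 1L
    tab[ty, "total"] <- tab[ty, "total"] + 1L
    if (all(m[g, std_samples] == 0)) undetectable <- c(undetectable, g)
  }
  tab["Total", ] <- colSums(tab[types, , drop = FALSE])
  stopifnot(sum(tab["Total", SPECIFICITY_COLS[1:8]]) == tab["Total", "total"],
            tab["Total", "total"] == length(genes))
  attr(tab, "undetectable") <- undetectable
  tab
}

#' Zone assignment report for all genes
#'
#' @inheritParams specificity_table
#' @return `data.frame` with gene_id, zone, specificity category and an
#'   `undetectable` flag (FPKM 0 in every standard-tissue sample).
#' @export
zone_report <- function(m, grouping, cutoff = 1.0, all_samples = FALSE) {
  if (nrow(m) == 0L) {
    return(data.frame(gene_id = character(0), zone = character(0),
                      specificity = character(0), undetectable = logical(0),
                      stringsAsFactors = FALSE))
  }
  std_samples <- colnames(m)[grouping[colnames(m)] %in% STANDARD_TISSUES]
  rows <- lapply(rownames(m), function(g) {
    e <- expressed_set(m, g, grouping, cutoff, all_samples)
    data.frame(gene_id = g,
               zone = assign_zone(m, g, grouping, cutoff, all_samples),
               specificity = specificity_category(e),
               undetectable = all(m[g, std_samples] == 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Sex-specific expression over reproductive tissue types
#'
#' Applies the same any-sample >= cutoff rule to the two reproductive
#' tissue types only.
#'
#' @param m FPKM matrix.
#' @param grouping A [tissue_grouping()] containing `female` and `male`
#'   types.
#' @param cutoff Detection cutoff (default 1.0).
#' @param all_samples Strict all-samples rule.
#' @return Named character vector gene -> one of `female_only`,
#'   `male_only`, `both`, `neither`.
#' @export
sex_specific_expression <- function(m, grouping, cutoff = 1.0,
                                    all_samples = FALSE) {
  present <- unique(unname(grouping[colnames(m)]))
  if (!all(c("female", "male") %in% present)) {
    stop("grouping must contain female and male reproductive types")
  }
  vapply(rownames(m), function(g) {
    f <- expressed_in_type(m, g, "female", grouping, cutoff, all_samples)
    ml <- expressed_in_type(m, g, "male", grouping, cutoff, all_samples)
    if (f && ml) "both" else if (f) "female_only" else if (ml) "male_only" else "neither"
  }, character(1))
}

#' Long-format expression table for plotting
#'
#' @param m FPKM matrix.
#' @param grouping A [tissue_grouping()].
#' @return `data.frame` with gene_id, sample, tissue_type, fpkm.
#' @export
fpkm_long <- function(m, grouping) {
  check_grouping(m, grouping)
  data.frame(gene_id = rep(rownames(m), times = ncol(m)),
             sample = rep(colnames(m), each = nrow(m)),
             tissue_type = rep(unname(grouping[colnames(m)]), each = nrow(m)),
             fpkm = as.vector(m), stringsAsFactors = FALSE)
}
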