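DOMAIN_ROLES <- c("lectin_bulb", "lectin_legume", "lectin_C", "kinase",
                  "s_locus", "egf", "pan", "duf3403", "other")
LECTIN_ROLES <- c("lectin_bulb", "lectin_legume", "lectin_C")
LECTIN_TYPE <- c(lectin_bulb = "G", lectin_legume = "L", lectin_C = "C")

#' Domain vocabulary: accession to role and model length
#'
#' Maps domain accessions to their functional role and the expected
#' full-length of the domain model (used to flag truncated hits). The
#' default ships Pfam-style names; any mapping can be supplied, e.g. from a
#' YAML file via [read_domain_vocabulary()].
#'
#' @param accession,role,model_length Equal-length vectors; `role` must be
#'   one of lectin_bulb, lectin_legume, lectin_C, kinase, s_locus, egf,
#'   pan, duf3403, other; `model_length` must exceed 10.
#' @return `data.frame` of class `lecfam_vocab`.
#' @export
domain_vocabulary <- function(accession, role, model_length) {
  stopifnot(length(accession) == length(role),
            length(role) == length(model_length))
  if (anyDuplicated(accession)) stop("duplicate accessions in vocabulary")
  if (!all(role %in% DOMAIN_ROLES)) {
    stop("unknown role: ", paste(setdiff(role, DOMAIN_ROLES), collapse = ", "))
  }
  if (!all(model_length > 10)) stop("model_length must exceed 10 residues")
  for (lr in LECTIN_ROLES) {
    if (!lr %in% role) stop("vocabulary must map at least one accession to ", lr)
  }
  structure(data.frame(accession = accession, role = role,
                       model_length = as.integer(model_length),
                       stringsAsFactors = FALSE),
            class = c("lecfam_vocab", "data.frame"))
}

#' Default domain vocabulary (Pfam-style accession names)
#' @return A [domain_vocabulary()].
#' @export
default_domain_vocabulary <- function() {
  domain_vocabulary(
    accession = c("B_lectin", "Lectin_legB", "Lectin_C", "Pkinase",
                  "Pkinase_Tyr", "S_locus_glycop", "EGF", "EGF_CA", "PAN_1",
                  "PAN_2", "DUF3403"),
    role = c("lectin_bulb", "lectin_legume", "lectin_C", "kinase", "kinase",
             "s_locus", "egf", "egf", "pan", "pan", "duf3403"),
    model_length = c(110L, 230L, 110L, 250L, 250L, 120L, 40L, 40L, 85L,
                     85L, 80L))
}

#' Read a domain vocabulary from YAML
#'
#' Expected structure: a mapping of accession to `{role, model_length}`.
#' @param path YAML file.
#' @return A [domain_vocabulary()].
#' @export
read_domain_vocabulary <- function(path) {
  y <- yaml::read_yaml(path)
  domain_vocabulary(accession = names(y),
                    role = vapply(y, `[[`, character(1), "role"),
                    model_length = vapply(y, function(e)
                      as.integer(e$model_length), integer(1)))
}

#' Read a domain-hit table
#'
#' Tab-separated, header required. Columns: `protein_id`, `accession`,
#' optionally `role`, `start`, `end` (1-based inclusive residue
#' coordinates), `score`. Missing roles are filled from the vocabulary.
#'
#' @param path TSV file.
#' @param vocab A [domain_vocabulary()] used to resolve roles.
#' @return `data.frame` of domain hits.
#' @export
read_domain_table <- function(path, vocab = default_domain_vocabulary()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "accession", "start", "end", "score")
  if (!all(need %in% names(df))) {
    stop("domain table must have columns: ", paste(need, collapse = ", "))
  }
  if (!"role" %in% names(df)) {
    df$role <- vocab$role[match(df$accession, vocab$accession)]
    if (anyNA(df$role)) {
      stop("unknown accession(s): ",
           paste(unique(df$accession[is.na(df$role)]), collapse = ", "))
    }
  }
  validate_domain_hits(df)
}

validate_domain_hits <- function(hits) {
  stopifnot(all(hits$start >= 1), all(hits$start <= hits$end))
  hits
}

#' Assign the lectin type of a family member
#'
#' G for a bulb (mannose-binding) lectin, L for a legume lectin, C for a
#' calcium-dependent lectin. A protein carrying more than one distinct
#' lectin role is a data problem and raises an `ambiguous_type` error; it
#' is never silently resolved.
#'
#' @param hits Domain-hit rows of a single protein (must contain a lectin).
#' @return `"G"`, `"L"` or `"C"`.
#' @export
assign_type <- function(hits) {
  lect <- unique(hits$role[hits$role %in% LECTIN_ROLES])
  if (length(lect) == 0L) stop("no lectin domain present")
  if (length(lect) > 1L) {
    stop("ambiguous_type: protein carries distinct lectin roles (",
         paste(lect, collapse = ", "), ")")
  }
  unname(LECTIN_TYPE[lect])
}

#' Domain architecture of a protein
#'
#' Roles ordered by ascending start coordinate; repeated roles (tandem
#' lectins, duplicated kinases) are preserved with their multiplicity.
#'
#' @param hits Domain-hit rows of a single protein.
#' @param collapse Optional separator; when given, a single string is
#'   returned instead of a character vector.
#' @return Character vector of roles (or collapsed string).
#' @export
architecture_string <- function(hits, collapse = NULL) {
  ord <- order(hits$start, hits$end, hits$role)
  roles <- hits$role[ord]
  if (is.null(collapse)) roles else paste(roles, collapse = collapse)
}

#' Flag truncated domain hits
#'
#' A hit is truncated when it lacks at least 10 residues relative to the
#' expected full model length: `end - start + 1 <= model_length - 10`.
#'
#' @param hits Domain-hit rows (columns accession, start, end).
#' @param vocab A [domain_vocabulary()].
#' @return Logical vector, one flag per hit.
#' @export
detect_truncation <- function(hits, vocab = default_domain_vocabulary()) {
  ml <- vocab$model_length[match(hits$accession, vocab$accession)]
  if (anyNA(ml)) {
    stop("unknown accession(s): ",
         paste(unique(hits$accession[is.na(ml)]), collapse = ", "))
  }
  (hits$end - hits$start + 1) <= (ml - 10)
}

#' Dual-domain family filter
#'
#' A protein is a family member iff it carries at least one lectin-role hit
#' AND at least one kinase-role hit. Everything else is rejected with a
#' reason (`no_lectin`, `no_kinase`, or `neither`). Duplicate hits with
#' identical coordinates are deduplicated with a warning. Truncation is
#' reported, never filtered: a member with a truncated lectin or kinase
#' remains a member.
#'
#' @param hits Domain-hit table (all proteins).
#' @param protein_ids Optional vector of proteins under consideration;
#'   proteins without any hit are rejected with reason `neither`.
#' @param vocab A [domain_vocabulary()] for truncation calls.
#' @return List with `members` (protein_id, lec_type, architecture,
#'   truncated_lectin, truncated_kinase, ambiguous) and `rejected`
#'   (protein_id, reason). Members with several distinct lectin roles get
#'   `ambiguous = TRUE` and `lec_type = NA`.
#' @export
filter_lecrlk <- function(hits, protein_ids = NULL,
                          vocab = default_domain_vocabulary()) {
  validate_domain_hits(hits)
  key <- paste(hits$protein_id, hits$accession, hits$start, hits$end)
  if (anyDuplicated(key)) {
    warning("deduplicated ", sum(duplicated(key)),
            " domain hit(s) with identical coordinates")
    hits <- hits[!duplicated(key), , drop = FALSE]
  }
  ids <- unique(c(hits$protein_id, protein_ids))
  grouped <- split(hits, factor(hits$protein_id, levels = ids))

  members <- list()
  rejected <- list()
  for (id in ids) {
    h <- grouped[[id]]
    has_lectin <- !is.null(h) && any(h$role %in% LECTIN_ROLES)
    has_kinase <- !is.null(h) && any(h$role == "kinase")
    if (has_lectin && has_kinase) {
      tr <- detect_truncation(h, vocab)
      type <- tryCatch(assign_type(h), error = function(e) NA_character_)
      members[[id]] <- data.frame(
        protein_id = id, lec_type = type,
        architecture = architecture_string(h, collapse = "+"),
        truncated_lectin = any(tr[h$role %in% LECTIN_ROLES]),
        truncated_kinase = any(tr[h$role == "kinase"]),
        ambiguous = is.na(type), stringsAsFactors = FALSE)
      if (is.na(type)) {
        warning("ambiguous_type: ", id, " carries distinct lectin roles")
      }
    } else {
      reason <- if (has_lectin) "no_kinase" else if (has_kinase) "no_lectin" else "neither"
      rejected[[id]] <- data.frame(protein_id = id, reason = reason,
                                   stringsAsFactors = FALSE)
    }
  }
  empty_members <- data.frame(protein_id = character(0),
                              lec_type = character(0),
                              architecture = character(0),
                              truncated_lectin = logical(0),
                              truncated_kinase = logical(0),
                              ambiguous = logical(0), stringsAsFactors = FALSE)
  empty_rej <- data.frame(protein_id = character(0), reason = character(0),
                          stringsAsFactors = FALSE)
  list(members = if (length(members)) do.call(rbind, c(members, make.row.names = FALSE)) else empty_members,
       rejected = if (length(rejected)) do.call(rbind, c(rejected, make.row.names = FALSE)) else empty_rej)
}
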