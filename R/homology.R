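#' Build a protein record table
#'
#' The basic container for proteome entries: one row per protein with its
#' sequence and the isoform group (locus) it belongs to. Alternative
#' isoforms of one locus share an `isoform_group`.
#'
#' @param id Character vector of unique protein identifiers.
#' @param sequence Character vector of amino-acid sequences.
#' @param isoform_group Character vector of locus identifiers; defaults to
#'   stripping a trailing `.N` isoform suffix from `id`.
#' @return A `data.frame` with columns `id`, `sequence`, `isoform_group`.
#' @export
protein_records <- function(id, sequence,
                            isoform_group = sub("\\.[0-9]+$", "", id)) {
  stopifnot(length(id) == length(sequence),
            length(id) == length(isoform_group))
  if (anyDuplicated(id)) stop("duplicate protein ids")
  for (k in seq_along(sequence)) check_aa_sequence(sequence[k], id[k])
  data.frame(id = as.character(id), sequence = as.character(sequence),
             isoform_group = as.character(isoform_group),
             stringsAsFactors = FALSE)
}

#' Read a proteome FASTA into a protein record table
#'
#' @param path FASTA file (wrapped lines, multi-record).
#' @param isoform_regex Regular expression removed from the identifier to
#'   obtain the isoform group (default: trailing `.N`).
#' @return A protein record `data.frame` (see [protein_records()]).
#' @export
read_proteome <- function(path, isoform_regex = "\\.[0-9]+$") {
  ss <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  protein_records(ids, as.character(ss),
                  isoform_group = sub(isoform_regex, "", ids))
}

#' Write a protein record table as FASTA
#'
#' @param records Protein record table.
#' @param path Output path.
#' @export
write_proteome <- function(records, path) {
  ss <- Biostrings::AAStringSet(stats::setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Keep the longest isoform per locus
#'
#' Exactly one record per isoform group is retained: the one with maximal
#' sequence length. Length ties are broken by taking the lexicographically
#' smallest id, so the result is deterministic. The original row order of
#' the retained records is preserved.
#'
#' @param records Protein record table.
#' @return Subset of `records`, one row per isoform group.
#' @export
select_longest_isoform <- function(records) {
  if (nrow(records) == 0L) return(records)
  len <- nchar(records$sequence)
  keep <- vapply(split(seq_len(nrow(records)), records$isoform_group),
                 function(idx) {
                   best <- idx[len[idx] == max(len[idx])]
                   best[order(records$id[best])][1]
                 }, integer(1))
  records[sort(keep), , drop = FALSE]
}

#' Reciprocal similarity-threshold homolog expansion
#'
#' Starting from a seed protein, collects all proteome entries whose local
#' alignment similarity to the query reaches `similarity_threshold`
#' (default 30 %), then re-queries with the highest-similarity hit not yet
#' used as a query, iterating until no new hits are found or `max_rounds`
#' queries have been issued. The returned set always contains the seed.
#'
#' @param seed_id Identifier of the seed protein (must be in `proteome`).
#' @param proteome Protein record table.
#' @param scheme A [scoring_scheme()].
#' @param similarity_threshold Fraction in (0, 1]; a subject is a hit when
#'   the local alignment similarity is `>=` this value (default 0.30).
#' @param max_rounds Maximum number of query rounds (default 5).
#' @param min_coverage Minimum fraction of the shorter sequence that the
#'   residue-residue columns of the local alignment must cover for a hit to
#'   count (default 0.5). Unrelated proteins almost always share a short
#'   high-scoring local alignment whose percent similarity is high, so a
#'   similarity cut alone cannot separate homologs from noise; the coverage
#'   requirement plays the role that alignment significance (E-values)
#'   plays in database searches. Set to 0 to apply the bare similarity cut.
#' @param min_score_density Minimum alignment score per residue-residue
#'   column (default 1.0). With the default BLOSUM62 costs, homologous
#'   alignments score roughly 3-5 per column while optimal alignments of
#'   unrelated sequences average about 0.25, so this gate separates the two
#'   regimes by more than an order of magnitude. Together with
#'   `min_coverage` it stands in for the score significance filter that
#'   precedes any percent-similarity readout in real database screens. Set
#'   to `-Inf` to disable.
#' @return Character vector of member identifiers (seed included), in
#'   discovery order.
#' @export
reciprocal_expand <- function(seed_id, proteome, scheme = scoring_scheme(),
                              similarity_threshold = 0.30, max_rounds = 5,
                              min_coverage = 0.5, min_score_density = 1.0) {
  if (nrow(proteome) == 0L) stop("empty proteome")
  if (!seed_id %in% proteome$id) stop("seed '", seed_id, "' absent from proteome")
  stopifnot(similarity_threshold > 0, similarity_threshold <= 1,
            max_rounds >= 1)

  alpha <- rownames(scheme$matrix)
  enc <- lapply(proteome$sequence, encode_aa, alphabet = alpha)
  names(enc) <- proteome$id

  found <- stats::setNames(1.0, seed_id)   # id -> best similarity seen
  used <- character(0)
  query <- seed_id
  for (round in seq_len(max_rounds)) {
    qe <- enc[[query]]
    sims <- vapply(proteome$id, function(id) {
      if (id == query) return(NA_real_)
      res <- align_affine_cpp(qe, enc[[id]], scheme$matrix, scheme$gap_open,
                              scheme$gap_extend, TRUE)
      n_resres <- sum(res$pairs[, 1] > 0 & res$pairs[, 2] > 0)
      if (n_resres == 0) return(-1)
      cov <- n_resres / min(length(qe), length(enc[[id]]))
      if (cov < min_coverage) return(-1)
      if (res$score / n_resres < min_score_density) return(-1)
      alignment_similarity(res, qe, enc[[id]], scheme$matrix)
    }, numeric(1))
    hits <- proteome$id[!is.na(sims) & sims >= similarity_threshold]
    new <- setdiff(hits, names(found))
    for (h in hits) {
      s <- sims[match(h, proteome$id)]
      if (!(h %in% names(found)) || found[[h]] < s) found[h] <- s
    }
    used <- c(used, query)
    if (length(new) == 0L) break
    unused <- setdiff(names(found), used)
    if (length(unused) == 0L) break
    query <- unused[order(-found[unused], unused)][1]
  }
  names(found)
}

# Residue-residue columns of a C++ alignment result over the shorter
# sequence length.
alignment_coverage <- function(res, len_a, len_b) {
  cols <- res$pairs
  if (nrow(cols) == 0L) return(0)
  sum(cols[, 1] > 0 & cols[, 2] > 0) / min(len_a, len_b)
}

# Similarity of a C++ alignment result, positive-scoring columns over all
# alignment columns (gaps included).
alignment_similarity <- function(res, ea, eb, S) {
  cols <- res$pairs
  if (nrow(cols) == 0L) return(0)
  both <- cols[, 1] > 0 & cols[, 2] > 0
  if (!any(both)) return(0)
  sc <- S[cbind(ea[cols[both, 1]] + 1L, eb[cols[both, 2]] + 1L)]
  sum(sc > 0) / nrow(cols)
}

#' All-vs-all similarity report
#'
#' Convenience helper producing the tabular hit report used by the search
#' front end: local alignment of every query against every subject.
#'
#' @param queries,subjects Protein record tables.
#' @param scheme A [scoring_scheme()].
#' @return `data.frame` with columns query, subject, score, similarity,
#'   identity.
#' @export
similarity_report <- function(queries, subjects, scheme = scoring_scheme()) {
  rows <- list()
  for (qi in seq_len(nrow(queries))) {
    for (si in seq_len(nrow(subjects))) {
      if (queries$id[qi] == subjects$id[si]) next
      al <- align(queries$sequence[qi], subjects$sequence[si], scheme, "local")
      rows[[length(rows) + 1L]] <- data.frame(
        query = queries$id[qi], subject = subjects$id[si], score = al$score,
        similarity = al$similarity, identity = al$identity,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
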