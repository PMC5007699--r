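ORIENTATION_CLASSES <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
                         "NO_TM", "UNCLASSIFIED")

#' Membrane topology model of one protein
#'
#' Ordered inside/membrane/outside segments tiling the whole sequence, plus
#' an optional signal-peptide score and cleavage position (as produced by
#' TMHMM/SignalP-style predictors or the built-in fallback).
#'
#' @param protein_id Identifier.
#' @param segments `data.frame` with columns `label` (one of inside,
#'   membrane, outside), `start`, `end` (1-based inclusive), `score` in
#'   `[0, 1]`. Segments must tile `1..length` without overlap and the side
#'   labels must alternate across each membrane segment.
#' @param sp_score Signal-peptide score in `[0, 1]`, or `NA` when absent.
#' @param sp_end Cleavage position, or `NA`.
#' @return Object of class `lecfam_topology`.
#' @export
topology_model <- function(protein_id, segments, sp_score = NA_real_,
                           sp_end = NA_integer_) {
  stopifnot(is.data.frame(segments),
            all(c("label", "start", "end", "score") %in% names(segments)))
  segments <- segments[order(segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  if (!all(segments$label %in% c("inside", "membrane", "outside"))) {
    stop("segment labels must be inside/membrane/outside")
  }
  if (!all(segments$score >= 0 & segments$score <= 1)) {
    stop("segment scores must lie in [0, 1]")
  }
  n <- nrow(segments)
  if (n == 0L) stop("a topology model needs at least one segment")
  if (segments$start[1] != 1L) stop("segments must start at position 1")
  if (n > 1L && any(segments$start[-1] != segments$end[-n] + 1L)) {
    stop("segments must tile the sequence without gaps or overlap")
  }
  contradictory <- FALSE
  sides <- segments$label[segments$label != "membrane"]
  memb <- segments$label == "membrane"
  # Sides must alternate; two side segments may not be adjacent.
  if (n > 1L) {
    adj <- which(!memb[-n] & !memb[-1])
    for (k in adj) {
      if (segments$label[k] != segments$label[k + 1L]) contradictory <- TRUE
    }
    # across each membrane segment the side flips
    for (k in which(memb)) {
      before <- if (k > 1L) segments$label[k - 1L] else NA
      after <- if (k < n) segments$label[k + 1L] else NA
      if (!is.na(before) && !is.na(after) && before == after) {
        contradictory <- TRUE
      }
    }
  }
  structure(list(protein_id = protein_id, segments = segments,
                 sp_score = sp_score, sp_end = sp_end,
                 contradictory = contradictory),
            class = "lecfam_topology")
}

#' Read a topology table (one row per segment)
#'
#' Tab-separated with header: `protein_id`, `segment_label` (inside,
#' membrane, outside), `start`, `end`, `score`, `sp_score`, `sp_end` (the
#' last two repeated on every row of a protein; empty/NA when absent).
#'
#' @param path TSV file.
#' @return Named list of [topology_model()] objects.
#' @export
read_topology_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "segment_label", "start", "end", "score")
  if (!all(need %in% names(df))) {
    stop("topology table must have columns: ", paste(need, collapse = ", "))
  }
  if (!"sp_score" %in% names(df)) df$sp_score <- NA_real_
  if (!"sp_end" %in% names(df)) df$sp_end <- NA_integer_
  lapply(split(df, df$protein_id)[unique(df$protein_id)], function(d) {
    topology_model(d$protein_id[1],
                   data.frame(label = d$segment_label, start = d$start,
                              end = d$end, score = d$score,
                              stringsAsFactors = FALSE),
                   sp_score = d$sp_score[1], sp_end = d$sp_end[1])
  })
}

#' Write topology models to a TSV table
#' @param models List of [topology_model()] objects.
#' @param path Output TSV path.
#' @export
write_topology_table <- function(models, path) {
  rows <- lapply(models, function(m) {
    data.frame(protein_id = m$protein_id, segment_label = m$segments$label,
               start = m$segments$start, end = m$segments$end,
               score = m$segments$score, sp_score = m$sp_score,
               sp_end = m$sp_end, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Renumber side labels downstream of a removed membrane segment and merge
# adjacent same-label side segments.
merge_side_segments <- function(segments) {
  n <- nrow(segments)
  if (n <= 1L) return(segments)
  out <- segments[1, , drop = FALSE]
  for (k in 2:n) {
    last <- nrow(out)
    if (segments$label[k] != "membrane" && out$label[last] != "membrane" &&
        segments$label[k] == out$label[last]) {
      out$end[last] <- segments$end[k]
      out$score[last] <- max(out$score[last], segments$score[k])
    } else {
      out <- rbind(out, segments[k, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

#' Apply the transmembrane probability threshold
#'
#' Membrane segments scoring below `tm_threshold` (default 0.8) are
#' rejected: the segment is reabsorbed into its flanking side regions, and
#' side labels downstream are flipped so inside/outside continue to
#' alternate across the remaining membrane segments.
#'
#' @param model A [topology_model()].
#' @param tm_threshold Acceptance threshold for the membrane probability
#'   score (default 0.8; a segment is kept when `score >= tm_threshold`).
#' @return The filtered [topology_model()].
#' @export
accept_tm_segments <- function(model, tm_threshold = 0.8) {
  seg <- model$segments
  repeat {
    drop <- which(seg$label == "membrane" & seg$score < tm_threshold)
    if (length(drop) == 0L) break
    k <- drop[1]
    after <- seg$label[-seq_len(k)]
    flip <- c(inside = "outside", outside = "inside", membrane = "membrane")
    if (k < nrow(seg)) {
      seg$label[(k + 1):nrow(seg)] <- unname(flip[after])
    }
    # reinterpret the rejected membrane stretch as part of the preceding
    # (or, at the N terminus, following) side region
    side_label <- if (k > 1L) seg$label[k - 1L] else if (k < nrow(seg))
      seg$label[k + 1L] else "outside"
    seg$label[k] <- side_label
    seg <- merge_side_segments(seg)
  }
  topology_model(model$protein_id, seg, model$sp_score, model$sp_end)
}

#' Give priority to the signal peptide over an overlapping first TM
#'
#' When the signal-peptide score reaches `sp_threshold` (default 0.7) and
#' the first membrane segment overlaps the signal region `1..sp_end`, that
#' membrane segment is reinterpreted as the signal peptide: it is removed
#' from the TM count and the mature chain starts extracellular. The TM
#' count never increases.
#'
#' @param model A [topology_model()], after [accept_tm_segments()].
#' @param sp_threshold Signal-peptide acceptance score (default 0.7).
#' @return The resolved [topology_model()].
#' @export
resolve_signal_peptide <- function(model, sp_threshold = 0.7) {
  if (is.na(model$sp_score) || model$sp_score < sp_threshold) return(model)
  seg <- model$segments
  tm <- which(seg$label == "membrane")
  if (length(tm) == 0L) return(model)
  k <- tm[1]
  # when no cleavage site is reported, fall back to the conventional
  # maximal signal-peptide extent of 40 residues
  sp_end <- if (is.na(model$sp_end)) 40L else model$sp_end
  if (seg$start[k] > sp_end) return(model)   # first TM beyond signal region
  # signal region and the removed TM become the extracellular N terminus
  seg$label[seq_len(k)] <- "outside"
  if (k < nrow(seg)) {
    # mature chain starts extracellular: relabel downstream alternately
    side <- "outside"
    for (j in (k + 1):nrow(seg)) {
      if (seg$label[j] == "membrane") {
        side <- if (side == "outside") "inside" else "outside"
      } else {
        seg$label[j] <- side
      }
    }
  }
  seg <- merge_side_segments(seg)
  topology_model(model$protein_id, seg, model$sp_score, model$sp_end)
}

#' Membrane side of a domain
#'
#' The side (extracellular for "outside", intracellular for "inside")
#' whose segments cover a strict majority of the domain's residues; when no
#' side reaches a strict majority (e.g. a membrane segment splits the
#' domain 50/50) the domain is called membrane_spanning.
#'
#' @param start,end Domain coordinates (1-based inclusive).
#' @param model A resolved [topology_model()].
#' @return `"extracellular"`, `"intracellular"` or `"membrane_spanning"`.
#' @export
domain_side <- function(start, end, model) {
  seg <- model$segments
  L <- seg$end[nrow(seg)]
  if (start < 1 || end > L) stop("domain outside sequence bounds")
  cover <- function(lab) {
    s <- seg[seg$label == lab, , drop = FALSE]
    if (nrow(s) == 0L) return(0L)
    sum(pmax(0L, pmin(s$end, end) - pmax(s$start, start) + 1L))
  }
  dlen <- end - start + 1L
  if (cover("outside") > dlen / 2) return("extracellular")
  if (cover("inside") > dlen / 2) return("intracellular")
  "membrane_spanning"
}

#' Eight-class transmembrane orientation classifier
#'
#' Classifies a receptor by its accepted TM count and the sides of its
#' first lectin and first kinase domain: one TM gives classes I
#' (lectin out / kinase in), II (in/out) and III (out/out); two TMs give IV
#' (out/out), V (in/out) and VI (out/in); three TMs give VII (out/in) and
#' VIII (in/out). Zero TMs map to NO_TM; every other combination (e.g. one
#' TM with both domains inside, four or more TMs, or a membrane-spanning
#' domain) is UNCLASSIFIED. The function is total over its input domain.
#'
#' @param n_tm Number of accepted membrane segments.
#' @param lectin_side,kinase_side Sides from [domain_side()] (ignored when
#'   `n_tm == 0`).
#' @return One of I..VIII, NO_TM, UNCLASSIFIED.
#' @export
classify_orientation <- function(n_tm, lectin_side, kinase_side) {
  stopifnot(n_tm >= 0)
  if (n_tm == 0) return("NO_TM")
  key <- paste(n_tm, substr(lectin_side, 1, 5), substr(kinase_side, 1, 5))
  map <- c("1 extra intra" = "I", "1 intra extra" = "II",
           "1 extra extra" = "III", "2 extra extra" = "IV",
           "2 intra extra" = "V", "2 extra intra" = "VI",
           "3 extra intra" = "VII", "3 intra extra" = "VIII")
  cls <- unname(map[key])
  if (is.na(cls)) "UNCLASSIFIED" else cls
}

#' Classify one protein from its domain hits and topology model
#'
#' Convenience wrapper: applies the TM score threshold, the signal-peptide
#' priority rule, determines the sides of the first (by coordinate) lectin
#' and kinase domains, and assigns the orientation class. For multi-copy
#' architectures the first lectin and first kinase decide the class;
#' duplicated domains remain visible in the architecture string.
#'
#' @param hits Domain-hit rows of the protein.
#' @param model A [topology_model()].
#' @param tm_threshold,sp_threshold Acceptance thresholds (defaults 0.8 and
#'   0.7).
#' @return List with `class`, `n_tm`, `lectin_side`, `kinase_side`.
#' @export
classify_protein <- function(hits, model, tm_threshold = 0.8,
                             sp_threshold = 0.7) {
  m <- accept_tm_segments(model, tm_threshold)
  m <- resolve_signal_peptide(m, sp_threshold)
  n_tm <- sum(m$segments$label == "membrane")
  lec <- hits[hits$role %in% LECTIN_ROLES, , drop = FALSE]
  kin <- hits[hits$role == "kinase", , drop = FALSE]
  if (nrow(lec) == 0L || nrow(kin) == 0L) {
    stop("classification needs at least one lectin and one kinase hit")
  }
  lec <- lec[which.min(lec$start), ]
  kin <- kin[which.min(kin$start), ]
  if (m$contradictory) {
    return(list(class = "UNCLASSIFIED", n_tm = n_tm, lectin_side = NA,
                kinase_side = NA))
  }
  ls <- domain_side(lec$start, lec$end, m)
  ks <- domain_side(kin$start, kin$end, m)
  list(class = classify_orientation(n_tm, ls, ks), n_tm = n_tm,
       lectin_side = ls, kinase_side = ks)
}

# Kyte-Doolittle hydropathy scale.
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2, X = 0)

#' Built-in sliding-window transmembrane predictor
#'
#' A deliberately simple stand-in used when no topology table is supplied:
#' per-residue Kyte-Doolittle hydropathy is averaged over a sliding window
#' (truncated at the ends), mapped to a `[0, 1]` score by a fixed logistic
#' centred at mean hydropathy 1.6, and maximal runs of positions above
#' `hydropathy_cutoff` become membrane segments (scored by their peak
#' position score, the run's strongest window).
#' Sides alternate, starting from the positive-inside heuristic: the
#' segment before the first TM is "inside" when its Arg+Lys fraction
#' exceeds that of the segment after it. This is a calibrated toy, not a
#' reimplementation of an HMM-based topology predictor.
#'
#' @param sequence Amino-acid string, longer than `window`.
#' @param window Window width (default 19).
#' @param hydropathy_cutoff Score cutoff in `(0, 1)` (default 0.5,
#'   i.e. mean hydropathy 1.6).
#' @return A [topology_model()] (no signal-peptide prediction).
#' @export
predict_tm_fallback <- function(sequence, window = 19,
                                hydropathy_cutoff = 0.5) {
  check_aa_sequence(sequence)
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  if (L <= window) stop("sequence must be longer than the window (", window, ")")
  h <- KD_SCALE[chars]
  half <- window %/% 2
  means <- vapply(seq_len(L), function(i) {
    mean(h[max(1, i - half):min(L, i + half)])
  }, numeric(1))
  score <- stats::plogis(means - 1.6)
  above <- score > hydropathy_cutoff
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tms <- data.frame(start = starts[r$values], end = ends[r$values])

  if (nrow(tms) == 0L) {
    seg <- data.frame(label = "outside", start = 1L, end = L, score = 1,
                      stringsAsFactors = FALSE)
    return(topology_model("query", seg))
  }
  rk_frac <- function(from, to) {
    if (to < from) return(0)
    mean(chars[from:to] %in% c("R", "K"))
  }
  before <- rk_frac(1L, tms$start[1] - 1L)
  after_start <- tms$end[1] + 1L
  after_end <- if (nrow(tms) > 1L) tms$start[2] - 1L else L
  first_side <- if (before > rk_frac(after_start, after_end)) "inside" else "outside"

  seg <- list()
  side <- first_side
  pos <- 1L
  for (k in seq_len(nrow(tms))) {
    if (tms$start[k] > pos) {
      seg[[length(seg) + 1L]] <- data.frame(label = side, start = pos,
                                            end = tms$start[k] - 1L, score = 1)
    }
    seg[[length(seg) + 1L]] <- data.frame(
      label = "membrane", start = tms$start[k], end = tms$end[k],
      score = max(score[tms$start[k]:tms$end[k]]))
    side <- if (side == "inside") "outside" else "inside"
    pos <- tms$end[k] + 1L
  }
  if (pos <= L) {
    seg[[length(seg) + 1L]] <- data.frame(label = side, start = pos, end = L,
                                          score = 1)
  }
  topology_model("query", do.call(rbind, seg))
}
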