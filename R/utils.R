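#' Apportion a total into integer counts following a vector of proportions
#'
#' Largest-remainder (Hamilton) apportionment: counts sum exactly to
#' `total` and each count differs from `total * proportion` by less than 1.
#' Ties on remainders are broken by position for determinism.
#'
#' @param total Non-negative integer total to distribute.
#' @param proportions Named non-negative numeric vector summing to 1.
#' @return Named integer vector summing to `total`.
#' @keywords internal
apportion_counts <- function(total, proportions) {
  stopifnot(total >= 0, all(proportions >= 0))
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1 (got ", sum(proportions), ")")
  }
  raw <- total * proportions
  base <- floor(raw)
  left <- total - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(base), names(proportions))
}

#' Validate an amino-acid sequence string
#'
#' @param x Character scalar.
#' @param what Label used in error messages.
#' @return `x`, invisibly, after validation.
#' @keywords internal
check_aa_sequence <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || nchar(x) == 0L) {
    stop(what, " must be a nonempty character scalar")
  }
  chars <- strsplit(x, "")[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0L) {
    stop("invalid residue symbol '", chars[bad[1]], "' at position ", bad[1],
         " of ", what)
  }
  invisible(x)
}

# Encode an amino-acid string as 0-based indices into a substitution-matrix
# row order.
encode_aa <- function(x, alphabet) {
  idx <- match(strsplit(x, "")[[1]], alphabet) - 1L
  if (anyNA(idx)) {
    stop("residue absent from substitution matrix at position ",
         which(is.na(idx))[1])
  }
  idx
}

# Deterministic sub-seed derivation, kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 10007L) %% 2147483647L
}
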