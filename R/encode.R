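# Encoding of supermatrices for parsimony scoring.
#
# Molecular states are bitmasks over {A,C,G,T}; IUPAC ambiguity codes
# expand to their state sets and '?'/'-'/'N' are full ambiguity by default
# (TNT-like treatment of gaps as missing).  Continuous observed values are
# degenerate intervals [v, v]; missing values are unbounded intervals.

IUPAC_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
                R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                B = 14L, D = 13L, H = 11L, V = 7L, N = 15L,
                "?" = 15L, "-" = 15L, X = 15L)

encode_bases <- function(chars, gap_as_state = FALSE) {
  bits <- IUPAC_BITS[toupper(chars)]
  if (gap_as_state) {
    bits[toupper(chars) == "-"] <- 16L
    bits[toupper(chars) %in% c("?", "N", "X")] <- 31L
    bits[is.na(bits)] <- 31L
  } else {
    bits[is.na(bits)] <- 15L
  }
  unname(bits)
}

# Rescale each column of a numeric matrix linearly to [0, 1] over the
# observed (non-missing) values; constant columns map to 0.
rescale_unit <- function(m) {
  apply(m, 2, function(v) {
    r <- range(v, na.rm = TRUE)
    if (!is.finite(r[1]) || r[2] == r[1]) return(ifelse(is.na(v), NA_real_, 0))
    (v - r[1]) / (r[2] - r[1])
  })
}

#' Encode a supermatrix for parsimony scoring
#'
#' Produces the internal representation the scorer and the tree search
#' consume: a bitmask matrix for molecular columns and interval bounds for
#' continuous columns.  Each continuous trait is linearly rescaled to
#' `[0, 1]` over observed taxa (making trait and nucleotide columns
#' commensurable) unless `rescale = FALSE`.
#'
#' @param sm A `supermatrix` (see [concatenate()]), or `NULL` alongside
#'   explicit matrices.
#' @param continuous_weight Non-negative weight multiplying the summed
#'   continuous length (default 1, i.e. weight 1 per rescaled column).
#' @param rescale Rescale continuous columns to `[0, 1]`? Default `TRUE`.
#' @param gap_as_state Treat `-` as a fifth state instead of missing?
#'   Default `FALSE`.
#' @return An object of class `encoded_matrix`.
#' @export
encode_supermatrix <- function(sm, continuous_weight = 1, rescale = TRUE,
                               gap_as_state = FALSE) {
  stopifnot(inherits(sm, "supermatrix"))
  if (continuous_weight < 0) stopf("continuous_weight must be non-negative")
  taxa <- sm$taxa
  mol <- NULL
  if (!is.null(sm$mol) && ncol(sm$mol)) {
    mol <- matrix(encode_bases(sm$mol, gap_as_state), nrow(sm$mol),
                  ncol(sm$mol), dimnames = list(taxa, NULL))
  }
  lo <- hi <- NULL
  if (!is.null(sm$cont) && ncol(sm$cont)) {
    vals <- if (rescale) rescale_unit(sm$cont) else sm$cont
    lo <- ifelse(is.na(vals), -Inf, vals)
    hi <- ifelse(is.na(vals), Inf, vals)
    rownames(lo) <- rownames(hi) <- taxa
  }
  structure(list(taxa = taxa, mol = mol, cont_lo = lo, cont_hi = hi,
                 continuous_weight = continuous_weight,
                 partitions = sm$partitions, gap_as_state = gap_as_state,
                 rescaled = rescale),
            class = "encoded_matrix")
}

# Reorder encoded rows to a utree's tip order (by label).
encoded_for_labels <- function(enc, labels) {
  bad <- setdiff(labels, enc$taxa)
  if (length(bad))
    stopf("taxa missing from matrix: %s", paste(bad, collapse = ", "))
  list(mol = if (!is.null(enc$mol)) enc$mol[labels, , drop = FALSE],
       lo = if (!is.null(enc$cont_lo)) enc$cont_lo[labels, , drop = FALSE],
       hi = if (!is.null(enc$cont_hi)) enc$cont_hi[labels, , drop = FALSE],
       w = enc$continuous_weight)
}
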