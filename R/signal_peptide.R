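# Rule-based signal-peptide caller. This is an explicit heuristic encoding
# of the classical tripartite architecture (charged n-region, hydrophobic
# h-region, small-residue cleavage context following the von Heijne -3/-1
# rule), not a re-implementation of any trained predictor. Constants below
# are fixed, documented choices.

SP_MIN_LENGTH <- 25L       # shortest sequence that can carry an SP + mature part
SP_NREGION_LEN <- 5L       # residues 1..5 form the n-region
SP_H_WINDOW <- 8L          # h-region window width (residues)
SP_H_RANGE <- c(3L, 20L)   # h-region windows must lie within residues 3..20
SP_H_MIN <- 1.6            # minimum mean Kyte-Doolittle hydropathy of a window
SP_CLEAVE_RANGE <- c(12L, 35L)  # allowed 1-based position of the SP's last residue
SP_SMALL <- c("A", "G", "S", "C", "T")  # -1/-3 small-residue set

#' Rule-based signal-peptide call
#'
#' Declares a cleavable N-terminal signal peptide when all of the following
#' hold: the sequence has at least 25 residues; the n-region (residues 1-5)
#' has non-negative net charge (K,R minus D,E); some 8-residue window within
#' residues 3-20 has mean Kyte-Doolittle hydropathy of at least 1.6 (the
#' maximum such mean is reported as `h_score`); and a cleavage position `p`
#' in 12-35 exists with small residues (A,G,S,C,T) at `p` and `p - 2`
#' (the von Heijne -1/-3 rule). `cleavage_pos` is the smallest qualifying
#' `p` at or after the end of the best-scoring h-region window.
#'
#' @param sequence amino-acid string.
#' @return List with `has_sp` (logical), `cleavage_pos` (1-based last residue
#'   of the signal peptide, 0 when `has_sp` is `FALSE`) and `h_score`.
#' @export
predict_signal_peptide <- function(sequence) {
  chars <- seq_chars(sequence)
  L <- length(chars)
  kd <- unname(KYTE_DOOLITTLE[chars])

  # h-region: best 8-mer fully inside residues 3..20
  h_score <- 0
  h_end <- NA_integer_
  lo <- SP_H_RANGE[1]
  hi <- min(SP_H_RANGE[2], L)
  if (hi - lo + 1L >= SP_H_WINDOW) {
    starts <- lo:(hi - SP_H_WINDOW + 1L)
    means <- vapply(starts, function(s) mean(kd[s:(s + SP_H_WINDOW - 1L)]), numeric(1))
    h_score <- max(means)
    h_end <- starts[which.max(means)] + SP_H_WINDOW - 1L
  }

  negative <- list(has_sp = FALSE, cleavage_pos = 0L, h_score = h_score)
  if (L < SP_MIN_LENGTH) return(negative)

  nreg <- chars[seq_len(SP_NREGION_LEN)]
  net <- sum(nreg %in% c("K", "R")) - sum(nreg %in% c("D", "E"))
  if (net < 0) return(negative)
  if (is.na(h_end) || h_score < SP_H_MIN) return(negative)

  p_lo <- max(SP_CLEAVE_RANGE[1], h_end)
  p_hi <- min(SP_CLEAVE_RANGE[2], L - 1L)  # mature part must be non-empty
  if (p_lo > p_hi) return(negative)
  for (p in p_lo:p_hi) {
    if (chars[p] %in% SP_SMALL && chars[p - 2L] %in% SP_SMALL) {
      return(list(has_sp = TRUE, cleavage_pos = p, h_score = h_score))
    }
  }
  negative
}

#' Signal-peptide calls for a record table
#'
#' @param records a protein record table.
#' @return Data frame with columns `record_id`, `has_sp`, `cleavage_pos`,
#'   `h_score`.
#' @export
signal_peptide_calls <- function(records) {
  calls <- lapply(records$sequence, predict_signal_peptide)
  data.frame(
    record_id = records$id,
    has_sp = vapply(calls, `[[`, logical(1), "has_sp"),
    cleavage_pos = vapply(calls, function(x) as.integer(x$cleavage_pos), integer(1)),
    h_score = vapply(calls, `[[`, numeric(1), "h_score"),
    stringsAsFactors = FALSE
  )
}
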