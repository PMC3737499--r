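# LU / three-finger cysteine-scaffold detection. The Ly-6/uPAR (LU) domain
# is a compact 80-90 residue fold with ten conserved cysteines forming five
# disulfide bridges; three-finger toxin variants carry 3-4 bridges. The
# detector looks for a compact cysteine-bounded window holding that cysteine
# complement; defaults span both variants (min_cys 8 admits 4-bridge TFPs).

#' Disulfide-bridge capacity of a cysteine count
#'
#' Bridge capacity is `floor(n_cys / 2)`: ten conserved cysteines support the
#' five disulfide bridges of an LU domain. No pairing map is implied.
#'
#' @param n_cys non-negative cysteine count.
#' @return Integer bridge count.
#' @export
count_bridges <- function(n_cys) {
  if (any(n_cys < 0)) stop("'n_cys' must be non-negative")
  as.integer(n_cys %/% 2)
}

#' Detect LU/three-finger-like cysteine frameworks
#'
#' Scans every window that starts and ends on a cysteine, keeping windows
#' whose length lies in `[min_len, max_len]`, whose cysteine count lies in
#' `[min_cys, max_cys]`, and which contain no internal cysteine-free stretch
#' longer than `max_cys_free` residues. Overlapping candidates are reduced to
#' the one with maximal cysteine count, then minimal length, then leftmost
#' start; the survivors are mutually non-overlapping.
#'
#' @param sequence amino-acid string.
#' @param min_cys,max_cys cysteine-count bounds for a window.
#' @param min_len,max_len window length bounds (residues).
#' @param max_cys_free longest allowed internal cysteine-free stretch.
#' @return Data frame with columns `window_start`, `window_end` (1-based
#'   inclusive), `n_cys`, `n_bridges`, `density`; zero rows when nothing
#'   matches.
#' @export
detect_lu_scaffold <- function(sequence, min_cys = 8L, max_cys = 12L,
                               min_len = 60L, max_len = 95L,
                               max_cys_free = 30L) {
  if (min_len > max_len) stop("'min_len' must not exceed 'max_len'")
  if (min_cys < 2L) stop("'min_cys' must be at least 2")
  chars <- seq_chars(sequence)
  cpos <- which(chars == "C")
  empty <- data.frame(
    window_start = integer(0), window_end = integer(0),
    n_cys = integer(0), n_bridges = integer(0), density = numeric(0)
  )
  if (length(cpos) < min_cys) return(empty)

  cand <- list()
  for (i in seq_along(cpos)) {
    for (j in seq_along(cpos)) {
      if (j <= i) next
      len <- cpos[j] - cpos[i] + 1L
      if (len < min_len || len > max_len) next
      ncys <- j - i + 1L
      if (ncys < min_cys || ncys > max_cys) next
      if (max(diff(cpos[i:j])) - 1L > max_cys_free) next
      cand[[length(cand) + 1L]] <- c(start = cpos[i], end = cpos[j], n_cys = ncys)
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- as.data.frame(cand)
  cand$len <- cand$end - cand$start + 1L

  # greedy overlap reduction: maximal n_cys, then minimal length, then leftmost
  cand <- cand[order(-cand$n_cys, cand$len, cand$start), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    ok <- TRUE
    if (any(keep)) {
      kept <- cand[keep, , drop = FALSE]
      ok <- all(cand$end[k] < kept$start | cand$start[k] > kept$end)
    }
    keep[k] <- ok
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  data.frame(
    window_start = as.integer(out$start),
    window_end = as.integer(out$end),
    n_cys = as.integer(out$n_cys),
    n_bridges = count_bridges(out$n_cys),
    density = out$n_cys / out$len
  )
}

#' Scaffold scan over a record table
#'
#' Runs [detect_lu_scaffold()] on every record and reports whether any window
#' matched, plus the best match (first row of the reduced match set).
#'
#' @param records a protein record table.
#' @param ... passed to [detect_lu_scaffold()].
#' @return Data frame with columns `record_id`, `scaffold_matched`,
#'   `window_start`, `window_end`, `n_cys`, `n_bridges`, `density`
#'   (NA for unmatched records).
#' @export
scaffold_calls <- function(records, ...) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    m <- detect_lu_scaffold(records$sequence[i], ...)
    if (nrow(m) == 0L) {
      data.frame(
        record_id = records$id[i], scaffold_matched = FALSE,
        window_start = NA_integer_, window_end = NA_integer_,
        n_cys = NA_integer_, n_bridges = NA_integer_, density = NA_real_,
        stringsAsFactors = FALSE
      )
    } else {
      best <- m[which.max(m$n_cys), , drop = FALSE][1, ]
      data.frame(
        record_id = records$id[i], scaffold_matched = TRUE,
        window_start = best$window_start, window_end = best$window_end,
        n_cys = best$n_cys, n_bridges = best$n_bridges, density = best$density,
        stringsAsFactors = FALSE
      )
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      record_id = character(0), scaffold_matched = logical(0),
      window_start = integer(0), window_end = integer(0),
      n_cys = integer(0), n_bridges = integer(0), density = numeric(0)
    )
  }
  rownames(out) <- NULL
  out
}
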