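# Per-residue scales. Kyte & Doolittle (1982) hydropathy; Zimmerman,
# Eliezer & Simha (1968) polarity. X (unknown residue) contributes 0.
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0
)
ZIMMERMAN_POLARITY <- c(
  A = 0.00, R = 52.00, N = 3.38, D = 49.70, C = 1.48, Q = 3.53, E = 49.90,
  G = 0.00, H = 51.60, I = 0.13, L = 0.13, K = 49.50, M = 1.43, F = 0.35,
  P = 1.58, S = 1.67, T = 1.66, W = 2.10, Y = 1.61, V = 0.13, X = 0
)

FEATURE_CATALOGUE_VERSION <- "1"

seq_chars <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      !nzchar(sequence)) {
    stop("'sequence' must be a single non-empty string")
  }
  strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
}

# All residue-class fractions use the number of non-X residues as denominator
# so that unknown residues neither count for nor against any class.
n_known <- function(chars) max(sum(chars != "X"), 1L)

#' Cysteine abundance and spacing features
#'
#' Counts cysteines and summarises the gaps between consecutive cysteines
#' (differences of 1-based positions). "Spaced" cysteine pairs are consecutive
#' cysteines separated by a gap of at least `spaced_gap_min` (adjacent CC and
#' CxC motifs are treated as scaffold-internal, not spaced). With fewer than
#' two cysteines all gap statistics are 0.
#'
#' @param sequence amino-acid string.
#' @param spaced_gap_min minimum consecutive-cysteine gap counted as "spaced".
#' @return Named numeric vector: `cys_count`, `cys_fraction`, `n_gaps`,
#'   `gap_min`, `gap_max`, `gap_mean`, `spaced_cys_pairs`, `has_cterm_cys`
#'   (cysteine within the final 3 residues).
#' @export
cysteine_features <- function(sequence, spaced_gap_min = 3L) {
  chars <- seq_chars(sequence)
  pos <- which(chars == "C")
  gaps <- if (length(pos) >= 2L) diff(pos) else numeric(0)
  c(
    cys_count = length(pos),
    cys_fraction = length(pos) / n_known(chars),
    n_gaps = length(gaps),
    gap_min = if (length(gaps)) min(gaps) else 0,
    gap_max = if (length(gaps)) max(gaps) else 0,
    gap_mean = if (length(gaps)) mean(gaps) else 0,
    spaced_cys_pairs = sum(gaps >= spaced_gap_min),
    has_cterm_cys = as.numeric(any(pos > length(chars) - 3L))
  )
}

#' Charged-residue features
#'
#' @param sequence amino-acid string.
#' @return Named numeric vector: `basic_fraction` (K,R), `acidic_fraction`
#'   (D,E), `his_fraction`, `net_charge` (count K,R minus count D,E) and
#'   `charged_fraction`.
#' @export
charge_features <- function(sequence) {
  chars <- seq_chars(sequence)
  nk <- n_known(chars)
  basic <- sum(chars %in% c("K", "R"))
  acidic <- sum(chars %in% c("D", "E"))
  c(
    basic_fraction = basic / nk,
    acidic_fraction = acidic / nk,
    his_fraction = sum(chars == "H") / nk,
    net_charge = basic - acidic,
    charged_fraction = (basic + acidic) / nk
  )
}

windowed_means <- function(values, window) {
  n <- length(values)
  if (n < window) return(mean(values))
  cs <- c(0, cumsum(values))
  (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
}

profile_block <- function(values, window, prefix) {
  wm <- windowed_means(values, window)
  out <- c(
    mean(wm),
    if (length(wm) > 1L) stats::sd(wm) else 0,
    max(wm),
    min(wm),
    mean(values[seq_len(min(20L, length(values)))]),
    if (length(values) > 20L) mean(values[21:length(values)]) else 0
  )
  names(out) <- paste0(prefix, c("_mean", "_sd", "_max", "_min", "_nterm_mean", "_mature_mean"))
  out
}

#' Polarity and hydropathy profile features
#'
#' Maps the sequence onto two fixed per-residue scales (Kyte-Doolittle
#' hydropathy, `kd_*`; Zimmerman polarity, `zim_*`), averages each in sliding
#' windows of width `window` (the whole sequence is a single window when
#' shorter), and summarises each windowed profile by mean, sd, max and min,
#' plus the unwindowed mean over the N-terminal 20 residues (`*_nterm_mean`;
#' whole sequence if shorter) and over residues 21..end (`*_mature_mean`, 0 if
#' absent).
#'
#' @param sequence amino-acid string.
#' @param window sliding-window width in residues.
#' @return Named numeric vector of 12 profile summaries.
#' @export
polarity_profile <- function(sequence, window = 5L) {
  if (!is.numeric(window) || length(window) != 1L || window < 1) {
    stop("'window' must be a single integer >= 1")
  }
  chars <- seq_chars(sequence)
  c(
    profile_block(unname(KYTE_DOOLITTLE[chars]), window, "kd"),
    profile_block(unname(ZIMMERMAN_POLARITY[chars]), window, "zim")
  )
}

#' Global composition features
#'
#' Frequencies of the 20 standard residues (X excluded from numerator and
#' denominator) plus the aromatic (F,W,Y) and small (A,G,S,T) class fractions.
#'
#' @param sequence amino-acid string.
#' @return Named numeric vector: `freq_A` .. `freq_Y`, `aromatic_fraction`,
#'   `small_fraction`.
#' @export
composition_features <- function(sequence) {
  chars <- seq_chars(sequence)
  nk <- n_known(chars)
  counts <- vapply(AA_STANDARD, function(a) sum(chars == a), numeric(1))
  freqs <- counts / nk
  names(freqs) <- paste0("freq_", AA_STANDARD)
  c(
    freqs,
    aromatic_fraction = sum(counts[c("F", "W", "Y")]) / nk,
    small_fraction = sum(counts[c("A", "G", "S", "T")]) / nk
  )
}

#' Names of the versioned feature catalogue
#'
#' The fixed, ordered list of features produced by [extract_features()].
#' Every feature matrix in a dataset shares this order; the catalogue is
#' versioned so that serialized models can refuse mismatched inputs.
#'
#' @return Character vector of feature names, with the catalogue version in
#'   attribute `"version"`.
#' @export
feature_catalogue <- function() {
  nm <- c(
    names(cysteine_features("C")),
    names(charge_features("A")),
    names(polarity_profile("A")),
    names(composition_features("A")),
    "length", "log_length"
  )
  attr(nm, "version") <- FEATURE_CATALOGUE_VERSION
  nm
}

#' Extract the full feature vector for one sequence
#'
#' Deterministic concatenation of the cysteine, charge, polarity-profile and
#' composition blocks plus `length` and `log_length` (natural log).
#'
#' @param sequence amino-acid string.
#' @param window polarity-profile window width.
#' @param spaced_gap_min see [cysteine_features()].
#' @return Named numeric vector in [feature_catalogue()] order.
#' @export
extract_features <- function(sequence, window = 5L, spaced_gap_min = 3L) {
  n <- nchar(sequence)
  c(
    cysteine_features(sequence, spaced_gap_min = spaced_gap_min),
    charge_features(sequence),
    polarity_profile(sequence, window = window),
    composition_features(sequence),
    length = n,
    log_length = log(n)
  )
}

#' Feature matrix for a record table
#'
#' @param records a protein record table (see [protein_records()]).
#' @param window polarity-profile window width.
#' @return Numeric matrix, one row per record (rownames = record ids),
#'   columns in [feature_catalogue()] order.
#' @export
feature_matrix <- function(records, window = 5L) {
  nm <- as.character(feature_catalogue())
  m <- matrix(
    0, nrow = nrow(records), ncol = length(nm),
    dimnames = list(records$id, nm)
  )
  for (i in seq_len(nrow(records))) {
    m[i, ] <- extract_features(records$sequence[i], window = window)
  }
  m
}

#' Write or read a feature matrix as TSV
#'
#' Rows are records, columns are named features; the first column holds the
#' record id.
#'
#' @param features numeric feature matrix with rownames.
#' @param path file path.
#' @return `path` (write) or the feature matrix (read).
#' @export
write_feature_tsv <- function(features, path) {
  df <- data.frame(record_id = rownames(features), features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$record_id
  m
}
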