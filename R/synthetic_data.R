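# Seeded synthetic proteomes and gene tables with planted structure.
#
# Positives emulate short secreted cysteine-rich proteins: an optional
# signal-peptide prefix followed by a mature domain with a planted
# 10-cysteine LU-like scaffold and a K/R-enriched background composition.
# Decoys cover the failure modes a proteome scan meets: composition-matched
# shuffles (destroy cysteine spacing, keep composition), cysteine-poor
# randoms, keratin-like low-complexity repeats, and long sequences that the
# length filter must remove. Generators are pure functions of (config, seed).

# background amino-acid frequencies (approximate vertebrate proteome averages)
BG_FREQ <- c(
  A = 0.074, C = 0.025, D = 0.054, E = 0.054, F = 0.047, G = 0.074,
  H = 0.026, I = 0.068, K = 0.058, L = 0.099, M = 0.025, N = 0.045,
  P = 0.039, Q = 0.034, R = 0.052, S = 0.057, T = 0.051, V = 0.073,
  W = 0.013, Y = 0.032
)

#' Simulation configuration
#'
#' Defaults define the study conditions for the synthetic screen: 500
#' positives and 500 decoys, positives of 60-119 residues carrying a
#' 10-cysteine scaffold in a mature domain of 80 +/- 5 residues, a
#' signal-peptide prefix on 90% of positives, K/R frequencies multiplied by
#' 1.5 in the positive background, and an even mix of the four decoy kinds.
#'
#' @param seed integer seed; generators are pure functions of the config.
#' @param n_pos,n_neg numbers of positives and decoys.
#' @param pos_len length range of positives (residues).
#' @param decoy_len length range of decoys.
#' @param n_scaffold_cys cysteines planted in each positive's scaffold.
#' @param scaffold_gap_range range each inter-cysteine gap is drawn from
#'   (conserved frameworks have bounded, fairly regular spacing; a shuffle
#'   destroys it).
#' @param scaffold_len mature-domain length range (residues).
#' @param sp_fraction fraction of positives given a signal-peptide prefix.
#' @param decoy_weights mixing weights of the decoy kinds (must sum to 1).
#' @param charge_multiplier K/R frequency multiplier in positive backgrounds.
#' @param hydrophobic_multiplier multiplier on strongly hydrophobic residues
#'   (I,L,V,F,M,W) in positive mature domains; disulfide-stabilized secreted
#'   domains are surface-exposed and hydrophilic, so the default < 1.
#' @param random_cys_freq per-residue cysteine probability in random decoys.
#' @param fragment_fraction fraction of decoys marked as fragments.
#' @return A validated configuration list.
#' @export
sim_config <- function(seed = 1L, n_pos = 500L, n_neg = 500L,
                       pos_len = c(60L, 119L), decoy_len = c(30L, 300L),
                       n_scaffold_cys = 10L,
                       scaffold_gap_range = c(5L, 13L),
                       scaffold_len = c(75L, 85L),
                       sp_fraction = 0.9,
                       decoy_weights = c(shuffled = 0.25, random = 0.25,
                                         keratin_like = 0.25, long = 0.25),
                       charge_multiplier = 1.5,
                       hydrophobic_multiplier = 0.6,
                       random_cys_freq = 0.005,
                       fragment_fraction = 0.02) {
  if (n_pos < 0 || n_neg < 0) stop("counts must be >= 0")
  if (abs(sum(decoy_weights) - 1) > 1e-8) stop("decoy_weights must sum to 1")
  if (sp_fraction < 0 || sp_fraction > 1) stop("sp_fraction must be in [0,1]")
  if (scaffold_len[2] > pos_len[2]) {
    stop("scaffold template longer than the positive length range allows")
  }
  list(
    seed = as.integer(seed), n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
    pos_len = as.integer(pos_len), decoy_len = as.integer(decoy_len),
    n_scaffold_cys = as.integer(n_scaffold_cys),
    scaffold_gap_range = as.integer(scaffold_gap_range),
    scaffold_len = as.integer(scaffold_len),
    sp_fraction = sp_fraction, decoy_weights = decoy_weights,
    charge_multiplier = charge_multiplier,
    hydrophobic_multiplier = hydrophobic_multiplier,
    random_cys_freq = random_cys_freq,
    fragment_fraction = fragment_fraction
  )
}

sample_background <- function(n, freq) {
  sample(names(freq), n, replace = TRUE, prob = freq)
}

positive_background_freq <- function(config) {
  f <- BG_FREQ[setdiff(names(BG_FREQ), "C")]
  f[c("K", "R")] <- f[c("K", "R")] * config$charge_multiplier
  f[c("I", "L", "V", "F", "M", "W")] <-
    f[c("I", "L", "V", "F", "M", "W")] * config$hydrophobic_multiplier
  f / sum(f)
}

# SP prefix: M + 2 charged + 9 hydrophobic + small-residue cleavage context.
# Satisfies the rule-based caller by construction (n-region net charge +2,
# h-region of hydrophobics within residues 3-20, -1/-3 small residues at
# position 15/13).
sp_prefix <- function() {
  paste0(
    "M",
    paste(sample(c("K", "R"), 2, replace = TRUE), collapse = ""),
    paste(sample(c("L", "I", "V", "F"), 9, replace = TRUE), collapse = ""),
    sample(c("A", "G", "S", "T"), 1),
    sample(c("A", "S"), 1),
    sample(c("A", "G", "S", "T"), 1)
  )
}

# Draw the scaffold template: n_cys - 1 inter-cysteine gaps from the
# configured range, resampled until the cysteine-bounded window fills
# 70-83 residues (inside the detector's window bounds and the mature
# domain's length budget).
scaffold_template <- function(config) {
  rng <- config$scaffold_gap_range
  for (try in 1:500) {
    gaps <- sample(rng[1]:rng[2], config$n_scaffold_cys - 1L, replace = TRUE)
    wlen <- sum(gaps) + 1L
    if (wlen >= 70L && wlen <= 83L) return(gaps)
  }
  stop("scaffold template longer than the mature-domain budget; ",
       "loosen 'scaffold_gap_range' or 'scaffold_len'")
}

#' Generate one synthetic positive
#'
#' Draws from the current RNG stream (seed it for reproducibility). The
#' mature domain carries the planted cysteine scaffold and, with probability
#' `sp_fraction`, is preceded by a signal-peptide prefix.
#'
#' @param config a [sim_config()].
#' @return List with `sequence`, `has_sp` and `mature_start`.
#' @export
generate_positive <- function(config) {
  gaps <- scaffold_template(config)
  wlen <- sum(gaps) + 1L
  first_c <- sample(1:3, 1)
  cys <- first_c + cumsum(c(0L, gaps))
  lo <- max(config$scaffold_len[1], first_c - 1L + wlen)
  tail_len <- sample(0:(config$scaffold_len[2] - lo), 1)
  mature_len <- max(config$scaffold_len[1], first_c - 1L + wlen + tail_len)
  chars <- sample_background(mature_len, positive_background_freq(config))
  chars[cys] <- "C"
  mature <- paste(chars, collapse = "")
  if (stats::runif(1) < config$sp_fraction) {
    prefix <- sp_prefix()
    list(sequence = paste0(prefix, mature), has_sp = TRUE,
         mature_start = nchar(prefix) + 1L)
  } else {
    list(sequence = mature, has_sp = FALSE, mature_start = 1L)
  }
}

#' Generate one synthetic decoy
#'
#' Kinds: `shuffled` (residue permutation of a freshly generated positive;
#' identical composition, destroyed spacing), `random` (near cysteine-free
#' background), `keratin_like` (G/S-rich low-complexity repeats, no
#' cysteines) and `long` (background sequence of >= 150 residues, removed by
#' the length filter).
#'
#' @param config a [sim_config()].
#' @param kind decoy kind.
#' @return List with `sequence` and `kind`.
#' @export
generate_decoy <- function(config, kind = c("shuffled", "random",
                                            "keratin_like", "long")) {
  kind <- match.arg(kind)
  seqn <- switch(kind,
    shuffled = {
      src <- generate_positive(config)
      paste(sample(strsplit(src$sequence, "")[[1]]), collapse = "")
    },
    random = {
      len <- sample(max(30L, config$decoy_len[1]):140L, 1)
      f <- BG_FREQ
      f["C"] <- config$random_cys_freq
      f <- f / sum(f)
      paste(sample_background(len, f), collapse = "")
    },
    keratin_like = {
      len <- sample(40:119, 1)
      unit <- c("G", "G", "S", "S", "Y", "G", "S", "G", "S", "F")
      chars <- rep(unit, length.out = len)
      swap <- stats::runif(len) < 0.1
      chars[swap] <- sample(c("G", "S", "A", "P", "Y", "F"), sum(swap), replace = TRUE)
      paste(chars, collapse = "")
    },
    long = {
      len <- sample(150:max(150L, config$decoy_len[2]), 1)
      paste(sample_background(len, BG_FREQ), collapse = "")
    }
  )
  list(sequence = seqn, kind = kind)
}

#' Generate a synthetic proteome with ground-truth labels
#'
#' Seeds the RNG from `config$seed` and generates `n_pos` positives and
#' `n_neg` decoys (kinds drawn by `decoy_weights`); a `fragment_fraction` of
#' decoys is marked as fragments. Ground truth is returned as a separate
#' table, never encoded in ids or descriptions, so label leakage into
#' features is impossible.
#'
#' @param config a [sim_config()].
#' @return List with `records` (protein record table) and `truth` (data frame
#'   `id`, `label` in positive/decoy, `kind`, `has_sp`).
#' @export
generate_proteome <- function(config) {
  set.seed(config$seed)
  n <- config$n_pos + config$n_neg
  ids <- sprintf("SYN%05d", seq_len(n))
  sequences <- character(n)
  label <- c(rep("positive", config$n_pos), rep("decoy", config$n_neg))
  kind <- character(n)
  has_sp <- logical(n)
  for (i in seq_len(config$n_pos)) {
    p <- generate_positive(config)
    sequences[i] <- p$sequence
    kind[i] <- "positive"
    has_sp[i] <- p$has_sp
  }
  kinds <- names(config$decoy_weights)
  for (i in seq_len(config$n_neg)) {
    k <- sample(kinds, 1, prob = config$decoy_weights)
    d <- generate_decoy(config, k)
    sequences[config$n_pos + i] <- d$sequence
    kind[config$n_pos + i] <- k
  }
  desc <- rep("synthetic protein", n)
  frag <- rep(FALSE, n)
  if (config$n_neg > 0 && config$fragment_fraction > 0) {
    idx <- config$n_pos + which(stats::runif(config$n_neg) < config$fragment_fraction)
    frag[idx] <- TRUE
    desc[idx] <- "synthetic protein (Fragment)"
  }
  list(
    records = protein_records(ids, sequences, desc, frag),
    truth = data.frame(id = ids, label = label, kind = kind, has_sp = has_sp,
                       stringsAsFactors = FALSE)
  )
}

#' Generate a gene table with planted clusters
#'
#' Places `n_clusters` runs of `genes_per_cluster` consecutive genes with
#' intra-cluster gaps of at most `cluster_gap_nt`, plus singletons at least
#' 10 x `cluster_gap_nt` away from any cluster, cycling over `n_chromosomes`
#' chromosomes. Ground-truth cluster labels are returned alongside.
#'
#' @param seed integer seed.
#' @param n_clusters,genes_per_cluster planted cluster structure.
#' @param cluster_gap_nt maximum intra-cluster inter-gene gap (nt).
#' @param n_singletons isolated genes.
#' @param n_chromosomes chromosomes to cycle over.
#' @return List with `loci` (gene table, 1-based inclusive) and `truth`
#'   (data frame `gene`, `cluster` with `NA` for singletons).
#' @export
generate_gene_table <- function(seed = 1L, n_clusters = 2L,
                                genes_per_cluster = 5L,
                                cluster_gap_nt = 50000L,
                                n_singletons = 5L, n_chromosomes = 3L) {
  if (any(c(n_clusters, genes_per_cluster, n_singletons, n_chromosomes) < 0)) {
    stop("counts must be >= 0")
  }
  set.seed(seed)
  max_coord <- 2e8
  cursor <- stats::setNames(rep(1e6, n_chromosomes), paste0("chr", seq_len(n_chromosomes)))
  spacing <- 20L * cluster_gap_nt  # isolation between planted entities
  rows <- list()
  truth <- list()
  gi <- 0L
  place_gene <- function(chrom, start) {
    len <- sample(2000:6000, 1)
    list(start = start, end = start + len - 1L)
  }
  for (ci in seq_len(n_clusters)) {
    chrom <- names(cursor)[(ci - 1L) %% n_chromosomes + 1L]
    pos <- cursor[[chrom]] + spacing
    for (g in seq_len(genes_per_cluster)) {
      gi <- gi + 1L
      gene <- sprintf("SGENE%03d", gi)
      loc <- place_gene(chrom, pos)
      rows[[gi]] <- data.frame(
        gene = gene, chromosome = chrom, start = loc$start, end = loc$end,
        strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE
      )
      truth[[gi]] <- data.frame(gene = gene, cluster = sprintf("T%02d", ci),
                                stringsAsFactors = FALSE)
      pos <- loc$end + 1L + sample(100:cluster_gap_nt, 1)
    }
    cursor[[chrom]] <- pos
    if (cursor[[chrom]] > max_coord) stop("chromosome too crowded to place clusters")
  }
  for (si in seq_len(n_singletons)) {
    chrom <- names(cursor)[(si - 1L) %% n_chromosomes + 1L]
    pos <- cursor[[chrom]] + spacing
    gi <- gi + 1L
    gene <- sprintf("SGENE%03d", gi)
    loc <- place_gene(chrom, pos)
    rows[[gi]] <- data.frame(
      gene = gene, chromosome = chrom, start = loc$start, end = loc$end,
      strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE
    )
    truth[[gi]] <- data.frame(gene = gene, cluster = NA_character_,
                              stringsAsFactors = FALSE)
    cursor[[chrom]] <- loc$end
    if (cursor[[chrom]] > max_coord) stop("chromosome too crowded to place singletons")
  }
  loci <- if (gi > 0) do.call(rbind, rows) else empty_loci()
  truth <- if (gi > 0) do.call(rbind, truth) else
    data.frame(gene = character(0), cluster = character(0))
  list(loci = loci, truth = truth)
}

#' Write a gene table as BED
#'
#' Converts the 1-based inclusive loci to BED's 0-based half-open convention.
#'
#' @param loci a gene table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(loci, path) {
  bed <- data.frame(
    chrom = loci$chromosome,
    chromStart = loci$start - 1L,
    chromEnd = loci$end,
    name = loci$gene,
    score = 0L,
    strand = loci$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
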