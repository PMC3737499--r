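# Chromosomal paralog-cluster detection. Tandemly duplicated TOLIP genes
# (e.g. the ANLP cluster on mouse 9qA4 and the Ly-6 locus on chromosome 15)
# form runs of loci within a bounded genomic distance; clusters are chained
# by single linkage on inter-gene gaps. Coordinates are stored 1-based
# inclusive; BED input (0-based half-open) is converted on ingestion.

#' @importFrom GenomicRanges GRanges reduce findOverlaps
#' @importFrom IRanges IRanges
NULL

validate_loci <- function(loci) {
  need <- c("gene", "chromosome", "start", "end", "strand")
  if (!all(need %in% names(loci))) {
    stop("gene table requires columns: ", paste(need, collapse = ", "))
  }
  if (any(!nzchar(loci$chromosome))) stop("empty chromosome name")
  if (any(loci$start > loci$end)) {
    stop("start > end for gene(s): ",
         paste(loci$gene[loci$start > loci$end], collapse = ", "))
  }
  if (!all(loci$strand %in% c("+", "-"))) {
    stop("unknown strand symbol(s): ",
         paste(unique(loci$strand[!loci$strand %in% c("+", "-")]), collapse = ", "))
  }
  loci
}

empty_loci <- function() {
  data.frame(
    gene = character(0), chromosome = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    stringsAsFactors = FALSE
  )
}

#' Read a gene coordinate table
#'
#' Reads gene loci from BED (6+ columns; 0-based half-open, converted to
#' 1-based inclusive on ingestion) or from a TSV already in 1-based inclusive
#' coordinates with columns `gene`, `chromosome`, `start`, `end`, `strand`.
#'
#' @param path input file path.
#' @param format `"bed"` or `"tsv"`.
#' @return Data frame of validated loci (1-based inclusive coordinates).
#' @export
read_gene_table <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read gene table: ", path)
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    if (length(gr) == 0L) return(empty_loci())
    strand <- as.character(GenomicRanges::strand(gr))
    loci <- data.frame(
      gene = if (!is.null(gr$name)) gr$name else paste0("gene", seq_along(gr)),
      chromosome = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = strand,
      stringsAsFactors = FALSE
    )
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    if (nrow(tab) == 0L) return(empty_loci())
    loci <- data.frame(
      gene = as.character(tab$gene),
      chromosome = as.character(tab$chromosome),
      start = as.integer(tab$start),
      end = as.integer(tab$end),
      strand = as.character(tab$strand),
      stringsAsFactors = FALSE
    )
  }
  validate_loci(loci)
}

#' Group loci into proximity clusters
#'
#' Per chromosome, loci are chained by single linkage: two loci link when the
#' gap between them (`next$start - prev$end - 1`, 0 if they overlap) is at
#' most `max_gap` nucleotides. Chains with at least `min_genes` members are
#' reported. Strand is ignored (tandem paralog clusters mix orientations).
#'
#' @param loci a gene table (1-based inclusive coordinates).
#' @param max_gap maximum linking gap in nucleotides.
#' @param min_genes minimum cluster size.
#' @return Data frame sorted by chromosome then start, with columns
#'   `cluster_id`, `chromosome`, `n_genes`, `start`, `end`, `span_nt`
#'   (`max(end) - min(start)`) and a list column `members` of member gene
#'   names ordered by start.
#' @export
find_clusters <- function(loci, max_gap = 200000L, min_genes = 3L) {
  if (max_gap < 0) stop("'max_gap' must be >= 0")
  if (min_genes < 1) stop("'min_genes' must be >= 1")
  empty <- data.frame(
    cluster_id = character(0), chromosome = character(0),
    n_genes = integer(0), start = integer(0), end = integer(0),
    span_nt = integer(0), stringsAsFactors = FALSE
  )
  empty$members <- list()
  if (nrow(loci) == 0L) return(empty)
  validate_loci(loci)

  gr <- GenomicRanges::GRanges(
    loci$chromosome, IRanges::IRanges(loci$start, loci$end)
  )
  merged <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1L)
  hits <- GenomicRanges::findOverlaps(gr, merged)
  group <- integer(nrow(loci))
  group[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)

  keep <- which(tabulate(group, nbins = length(merged)) >= min_genes)
  if (!length(keep)) return(empty)

  rows <- lapply(keep, function(g) {
    mem <- loci[group == g, , drop = FALSE]
    mem <- mem[order(mem$start, mem$end, mem$gene), , drop = FALSE]
    df <- data.frame(
      chromosome = mem$chromosome[1],
      n_genes = nrow(mem),
      start = min(mem$start),
      end = max(mem$end),
      span_nt = max(mem$end) - min(mem$start),
      stringsAsFactors = FALSE
    )
    df$members <- list(mem$gene)
    df
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chromosome, out$start), , drop = FALSE]
  out <- cbind(
    cluster_id = sprintf("C%03d", seq_len(nrow(out))),
    out, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Genomic span of a set of loci
#'
#' @param loci non-empty gene table (the members of one cluster).
#' @return `max(end) - min(start)` in nucleotides.
#' @export
cluster_span <- function(loci) {
  if (nrow(loci) == 0L) stop("cluster is empty")
  max(loci$end) - min(loci$start)
}

#' Write clusters to TSV
#'
#' @param clusters output of [find_clusters()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_clusters_tsv <- function(clusters, path) {
  flat <- clusters
  flat$members <- vapply(clusters$members, paste, character(1), collapse = ",")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header("cluster_id\tchromosome\tn_genes\tmin_start\tmax_end\tspan_nt\tmembers"), con)
  utils::write.table(
    flat[, c("cluster_id", "chromosome", "n_genes", "start", "end", "span_nt", "members")],
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
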