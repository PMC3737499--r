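#' @importFrom Biostrings readAAStringSet writeXStringSet AAStringSet
NULL

# Residue alphabet accepted on ingestion. X is tolerated (unknown residue,
# ignored by residue-class fractions); B/Z/U/O are rejected so that every
# feature has an unambiguous definition.
AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
AA_ALLOWED <- c(AA_STANDARD, "X")

#' Assemble a validated protein record table
#'
#' The package represents a protein collection as a plain data frame with one
#' row per sequence and columns `id`, `description`, `sequence`, `is_fragment`
#' and `length`. This constructor validates residues, uppercases sequences and
#' enforces unique non-empty identifiers.
#'
#' @param id character vector of unique accessions.
#' @param sequence character vector of amino-acid sequences (20 standard
#'   residues plus `X`).
#' @param description character vector of free-text descriptions.
#' @param is_fragment logical; whether the entry is annotated as a fragment.
#' @return A `data.frame` with columns `id`, `description`, `sequence`,
#'   `is_fragment`, `length`.
#' @export
protein_records <- function(id, sequence, description = "", is_fragment = NULL) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  description <- rep_len(as.character(description), length(id))
  if (is.null(is_fragment)) {
    is_fragment <- grepl("(fragment)", tolower(description), fixed = TRUE)
  }
  is_fragment <- rep_len(as.logical(is_fragment), length(id))
  if (length(sequence) != length(id)) {
    stop("'id' and 'sequence' must have the same length")
  }
  if (any(!nzchar(id)) || anyNA(id)) {
    stop("record ids must be non-empty")
  }
  if (anyDuplicated(id)) {
    stop("duplicate record ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(sequence))) {
    stop("record(s) without sequence: ", paste(id[!nzchar(sequence)], collapse = ", "))
  }
  bad <- grepl(sprintf("[^%s]", paste(AA_ALLOWED, collapse = "")), sequence)
  if (any(bad)) {
    stop(
      "non-amino-acid characters (only the 20 standard residues plus X are ",
      "accepted) in record(s): ", paste(id[bad], collapse = ", ")
    )
  }
  data.frame(
    id = id,
    description = description,
    sequence = sequence,
    is_fragment = is_fragment,
    length = nchar(sequence),
    stringsAsFactors = FALSE
  )
}

empty_records <- function() {
  protein_records(character(0), character(0), character(0), logical(0))
}

parse_fasta_header <- function(header) {
  first <- sub("\\s.*$", "", header)
  desc <- sub("^\\S+\\s*", "", header)
  # UniProt dialect db|ACC|NAME: the accession is the second pipe token
  toks <- strsplit(first, "|", fixed = TRUE)[[1]]
  id <- if (length(toks) >= 2 && nzchar(toks[2])) toks[2] else first
  list(id = id, description = desc)
}

#' Read protein sequences from FASTA
#'
#' Reads a FASTA file into a protein record table. UniProt-style headers
#' (`db|ACC|NAME description`) are recognised and the accession is used as the
#' id; otherwise the first whitespace-delimited header token is the id.
#' Entries whose description contains the token `(Fragment)`
#' (case-insensitive) are flagged `is_fragment`.
#'
#' @param path path to a FASTA file.
#' @return A protein record table (see [protein_records()]); an empty file
#'   yields a zero-row table.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) return(empty_records())
  if (any(Biostrings::width(aa) == 0L)) {
    stop(
      "FASTA header(s) without any sequence line: ",
      paste(names(aa)[Biostrings::width(aa) == 0L], collapse = ", ")
    )
  }
  parsed <- lapply(names(aa), parse_fasta_header)
  protein_records(
    id = vapply(parsed, `[[`, character(1), "id"),
    sequence = as.character(aa),
    description = vapply(parsed, `[[`, character(1), "description")
  )
}

#' Write protein records to FASTA
#'
#' @param records a protein record table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  headers <- ifelse(
    nzchar(records$description),
    paste(records$id, records$description),
    records$id
  )
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- headers
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read protein records from TSV
#'
#' Tab-separated alternative to FASTA with columns `id`, `sequence` and an
#' explicit `is_fragment` logical column (optional `description`).
#'
#' @param path path to a TSV file with a header row.
#' @return A protein record table.
#' @export
read_protein_tsv <- function(path) {
  if (!file.exists(path)) stop("cannot read TSV file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(tab) == 0L) return(empty_records())
  need <- c("id", "sequence")
  if (!all(need %in% names(tab))) {
    stop("protein TSV requires columns: ", paste(need, collapse = ", "))
  }
  protein_records(
    id = tab$id,
    sequence = tab$sequence,
    description = if ("description" %in% names(tab)) tab$description else "",
    is_fragment = if ("is_fragment" %in% names(tab)) as.logical(tab$is_fragment) else NULL
  )
}

#' Keep only short proteins
#'
#' Retains records strictly shorter than `max_length` residues, preserving the
#' input order. The default reproduces the screen's "shorter than 120 amino
#' acids" input definition.
#'
#' @param records a protein record table.
#' @param max_length integer length cutoff (exclusive).
#' @return The filtered record table.
#' @export
filter_short <- function(records, max_length = 120L) {
  if (!is.numeric(max_length) || length(max_length) != 1L || max_length < 1) {
    stop("'max_length' must be a single integer >= 1")
  }
  records[records$length < max_length, , drop = FALSE]
}

#' Drop fragment entries
#'
#' Removes records flagged as fragments (order preserved), mirroring the
#' exclusion of UniProtKB entries marked "fragment".
#'
#' @param records a protein record table.
#' @return The filtered record table.
#' @export
exclude_fragments <- function(records) {
  records[!records$is_fragment, , drop = FALSE]
}

#' Split records into batches
#'
#' Splits a record table into consecutive batches of at most `batch_size`
#' records (default 10,000, the per-call limit of the original prediction
#' server, kept here as an internal chunk size).
#'
#' @param records a protein record table.
#' @param batch_size maximum records per batch.
#' @return A list of record tables whose row-concatenation equals the input.
#' @export
batch_records <- function(records, batch_size = 10000L) {
  if (!is.numeric(batch_size) || length(batch_size) != 1L || batch_size < 1) {
    stop("'batch_size' must be a single integer >= 1")
  }
  n <- nrow(records)
  if (n == 0L) return(list())
  idx <- unname(split(seq_len(n), ceiling(seq_len(n) / batch_size)))
  lapply(idx, function(i) records[i, , drop = FALSE])
}
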