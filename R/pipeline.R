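# End-to-end screen: filter -> features -> tiers -> signal peptide ->
# scaffold -> report, with a JSON run log reconciling per-stage counts.

#' Run the full TOLIP screen
#'
#' Reads (or takes) a protein record table, excludes fragments, keeps
#' sequences shorter than `max_length`, extracts features in chunks of
#' `chunk_size` records, predicts confidence tiers with `model`, adds
#' signal-peptide and scaffold calls and optional cluster membership, and
#' writes `report.tsv`, `tier_table.tsv` and `run_log.json` to `out_dir`.
#' Report and tier-table files are byte-reproducible for identical inputs.
#'
#' @param input a protein record table, or a path to a FASTA file.
#' @param model a model from [train_ensemble()] or a model-file path.
#' @param out_dir output directory (created if needed).
#' @param max_length length filter cutoff (exclusive).
#' @param chunk_size records per prediction chunk.
#' @param clusters,gene_map optional cluster annotation (see [build_report()]).
#' @param fp_keywords false-positive family keywords.
#' @return Invisibly, a list with `report`, `tier_table`, `run_log` and the
#'   output paths.
#' @export
run_scan <- function(input, model, out_dir, max_length = 120L,
                     chunk_size = 10000L, clusters = NULL, gene_map = NULL,
                     fp_keywords = FP_FAMILY_KEYWORDS) {
  records <- if (is.character(input)) read_fasta(input) else input
  if (is.character(model)) model <- read_model(model)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  n_input <- nrow(records)
  no_frag <- exclude_fragments(records)
  short <- filter_short(no_frag, max_length = max_length)

  if (nrow(short) > 0L) {
    preds <- do.call(rbind, lapply(
      batch_records(short, batch_size = chunk_size),
      function(b) predict_tiers(model, feature_matrix(b))
    ))
    rownames(preds) <- NULL
    sp <- signal_peptide_calls(short)
    sc <- scaffold_calls(short)
    report <- build_report(short, preds, sp, sc,
                           clusters = clusters, gene_map = gene_map,
                           fp_keywords = fp_keywords)
  } else {
    report <- data.frame(
      record_id = character(0), tier = character(0), score = numeric(0),
      has_sp = logical(0), scaffold_matched = logical(0),
      cluster_id = character(0), fp_flag = character(0),
      is_tolip_candidate = logical(0), stringsAsFactors = FALSE
    )
  }
  tier_table <- summarize_tiers(report$tier)

  report_path <- file.path(out_dir, "report.tsv")
  tier_path <- file.path(out_dir, "tier_table.tsv")
  log_path <- file.path(out_dir, "run_log.json")
  write_report(report, report_path)
  write_tier_table(tier_table, tier_path)

  run_log <- list(
    tool = "tolipscan",
    version = as.character(utils::packageVersion("tolipscan")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = list(max_length = max_length, chunk_size = chunk_size),
    counts = list(
      input = n_input,
      after_fragment_exclusion = nrow(no_frag),
      after_length_filter = nrow(short),
      predicted = nrow(report),
      tolip_candidates = sum(report$is_tolip_candidate)
    )
  )
  jsonlite::write_json(run_log, log_path, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    report = report, tier_table = tier_table, run_log = run_log,
    paths = c(report = report_path, tier_table = tier_path, run_log = log_path)
  ))
}

#' Generate and write a synthetic screening data set
#'
#' Writes `proteome.fasta`, `labels.tsv` (ground truth), `genes.bed` and
#' `gene_truth.tsv` to `out_dir`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param gene_args named list of arguments for [generate_gene_table()]
#'   (its `seed` defaults to `config$seed + 1`).
#' @return Invisibly, a list with `records`, `truth`, `loci`, `gene_truth`
#'   and the output paths.
#' @export
run_simulate <- function(config = sim_config(), out_dir,
                         gene_args = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_proteome(config)
  if (is.null(gene_args$seed)) gene_args$seed <- config$seed + 1L
  genes <- do.call(generate_gene_table, gene_args)

  fasta_path <- file.path(out_dir, "proteome.fasta")
  labels_path <- file.path(out_dir, "labels.tsv")
  bed_path <- file.path(out_dir, "genes.bed")
  gene_truth_path <- file.path(out_dir, "gene_truth.tsv")
  write_fasta(sim$records, fasta_path)
  utils::write.table(sim$truth, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gene_bed(genes$loci, bed_path)
  utils::write.table(genes$truth, gene_truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(list(
    records = sim$records, truth = sim$truth,
    loci = genes$loci, gene_truth = genes$truth,
    paths = c(proteome = fasta_path, labels = labels_path,
              genes = bed_path, gene_truth = gene_truth_path)
  ))
}
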