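# Candidate integration and tier accounting. A record is a TOLIP candidate
# when it is positively tiered (P1/P2/P3), carries a secretion signal or an
# LU-like cysteine scaffold, and is not flagged as a member of a known
# false-positive family (keratins, Zn-fingers, RNase-like, plexin/semaphorin
# domains, which dominate the screen's false calls).

FP_FAMILY_KEYWORDS <- c(
  "keratin", "zinc finger", "zn-finger", "ribonuclease", "rnase",
  "plexin", "semaphorin"
)

output_header <- function(columns) {
  c(
    sprintf(
      "# tolipscan %s; coordinates: 1-based inclusive",
      as.character(utils::packageVersion("tolipscan"))
    ),
    columns
  )
}

#' Flag known false-positive families from descriptions
#'
#' Case-insensitive keyword match of a record description against the
#' configurable false-positive family list. The first matching keyword (in
#' list order) is returned as the family label; `NA` when none matches.
#'
#' @param description character vector of record descriptions (or a protein
#'   record table, whose `description` column is used).
#' @param keywords character vector of lower-case family keywords.
#' @return Character vector of family labels or `NA`.
#' @export
flag_false_positive_families <- function(description, keywords = FP_FAMILY_KEYWORDS) {
  if (is.data.frame(description)) description <- description$description
  desc <- tolower(description)
  out <- rep(NA_character_, length(desc))
  for (kw in rev(keywords)) {
    out[grepl(kw, desc, fixed = TRUE)] <- kw
  }
  out
}

# one-decimal percentage as printed in the screen's tier accounting:
# truncated toward zero (114/7337 prints as 1.5)
pct_1dp <- function(x) trunc(x * 10 + 1e-9) / 10

# nearest integer, halves away from zero
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Tier accounting table
#'
#' Counts and percentages per confidence tier, plus the combined
#' "high" (P2+P3) and "positive" (P1+P2+P3) rows. `pct` is the percentage of
#' all inputs printed at one decimal (truncated toward zero, the convention
#' of the screen's headline accounting, under which 114/7337 reads 1.5);
#' `pct_int` is the nearest integer (halves away from zero), under which
#' 418/7337 reads 6.
#'
#' @param tiers character vector of tiers (`N`, `P1`, `P2`, `P3`) or a
#'   prediction data frame with a `tier` column.
#' @return Data frame with columns `class`, `count`, `pct`, `pct_int`.
#' @export
summarize_tiers <- function(tiers) {
  if (is.data.frame(tiers)) tiers <- tiers$tier
  if (!all(tiers %in% TIER_LEVELS)) {
    stop("tiers must be one of: ", paste(TIER_LEVELS, collapse = ", "))
  }
  n <- length(tiers)
  counts <- vapply(TIER_LEVELS, function(t) sum(tiers == t), numeric(1))
  counts <- c(
    counts,
    high = unname(counts["P2"] + counts["P3"]),
    positive = unname(counts["P1"] + counts["P2"] + counts["P3"])
  )
  raw <- if (n > 0) 100 * counts / n else rep(0, length(counts))
  data.frame(
    class = names(counts),
    count = as.integer(counts),
    pct = pct_1dp(raw),
    pct_int = round_half_away(raw),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

tier_rank <- function(tier) match(tier, TIER_LEVELS) - 1L

#' Build the integrated candidate report
#'
#' Joins tier predictions, signal-peptide calls, scaffold matches and
#' (optionally) gene-cluster membership into one row per record, and applies
#' the TOLIP-candidate rule: positive tier AND (signal peptide OR scaffold
#' match) AND no false-positive-family flag. Rows are ordered by tier rank
#' (descending), then score (descending), then id.
#'
#' @param records protein record table (post-filter input of the scan).
#' @param predictions output of [predict_tiers()] for exactly these records.
#' @param sp_calls output of [signal_peptide_calls()].
#' @param scaffold output of [scaffold_calls()].
#' @param clusters optional output of [find_clusters()].
#' @param gene_map optional data frame `record_id`, `gene` linking records to
#'   gene-table entries (required for cluster membership).
#' @param fp_keywords false-positive family keywords.
#' @return Data frame with columns `record_id`, `tier`, `score`, `has_sp`,
#'   `scaffold_matched`, `cluster_id`, `fp_flag`, `is_tolip_candidate`.
#' @export
build_report <- function(records, predictions, sp_calls, scaffold,
                         clusters = NULL, gene_map = NULL,
                         fp_keywords = FP_FAMILY_KEYWORDS) {
  extra <- setdiff(predictions$record_id, records$id)
  if (length(extra)) {
    stop("prediction id(s) absent from records: ", paste(extra, collapse = ", "))
  }
  absent <- setdiff(records$id, predictions$record_id)
  if (length(absent)) {
    stop("record(s) without prediction: ", paste(absent, collapse = ", "))
  }
  ord <- match(records$id, predictions$record_id)
  sp <- sp_calls$has_sp[match(records$id, sp_calls$record_id)]
  sc <- scaffold$scaffold_matched[match(records$id, scaffold$record_id)]
  if (anyNA(sp) || anyNA(sc)) {
    stop("signal-peptide or scaffold calls missing for some records")
  }
  cluster_id <- rep(NA_character_, nrow(records))
  if (!is.null(clusters) && nrow(clusters) > 0 && !is.null(gene_map)) {
    gene2cluster <- do.call(rbind, lapply(seq_len(nrow(clusters)), function(i) {
      data.frame(gene = clusters$members[[i]],
                 cluster_id = clusters$cluster_id[i],
                 stringsAsFactors = FALSE)
    }))
    gm <- merge(gene_map, gene2cluster, by = "gene")
    cluster_id <- gm$cluster_id[match(records$id, gm$record_id)]
  }
  fp <- flag_false_positive_families(records$description, fp_keywords)
  tier <- predictions$tier[ord]
  out <- data.frame(
    record_id = records$id,
    tier = tier,
    score = predictions$score[ord],
    has_sp = sp,
    scaffold_matched = sc,
    cluster_id = cluster_id,
    fp_flag = fp,
    is_tolip_candidate = tier %in% c("P1", "P2", "P3") & (sp | sc) & is.na(fp),
    stringsAsFactors = FALSE
  )
  out <- out[order(-tier_rank(out$tier), -out$score, out$record_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the candidate report / tier table as TSV
#'
#' Output starts with a header line naming the tool version and coordinate
#' convention; report files are byte-reproducible across identical runs.
#'
#' @param report output of [build_report()] (or [summarize_tiers()] for
#'   `write_tier_table`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(paste(names(report), collapse = "\t")), con)
  utils::write.table(report, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_report
#' @export
write_tier_table <- function(report, path) {
  write_report(report, path)
}
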