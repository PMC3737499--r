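test_that("false-positive families are flagged by description keywords", {
  expect_equal(flag_false_positive_families("Keratin-associated protein 4"), "keratin")
  expect_equal(flag_false_positive_families("RNase A family member"), "rnase")
  expect_equal(flag_false_positive_families("Zinc finger protein 37"), "zinc finger")
  expect_true(is.na(flag_false_positive_families("Uncharacterized protein")))
  expect_equal(
    flag_false_positive_families(c("plexin domain", "semaphorin-like", "other")),
    c("plexin", "semaphorin", NA)
  )
})

test_that("tier accounting matches the screen's printed percentages", {
  tiers <- c(rep("P3", 57), rep("P2", 57), rep("P1", 304), rep("N", 7337 - 418))
  tab <- summarize_tiers(tiers)
  expect_equal(tab$count[tab$class == "high"], 114L)
  expect_equal(tab$pct[tab$class == "high"], 1.5)
  expect_equal(tab$count[tab$class == "positive"], 418L)
  expect_equal(tab$pct_int[tab$class == "positive"], 6)
  expect_equal(sum(tab$count[tab$class %in% c("N", "P1", "P2", "P3")]), 7337L)

  allN <- summarize_tiers(rep("N", 10))
  expect_equal(allN$pct[allN$class == "positive"], 0)
  empty <- summarize_tiers(character(0))
  expect_equal(sum(empty$count), 0L)
  expect_error(summarize_tiers("P4"), "tiers")
})

report_fixture <- function() {
  rec <- protein_records(
    id = c("cand", "keratin_hit", "neg_scaffold", "plain"),
    sequence = rep(strrep("ACKDE", 10), 4),
    description = c("uncharacterized", "Keratin-like", "uncharacterized", "x")
  )
  preds <- data.frame(
    record_id = rec$id,
    score = c(2.0, 1.5, -1.0, 0.5),
    votes = c(9L, 9L, 0L, 7L),
    tier = c("P3", "P3", "N", "P2"),
    stringsAsFactors = FALSE
  )
  sp <- data.frame(record_id = rec$id, has_sp = c(TRUE, TRUE, FALSE, FALSE),
                   cleavage_pos = c(20L, 20L, 0L, 0L), h_score = 2)
  sc <- data.frame(record_id = rec$id,
                   scaffold_matched = c(FALSE, FALSE, TRUE, FALSE))
  list(rec = rec, preds = preds, sp = sp, sc = sc)
}

test_that("the candidate rule is the documented conjunction", {
  fx <- report_fixture()
  rep_ <- build_report(fx$rec, fx$preds, fx$sp, fx$sc)
  row <- function(id) rep_[rep_$record_id == id, ]
  expect_true(row("cand")$is_tolip_candidate)              # P3 + SP + no flag
  expect_false(row("keratin_hit")$is_tolip_candidate)      # FP-family flag
  expect_equal(row("keratin_hit")$fp_flag, "keratin")
  expect_false(row("neg_scaffold")$is_tolip_candidate)     # tier N
  expect_false(row("plain")$is_tolip_candidate)            # no SP, no scaffold
  # ordered by tier rank desc then score desc
  expect_equal(rep_$record_id, c("cand", "keratin_hit", "plain", "neg_scaffold"))
  # row-by-row invariant
  expect_equal(
    rep_$is_tolip_candidate,
    rep_$tier %in% c("P1", "P2", "P3") & (rep_$has_sp | rep_$scaffold_matched) &
      is.na(rep_$fp_flag)
  )
})

test_that("report joins validate ids and attach cluster membership", {
  fx <- report_fixture()
  bad <- fx$preds
  bad$record_id[1] <- "ghost"
  expect_error(build_report(fx$rec, bad, fx$sp, fx$sc), "ghost")

  clusters <- find_clusters(data.frame(
    gene = c("gA", "gB", "gC"), chromosome = "chr9",
    start = c(1e6, 1.05e6, 1.1e6), end = c(1.002e6, 1.052e6, 1.102e6),
    strand = "+", stringsAsFactors = FALSE
  ))
  gene_map <- data.frame(record_id = c("cand", "plain"), gene = c("gA", "gC"),
                         stringsAsFactors = FALSE)
  rep_ <- build_report(fx$rec, fx$preds, fx$sp, fx$sc,
                       clusters = clusters, gene_map = gene_map)
  expect_equal(rep_$cluster_id[rep_$record_id == "cand"], "C001")
  expect_true(is.na(rep_$cluster_id[rep_$record_id == "neg_scaffold"]))
})

test_that("report files carry the version/coordinate header", {
  fx <- report_fixture()
  rep_ <- build_report(fx$rec, fx$preds, fx$sp, fx$sc)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep_, path)
  lines <- readLines(path)
  expect_match(lines[1], "^# tolipscan .*1-based inclusive")
  expect_equal(length(lines), 2 + nrow(rep_))
})
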