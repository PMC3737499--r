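toy_matrix <- function(x, name = "f") {
  m <- matrix(x, ncol = 1, dimnames = list(NULL, name))
  m
}

test_that("a separable 1-D problem is solved in one round", {
  m <- toy_matrix(c(1, 2, 3, 10, 11, 12))
  y <- c(-1, -1, -1, 1, 1, 1)
  member <- train_member(m, y, T = 1)
  expect_equal(member$train_error[1], 0)
  expect_equal(member$stumps$threshold, 6.5)  # midpoint across the gap
  expect_equal(member$stumps$polarity, 1)
})

test_that("first round follows the closed-form AdaBoost update", {
  # x = 1..4, y = (+1,-1,+1,+1): best stump is x > 2.5 with eps = 1/4,
  # alpha = log(3)/2; weights become 1/(2*eps*n) misclassified,
  # 1/(2*(1-eps)*n) correct.
  m <- toy_matrix(1:4)
  y <- c(1, -1, 1, 1)
  member <- train_member(m, y, T = 1)
  expect_equal(member$stumps$threshold, 2.5)
  expect_equal(member$stumps$polarity, 1)
  expect_equal(member$stumps$alpha, 0.5 * log(3))
  expect_equal(member$train_error[1], 0.25)

  # the round-2 stump must be the best stump under the closed-form weights
  w2 <- c(1 / (2 * 0.25 * 4), rep(1 / (2 * 0.75 * 4), 3))
  s2 <- tolipscan:::best_stump(m, y, w2 / sum(w2))
  member2 <- train_member(m, y, T = 2)
  expect_equal(member2$stumps$threshold[2], s2$threshold)
  expect_equal(member2$stumps$polarity[2], s2$polarity)
})

test_that("training error is driven down under the decreasing boosting bound", {
  set.seed(21)
  rec <- protein_records(
    sprintf("r%02d", 1:60),
    c(replicate(30, rand_seq(sample(40:100, 1), cys_rich = TRUE)),
      replicate(30, rand_seq(sample(40:100, 1))))
  )
  ts <- build_training_set(rec, rec$id[1:30], rec$id[31:60])
  member <- train_member(ts$features, ts$labels, T = 30)
  bound <- boosting_bound(member)
  expect_true(all(diff(bound) <= 1e-12))
  expect_true(all(member$train_error <= bound + 1e-12))
  expect_lte(member$train_error[30], member$train_error[1])
})

test_that("training input is validated", {
  m <- toy_matrix(1:4)
  expect_error(train_member(m, c(1, 1, 1, 1)), "positive and .* negative")
  expect_error(train_member(m, c(1, 1, -1, 0)), "-1/\\+1")
  m2 <- m; m2[1] <- NA
  expect_error(train_member(m2, c(1, 1, -1, -1)), "finite")
})

test_that("votes map onto tiers at the documented thresholds, monotonically", {
  tf <- list(p1 = 0.5, p2 = 0.75)
  expect_equal(tolipscan:::tier_from_votes(c(9, 8, 7, 6, 5, 4, 0), 9, tf),
               c("P3", "P2", "P2", "P1", "P1", "N", "N"))
  for (M in c(1, 3, 5, 9, 12)) {
    tiers <- tolipscan:::tier_from_votes(0:M, M, tf)
    ranks <- match(tiers, c("N", "P1", "P2", "P3"))
    expect_true(all(diff(ranks) >= 0))
    if (M == 1) expect_setequal(unique(tiers), c("N", "P3"))
  }
})

test_that("ensemble training is seed-deterministic and serializes bit-exactly", {
  set.seed(22)
  rec <- protein_records(
    sprintf("r%02d", 1:40),
    c(replicate(20, rand_seq(sample(40:90, 1), cys_rich = TRUE)),
      replicate(20, rand_seq(sample(40:90, 1))))
  )
  ts <- build_training_set(rec, rec$id[1:20], rec$id[21:40])
  m1 <- train_ensemble(ts$features, ts$labels, T = 10, M = 3, seed = 5)
  m2 <- train_ensemble(ts$features, ts$labels, T = 10, M = 3, seed = 5)
  expect_identical(m1, m2)

  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_model(m1, p1); write_model(m2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)), readBin(p2, "raw", file.size(p2)))

  reloaded <- read_model(p1)
  fm <- feature_matrix(rec)
  expect_identical(predict_tiers(m1, fm), predict_tiers(reloaded, fm))
})

test_that("tier counts conserve inputs and score orders with votes", {
  set.seed(23)
  rec <- protein_records(
    sprintf("r%03d", 1:120),
    c(replicate(60, rand_seq(sample(40:100, 1), cys_rich = TRUE)),
      replicate(60, rand_seq(sample(40:100, 1))))
  )
  ts <- build_training_set(rec, rec$id[1:60], rec$id[61:120])
  model <- train_ensemble(ts$features, ts$labels, T = 15, M = 5, seed = 2)
  preds <- predict_tiers(model, ts$features)
  tab <- summarize_tiers(preds)
  expect_equal(sum(tab$count[tab$class %in% c("N", "P1", "P2", "P3")]), nrow(preds))
  expect_gte(cor(preds$score, preds$votes, method = "spearman"), 0)
})

test_that("when only cysteine features differ, members pick them first", {
  set.seed(24)
  nm <- as.character(feature_catalogue())
  n <- 80
  m <- matrix(rnorm(n * length(nm)), nrow = n, dimnames = list(NULL, nm))
  y <- rep(c(1, -1), each = n / 2)
  cys_cols <- c("cys_count", "cys_fraction", "gap_min", "gap_max", "gap_mean",
                "n_gaps", "spaced_cys_pairs", "has_cterm_cys")
  m[y == 1, cys_cols] <- m[y == 1, cys_cols] + 3
  model <- train_ensemble(m, y, T = 5, M = 10, seed = 3)
  first <- vapply(model$members, function(mem) mem$stumps$feature[1], character(1))
  expect_gte(mean(first %in% cys_cols), 0.8)
})

test_that("build_training_set validates id sets", {
  rec <- protein_records(c("a", "b", "c"), c("MKC", "MKA", "MKW"))
  ts <- build_training_set(rec, c("a", "b"), "c")
  expect_equal(ts$labels, c(1, 1, -1))
  expect_equal(rownames(ts$features), c("a", "b", "c"))
  expect_error(build_training_set(rec, c("a", "b"), c("b", "c")), "overlap")
  expect_error(build_training_set(rec, "a", character(0)), "non-empty")
  expect_error(build_training_set(rec, "a", "zz"), "absent")
})
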