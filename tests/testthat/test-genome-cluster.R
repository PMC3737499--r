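test_that("BED ingestion converts to 1-based inclusive coordinates", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr9\t35607092\t35611884\tPate4\t0\t-", path)
  loci <- read_gene_table(path, "bed")
  expect_equal(loci$start, 35607093)
  expect_equal(loci$end, 35611884)
  expect_equal(loci$end - loci$start + 1, 4792)  # printed transcript length
  expect_equal(loci$strand, "-")

  empty <- withr::local_tempfile(fileext = ".bed")
  file.create(empty)
  expect_equal(nrow(read_gene_table(empty, "bed")), 0L)
})

test_that("TSV gene tables round-trip unchanged and are validated", {
  loci <- data.frame(
    gene = c("g1", "g2"), chromosome = "chr1",
    start = c(100L, 5000L), end = c(400L, 5400L), strand = c("+", "-"),
    stringsAsFactors = FALSE
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(loci, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_gene_table(path, "tsv"), loci)

  bad <- loci; bad$start[1] <- 500L
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_gene_table(path, "tsv"), "start > end")
  bad <- loci; bad$strand[2] <- "?"
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_gene_table(path, "tsv"), "strand")
})

make_loci <- function(chrom, starts, width = 2000) {
  data.frame(
    gene = sprintf("%s_g%d", chrom, seq_along(starts)), chromosome = chrom,
    start = as.integer(starts), end = as.integer(starts + width - 1),
    strand = "+", stringsAsFactors = FALSE
  )
}

test_that("gap chaining groups nearby loci and never crosses chromosomes", {
  # three genes with ~50 kb inter-gene gaps on one chromosome
  a <- make_loci("chr9", c(1e6, 1e6 + 52000, 1e6 + 104000))
  cl <- find_clusters(a)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_genes, 3L)

  # identical coordinates on two chromosomes never co-cluster
  b <- rbind(make_loci("chr1", c(1e6, 1.01e6, 1.02e6)),
             make_loci("chr2", c(1e6, 1.01e6, 1.02e6)))
  cl <- find_clusters(b)
  expect_equal(cl$chromosome, c("chr1", "chr2"))
  expect_equal(cl$n_genes, c(3L, 3L))

  # 28 loci within 0.9 Mb chain into a single cluster at defaults
  c28 <- make_loci("chr15", seq(74700000, by = 33000, length.out = 28))
  cl <- find_clusters(c28)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_genes, 28L)
  expect_lte(cl$span_nt, 0.9e6)

  expect_error(find_clusters(a, max_gap = -1), "max_gap")
  expect_error(find_clusters(a, min_genes = 0), "min_genes")
})

test_that("cluster span is max(end) - min(start)", {
  loci <- make_loci("chr15", c(74700000, 75100000, 75598001))
  expect_equal(cluster_span(loci), 75600000 - 74700000)
  expect_equal(cluster_span(loci[1, , drop = FALSE]), 1999)
  expect_error(cluster_span(loci[0, ]), "empty")
})

test_that("clustering matches an O(n^2) transitive-closure oracle and is shuffle-stable", {
  set.seed(51)
  for (i in 1:250) {
    n <- sample(3:22, 1)
    loci <- data.frame(
      gene = sprintf("g%02d", 1:n),
      chromosome = sample(paste0("chr", 1:3), n, replace = TRUE),
      start = sample.int(1e6, n),
      strand = "+", stringsAsFactors = FALSE
    )
    loci$end <- loci$start + sample.int(5e4, n)
    max_gap <- sample.int(2e5, 1)
    min_genes <- sample(1:3, 1)
    got <- find_clusters(loci, max_gap = max_gap, min_genes = min_genes)
    expect_identical(cluster_sets(got), naive_clusters(loci, max_gap, min_genes),
                     label = sprintf("case %d", i))

    shuffled <- loci[sample.int(n), , drop = FALSE]
    got2 <- find_clusters(shuffled, max_gap = max_gap, min_genes = min_genes)
    rownames(got2) <- NULL
    expect_identical(got2, got)

    # no locus in two clusters
    members <- unlist(got$members)
    expect_equal(anyDuplicated(members), 0L)
  }
})

test_that("raising max_gap never un-clusters loci", {
  set.seed(52)
  loci <- make_loci("chr2", cumsum(sample.int(8e4, 30)) + 1e5)
  sizes <- vapply(c(1e4, 5e4, 1e5, 2e5), function(g) {
    sum(find_clusters(loci, max_gap = g, min_genes = 2)$n_genes)
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
})
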