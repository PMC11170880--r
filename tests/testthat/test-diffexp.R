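test_that("exact Wilcoxon p-values match hand-derived cases", {
  res <- wilcoxon_rank_sum(c(3, 4, 5), c(0, 1, 2))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$statistic, 9)  # maximal U for 3 vs 3

  # identical multisets sit exactly at the null centre
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("exact branch equals full permutation enumeration up to 7 per group", {
  set.seed(17)
  for (nx in c(1, 3, 5, 7)) {
    for (ny in c(2, 4, 7)) {
      # ties on purpose: small integer support
      x <- sample(0:3, nx, replace = TRUE)
      y <- sample(0:3, ny, replace = TRUE)
      expect_equal(wilcoxon_rank_sum(x, y)$p_value,
                   oracle_wilcoxon_p(x, y), tolerance = 1e-12)
    }
  }
})

test_that("exact branch agrees with the reference exact test when tie-free", {
  set.seed(18)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(6)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("normal branch is close to the reference on larger tied samples", {
  set.seed(19)
  x <- sample(0:6, 40, replace = TRUE)
  y <- sample(0:8, 55, replace = TRUE)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(wilcoxon_rank_sum(x, y)$p_value, ref, tolerance = 1e-10)
})

norm_cm <- function(vals) count_matrix(vals, layer = "normalized",
                                       feature_kind = "gene")

test_that("differential activity computes the stated log2 fold-change", {
  # in-group back-transformed mean 3, out-group 1 -> log2(4 / 2) = 1
  vals <- rbind(
    marker = c(rep(log1p(3), 10), rep(log1p(1), 10)),
    flat = rep(log1p(2), 20),
    silent = rep(0, 20)
  )
  colnames(vals) <- paste0("c", 1:20)
  labels <- setNames(rep(c("A", "B"), each = 10), colnames(vals))
  rec <- differential_activity(norm_cm(vals), labels, "A")

  expect_equal(rec$log2fc[rec$gene == "marker"], 1)
  expect_equal(rec$log2fc[rec$gene == "flat"], 0)
  expect_gt(rec$p_value[rec$gene == "flat"], 0.99)
  expect_false("silent" %in% rec$gene)      # all-zero: below min_pct
  expect_true(all(rec$adj_p_value >= rec$p_value))

  expect_error(differential_activity(norm_cm(vals), labels, "Z"), "Z")
  one <- setNames(rep("A", 20), colnames(vals))
  expect_error(differential_activity(norm_cm(vals), one, "A"), "two distinct")
})

test_that("differential activity is invariant to cell ordering", {
  set.seed(21)
  vals <- matrix(abs(rnorm(300)), 15, 20,
                 dimnames = list(paste0("g", 1:15), paste0("c", 1:20)))
  labels <- setNames(sample(c("A", "B"), 20, replace = TRUE,
                            prob = c(.4, .6)), colnames(vals))
  rec1 <- differential_activity(norm_cm(vals), labels, "A")
  perm <- sample(20)
  rec2 <- differential_activity(norm_cm(vals[, perm]), labels, "A")
  expect_equal(rec1, rec2)
})

test_that("gene sets take the top/bottom genes by log2fc with |log2fc| weights", {
  set.seed(22)
  n_pos <- 150; n_neg <- 40
  rec <- data.frame(
    gene = sprintf("g%03d", seq_len(n_pos + n_neg + 10)),
    cell_type = "T",
    log2fc = c(runif(n_pos, 0.01, 5), -runif(n_neg, 0.01, 3), rep(0, 10)),
    p_value = runif(n_pos + n_neg + 10),
    adj_p_value = 1, pct_in = 0.5, pct_out = 0.5)

  expect_warning(sets <- build_cell_type_gene_sets(rec, n_genes = 100),
                 "only 40")
  up <- sets[sets$direction == "up", ]
  down <- sets[sets$direction == "down", ]
  expect_identical(nrow(up), 100L)
  expect_identical(nrow(down), 40L)      # saturated below n_genes

  # up-set = the 100 largest log2fc, ordered descending
  want <- rec[order(-rec$log2fc), ][1:100, ]
  expect_identical(up$gene, want$gene)
  expect_equal(up$weight, want$log2fc)
  # down-set ranked most-negative first; weights are |log2fc|
  expect_equal(down$weight, abs(sort(rec$log2fc[rec$log2fc < 0])),
               tolerance = 1e-12)
  expect_true(all(down$weight > 0))
  expect_length(intersect(up$gene, down$gene), 0)
})

test_that("log2fc ties break by smaller p then gene name", {
  rec <- data.frame(
    gene = c("b", "a", "c"), cell_type = "T",
    log2fc = c(2, 2, 2), p_value = c(0.5, 0.5, 0.1),
    adj_p_value = 1, pct_in = 1, pct_out = 1)
  suppressWarnings(sets <- build_cell_type_gene_sets(rec, n_genes = 2))
  expect_identical(sets$gene[sets$direction == "up"], c("c", "a"))
})

test_that("a direction with no qualifying gene is omitted with a warning", {
  rec <- data.frame(gene = c("g1", "g2"), cell_type = "T",
                    log2fc = c(1, 2), p_value = 0.01,
                    adj_p_value = 0.02, pct_in = 1, pct_out = 0.1)
  expect_warning(sets <- build_cell_type_gene_sets(rec, n_genes = 2),
                 "down")
  expect_identical(unique(sets$direction), "up")
})

test_that("planted up-markers are recovered from a small simulation", {
  d <- make_fixture("tiny")
  norm <- log_normalize(d$activity)
  types <- unique(d$truth_labels)
  recs <- lapply(types, function(ct)
    differential_activity(norm, d$truth_labels, ct))
  # in one-vs-rest the other type's down-markers also rank as relatively
  # up-regulated, so give the set room for both programs
  sets <- suppressWarnings(build_cell_type_gene_sets(recs, n_genes = 10))
  for (ct in types) {
    planted <- d$planted$gene[d$planted$cell_type == ct &
                                d$planted$direction == "up"]
    built <- sets$gene[sets$cell_type == ct & sets$direction == "up"]
    expect_gte(mean(planted %in% built), 0.8)
  }
})
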