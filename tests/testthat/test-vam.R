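norm_cm <- function(vals) count_matrix(vals, layer = "normalized",
                                       feature_kind = "gene")

test_that("variance-adjusted distances follow the stated formula", {
  # single gene, values {0, 1, 2}: sample variance 1, distances {0, 1, 4}
  vals <- named_mat(c(0, 1, 2), 1, 3)
  set <- data.frame(cell_type = "T", direction = "up", gene = "g1",
                    weight = 1)
  d <- compute_vam_distances(norm_cm(vals), set, vam_params(seed = 3))
  expect_equal(unname(d$observed), c(0, 1, 4))
  expect_equal(unname(d$variances), 1)
  expect_length(d$null, 1000)
})

test_that("an all-zero cell is at distance zero", {
  vals <- named_mat(c(0, 0, 3, 1, 2, 5), 2, 3)
  set <- data.frame(cell_type = "T", direction = "up",
                    gene = c("g1", "g2"), weight = c(1, 2))
  d <- compute_vam_distances(norm_cm(vals), set, vam_params(seed = 3))
  expect_equal(unname(d$observed[1]), 0)
  expect_true(all(d$observed >= 0) && all(d$null >= 0))
})

test_that("scores are invariant to a global rescaling of the raw weights", {
  set.seed(31)
  vals <- named_mat(abs(rnorm(200)), 10, 20)
  set1 <- data.frame(cell_type = "T", direction = "up",
                     gene = paste0("g", 1:6), weight = runif(6, 0.5, 3))
  set2 <- set1
  set2$weight <- set1$weight * 57.3
  p <- vam_params(seed = 9)
  expect_equal(score_gene_set(norm_cm(vals), set1, p)$scores,
               score_gene_set(norm_cm(vals), set2, p)$scores)
})

test_that("absent set genes are dropped with a warning; none left is an error", {
  vals <- named_mat(abs(rnorm(40)), 4, 10)
  set <- data.frame(cell_type = "T", direction = "up",
                    gene = c("g1", "nope1", "nope2"), weight = 1)
  expect_warning(d <- compute_vam_distances(norm_cm(vals), set,
                                            vam_params(seed = 1)),
                 "nope1")
  expect_identical(d$genes, "g1")
  ghost <- data.frame(cell_type = "T", direction = "up",
                      gene = "nope", weight = 1)
  expect_error(compute_vam_distances(norm_cm(vals), ghost,
                                     vam_params(seed = 1)), "T up")
})

test_that("distances are monotone in a gene's squared value at frozen variances", {
  set.seed(32)
  vals <- named_mat(abs(rnorm(100)), 5, 20)
  set <- data.frame(cell_type = "T", direction = "up",
                    gene = paste0("g", 1:5), weight = 1)
  d <- compute_vam_distances(norm_cm(vals), set, vam_params(seed = 2))
  # recompute cell 1's distance by hand with doubled g1, frozen variances
  x <- vals[d$genes, 1]
  base <- sum(d$weights * x^2 / d$variances)
  x2 <- x; x2[1] <- 2 * x2[1]
  expect_gte(sum(d$weights * x2^2 / d$variances), base)
  expect_equal(base, unname(d$observed[1]))
})

test_that("moment and likelihood gamma fits recover known parameters", {
  # exact moments: affinely rescale any sample to mean 4, variance 8
  set.seed(33)
  x <- rgamma(500, shape = 2, rate = 0.5)
  x <- (x - mean(x)) / sd(x) * sqrt(8) + 4
  stopifnot(all(x > 0))
  fit <- fit_gamma(x, "method_of_moments")
  expect_equal(fit$shape, 2, tolerance = 1e-12)
  expect_equal(fit$rate, 0.5, tolerance = 1e-12)

  # consistency at large n
  set.seed(34)
  big <- rgamma(1e5, shape = 3, rate = 1)
  expect_true(fit_gamma(big, "method_of_moments")$shape > 2.9 &&
                fit_gamma(big, "method_of_moments")$shape < 3.1)
  mle <- fit_gamma(big, "mle")
  expect_true(mle$shape > 2.9 && mle$shape < 3.1)
  expect_true(mle$rate > 0.9 && mle$rate < 1.1)

  expect_error(fit_gamma(rep(2, 200)), "constant")
  expect_error(fit_gamma(rgamma(50, 2)), "100")
})

test_that("likelihood fit matches an independent reference fitter", {
  skip_if_not_installed("fitdistrplus")
  set.seed(35)
  x <- rgamma(2000, shape = 1.7, rate = 2.2)
  mine <- fit_gamma(x, "mle")
  ref <- fitdistrplus::fitdist(x, "gamma")
  expect_equal(mine$shape, unname(ref$estimate["shape"]), tolerance = 1e-4)
  expect_equal(mine$rate, unname(ref$estimate["rate"]), tolerance = 1e-4)
})

test_that("set scores live in [0,1], send d2=0 to 0 and are seeded", {
  d <- make_fixture("tiny")
  norm <- log_normalize(d$activity)
  set <- d$planted[d$planted$cell_type == "type01" &
                     d$planted$direction == "up", ]
  p <- vam_params(seed = 8)
  s1 <- score_gene_set(norm, set, p)
  s2 <- score_gene_set(norm, set, p)
  expect_identical(s1$scores, s2$scores)        # deterministic given seed
  expect_true(all(s1$scores >= 0 & s1$scores <= 1))
  expect_equal(s1$p_values, 1 - s1$scores)
  expect_true(s1$gamma_shape > 0 && s1$gamma_rate > 0)
  zero_cells <- s1$distances == 0
  if (any(zero_cells)) expect_true(all(s1$scores[zero_cells] == 0))
})

test_that("a cell beyond every null distance scores near 1 when separated", {
  set.seed(36)
  vals <- named_mat(abs(rnorm(300, sd = 0.5)), 10, 30)
  vals[1:5, 1] <- 25                       # one extreme cell
  set <- data.frame(cell_type = "T", direction = "up",
                    gene = paste0("g", 1:5), weight = 1)
  s <- score_gene_set(norm_cm(vals), set, vam_params(seed = 4))
  d <- compute_vam_distances(norm_cm(vals), set, vam_params(seed = 4))
  expect_gt(d$observed[1], max(d$null))
  expect_gt(s$scores[1], 0.99)
})

test_that("gamma-CDF scores track the empirical null quantiles", {
  d <- make_fixture("tiny")
  norm <- log_normalize(d$activity)
  set <- d$planted[d$planted$cell_type == "type01" &
                     d$planted$direction == "up", ]
  p <- vam_params(n_permutations = 10000, seed = 12)
  dd <- compute_vam_distances(norm, set, p)
  fit <- fit_gamma(dd$null)
  gamma_scores <- pgamma(dd$observed, shape = fit$shape, rate = fit$rate)
  empirical <- ecdf(dd$null)(dd$observed)
  expect_lt(max(abs(gamma_scores - empirical)), 0.05)
})

test_that("scores on iid noise are uniformly distributed", {
  nl <- make_fixture("null")
  norm <- log_normalize(nl$activity)
  set.seed(99)
  set <- data.frame(cell_type = "noise", direction = "up",
                    gene = sample(cm_features(norm), 50), weight = 1)
  s <- score_gene_set(norm, set, vam_params(seed = 5))
  ks <- suppressWarnings(stats::ks.test(s$scores, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("parameter validation guards the calibration preconditions", {
  expect_error(vam_params(n_permutations = 50), "100")
  expect_error(vam_params(variance_floor = 0), "positive")
  p <- vam_params()
  expect_identical(p$gamma_fit, "method_of_moments")
  expect_identical(p$input_layer, "normalized")
})
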