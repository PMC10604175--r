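test_that("z-score normalization yields mean 0, sd 1 and is affine invariant", {
  data <- tiny_separable_data()
  norm <- zscore_normalize(data)
  expect_true(all(abs(colMeans(norm$values)) < 1e-10))
  expect_true(all(abs(apply(norm$values, 2, sd) - 1) < 1e-10))

  # affine transform of a gene leaves its z-scores unchanged
  shifted <- data
  shifted$values[, 2] <- 3.7 * data$values[, 2] - 11
  norm2 <- zscore_normalize(shifted)
  expect_equal(norm2$values[, 2], norm$values[, 2], tolerance = 1e-10)

  # constant gene becomes an all-zero flagged column, not an error
  flat <- data
  flat$values[, 3] <- 5
  norm3 <- zscore_normalize(flat)
  expect_identical(unname(norm3$values[, 3]), rep(0, nrow(data$values)))
  expect_identical(attr(norm3, "zero_variance"), 3L)
})

test_that("per-gene Welch statistics match t.test gene by gene", {
  truth <- make_synthetic_expression(
    synthetic_spec(n_samples = 24, n_genes = 30, n_informative = 4,
                   effect_size = 1.5, class_balance = 0.5, seed = 6))
  data <- truth$data
  de <- differential_expression(data)
  for (j in seq_len(ncol(data$values))) {
    ref <- t.test(data$values[data$labels == "tumor", j],
                  data$values[data$labels == "normal", j],
                  var.equal = FALSE)
    expect_equal(de$t_stat[j], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(de$p_value[j], ref$p.value, tolerance = 1e-10)
  }
  # logfc is the group-mean difference, second sorted class minus first
  m_tumor <- colMeans(data$values[data$labels == "tumor", ])
  m_normal <- colMeans(data$values[data$labels == "normal", ])
  expect_equal(de$logfc, unname(m_tumor - m_normal), tolerance = 1e-12)
  expect_identical(de$mean_diff, de$logfc)
})

test_that("strong planted signal reaches the reference Welch p-value scale", {
  # group means 0 vs 3, sd 1, n = 30/30: t around 11.6
  set.seed(77)
  g <- c(rnorm(30), rnorm(30, mean = 3))
  data <- labeled_expression(cbind(g, rnorm(60)),
                             sprintf("s%d", 1:60), c("sig", "noise"),
                             rep(c("a", "b"), each = 30))
  de <- differential_expression(data)
  expect_gt(abs(de$t_stat[1]), 8)
  expect_lt(de$p_value[1], 1e-6)
})

test_that("degenerate genes and tied p-values behave as specified", {
  data <- tiny_separable_data()
  data$values[, 4] <- 2  # zero variance in both groups
  de <- differential_expression(data)
  expect_identical(de$t_stat[4], 0)
  expect_identical(de$p_value[4], 1)
  expect_true(all(de$adj_p >= de$p_value - 1e-15))
  expect_true(all(de$adj_p <= 1))
  expect_equal(de$adj_p, bh_bruteforce(de$p_value), tolerance = 1e-12)
  # all genes sharing one raw p adjust to exactly that p
  expect_identical(unname(p.adjust(rep(0.03, 7), method = "BH")),
                   rep(0.03, 7))
  small <- labeled_expression(matrix(rnorm(8), 4, 2), sprintf("s%d", 1:4),
                              c("g1", "g2"), c("a", "a", "a", "b"))
  expect_error(differential_expression(small), "at least 2 samples")
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  set.seed(31)
  for (k in 1:40) {
    m <- sample(1:50, 1)
    p <- runif(m)
    expect_equal(unname(p.adjust(p, method = "BH")), bh_bruteforce(p),
                 tolerance = 1e-12)
  }
})

test_that("filter_degs applies both gates, preserves order, is monotone in alpha", {
  tab <- data.frame(gene_id = paste0("g", 1:4),
                    mean_diff = c(2, -1, 0.5, 3),
                    logfc = c(2, -1, 0.5, 3),
                    t_stat = c(5, -4, 1, 6),
                    p_value = c(0.001, 0.004, 0.2, 0.0001),
                    adj_p = c(0.004, 0.008, 0.2, 0.0008))
  expect_identical(filter_degs(tab, alpha = 0.01), c(1L, 2L, 4L))
  expect_identical(filter_degs(tab, alpha = 1), 1:4)
  # fold-change gate is strict
  one <- data.frame(gene_id = "g", mean_diff = 0.5, logfc = 0.5,
                    t_stat = 3, p_value = 0.005, adj_p = 0.01)
  expect_warning(out <- filter_degs(one, alpha = 0.05, logfc_min = 0.68),
                 "no genes")
  expect_length(out, 0)

  set.seed(60)
  for (k in 1:20) {
    tab2 <- data.frame(gene_id = paste0("g", 1:30), mean_diff = rnorm(30),
                       logfc = rnorm(30), t_stat = rnorm(30),
                       p_value = runif(30), adj_p = runif(30))
    alphas <- sort(runif(3))
    prev <- integer(0)
    for (a in alphas) {
      cur <- suppressWarnings(filter_degs(tab2, alpha = a))
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("pure-noise data rarely yields BH survivors at alpha 0.05", {
  survivors <- sapply(1:20, function(s) {
    truth <- make_synthetic_expression(
      synthetic_spec(n_samples = 40, n_genes = 200, n_informative = 0,
                     effect_size = 0, class_balance = 0.5, seed = 1000 + s))
    de <- differential_expression(truth$data)
    length(suppressWarnings(filter_degs(de, alpha = 0.05)))
  })
  expect_identical(median(survivors), 0)
  # FDR smoke: few replicates have any survivor at all
  expect_lt(mean(survivors > 0), 0.2)
})
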