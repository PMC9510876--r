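test_that("size factors follow the median-of-ratios construction", {
  cnt <- tibble::tibble(gene = c("g1", "g2", "g3"), A = c(2, 4, 6), B = c(4, 8, 12))
  sf <- size_factors(cnt)
  expect_equal(sf$size_factor, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)
  expect_equal(sf$size_factor[2] / sf$size_factor[1], 2)

  # identical samples are left untouched
  same <- tibble::tibble(gene = c("g1", "g2"), A = c(5, 9), B = c(5, 9))
  expect_equal(size_factors(same)$size_factor, c(1, 1))

  # no gene positive everywhere
  zero <- tibble::tibble(gene = c("g1", "g2"), A = c(0, 3), B = c(2, 0))
  expect_error(size_factors(zero), "pseudo-reference")
})

test_that("size factors agree with the standard median-of-ratios tool", {
  skip_if_not_installed("DESeq2")
  sim <- simulate_rip_counts(n_features = 300, library_sizes = c(1, 2, 0.5, 1, 1.5, 1, 2), seed = 4)
  m <- as.matrix(sim$counts[, sim$samples$sample])
  ours <- size_factors(sim$counts[, c("feature", sim$samples$sample)] |>
    dplyr::rename(gene = feature))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(ours$size_factor, unname(ref), tolerance = 1e-8)
})

test_that("normalization removes planted library-size differences", {
  sim <- simulate_rip_counts(
    n_features = 500,
    library_sizes = c(0.5, 1, 2, 1, 1.5, 0.8, 1.2), seed = 8
  )
  cnt <- dplyr::rename(sim$counts[, c("feature", sim$samples$sample)],
    gene = feature
  )
  norm <- normalize_counts(cnt)
  col_sums <- colSums(as.matrix(norm[, -1]))
  expect_lt(max(col_sums) / min(col_sums), 1.05)
})

test_that("the pooled t-test reproduces its closed form", {
  cnt <- tibble::tibble(
    gene = "g1", a1 = 1, a2 = 2, a3 = 3, b1 = 4, b2 = 5, b3 = 6
  )
  de <- de_ttest(cnt, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  expect_equal(de$t_statistic, -3.674, tolerance = 1e-3)
  want <- oracle_pooled_t(1:3, 4:6)
  expect_equal(de$t_statistic, want$t, tolerance = 1e-10)
  expect_equal(de$p_value, want$p, tolerance = 1e-10)
  expect_equal(de$p_value, 0.021, tolerance = 0.05)
})

test_that("t statistics match the brute-force definition on random data", {
  withr::with_seed(21, {
    for (i in 1:50) {
      x <- rnorm(sample(2:6, 1), 5, 2)
      y <- rnorm(sample(2:6, 1), 4, 1)
      cnt <- tibble::tibble(gene = "g", !!!setNames(
        as.list(abs(c(x, y))),
        c(paste0("x", seq_along(x)), paste0("y", seq_along(y)))
      ))
      de <- de_ttest(cnt, paste0("x", seq_along(x)), paste0("y", seq_along(y)))
      want <- oracle_pooled_t(abs(x), abs(y))
      expect_equal(de$t_statistic, want$t, tolerance = 1e-10)
      expect_equal(de$p_value, want$p, tolerance = 1e-10)
    }
  })
})

test_that("fold changes are ratios of group means", {
  cnt <- tibble::tibble(
    gene = "g1",
    a1 = 4.001, a2 = 3.999, b1 = 2.0001, b2 = 1.9999
  )
  de <- de_ttest(cnt, c("a1", "a2"), c("b1", "b2"))
  expect_equal(de$fold_change, 2, tolerance = 1e-4)

  same <- tibble::tibble(gene = "g", a1 = 3, a2 = 3, b1 = 3, b2 = 3)
  de0 <- de_ttest(same, c("a1", "a2"), c("b1", "b2"))
  expect_equal(de0$fold_change, 1)
  expect_equal(de0$p_value, 1)

  # constant but unequal groups cannot be tested
  flat <- tibble::tibble(gene = "g", a1 = 3, a2 = 3, b1 = 5, b2 = 5)
  def <- de_ttest(flat, c("a1", "a2"), c("b1", "b2"))
  expect_true(is.na(def$p_value))
  expect_true(def$zero_variance)
})

test_that("fold change is equivariant under scaling of the case group", {
  withr::with_seed(13, {
    cnt <- tibble::tibble(
      gene = paste0("g", 1:20),
      a1 = rpois(20, 50) + 1, a2 = rpois(20, 50) + 1,
      b1 = rpois(20, 50) + 1, b2 = rpois(20, 50) + 1
    )
  })
  de1 <- de_ttest(cnt, c("a1", "a2"), c("b1", "b2"))
  scaled <- dplyr::mutate(cnt, a1 = a1 * 3, a2 = a2 * 3)
  de2 <- de_ttest(scaled, c("a1", "a2"), c("b1", "b2"))
  expect_equal(de2$fold_change, de1$fold_change * 3, tolerance = 1e-12)
})

test_that("the null false-positive rate is calibrated", {
  sim <- simulate_rip_counts(
    n_features = 1000, n_ip_case = 4, n_ip_ctrl = 4,
    mean_count = 100, seed = 17
  )
  cnt <- dplyr::rename(
    sim$counts[, c("feature", sim$samples$sample)],
    gene = feature
  )
  de <- de_ttest(
    normalize_counts(cnt),
    sim$samples$sample[sim$samples$side == "case"],
    sim$samples$sample[sim$samples$side == "ctrl"]
  )
  fpr <- mean(de$p_value < 0.05, na.rm = TRUE)
  expect_gte(fpr, 0.03)
  expect_lte(fpr, 0.07)
})

test_that("candidate nomination combines enrichment and regulation", {
  hss_scores <- tibble::tibble(
    gene = c("slm2_like", "rbm20_like", "broad"),
    heart_expr = c(5, 30, 10),
    hss = c(5, 11.4, 1.2),
    passes_enrichment = c(TRUE, TRUE, FALSE)
  )
  de <- tibble::tibble(
    gene = c("slm2_like", "rbm20_like", "broad"),
    mean_case = c(19, 10, 12), mean_ctrl = c(10, 10, 6),
    fold_change = c(1.9, 1.0, 2.0),
    log2_fold_change = log2(c(1.9, 1.0, 2.0)),
    t_statistic = c(5, 0.1, 4),
    p_value = c(0.001, 0.4, 0.002),
    direction = c("up", "ns", "up"),
    zero_variance = FALSE
  )
  cand <- nominate_candidates(hss_scores, de)
  expect_equal(cand$verdict, c(TRUE, FALSE, FALSE))
  expect_equal(cand$gene[1], "slm2_like")
  # enriched but unregulated (the constitutive splicing-factor pattern)
  rbm <- cand[cand$gene == "rbm20_like", ]
  expect_true(rbm$enriched)
  expect_false(rbm$regulated)
  expect_equal(
    attr(cand, "regulated_counts"),
    c(up = 1L, down = 0L)
  )
  expect_error(
    nominate_candidates(
      dplyr::mutate(hss_scores, gene = paste0("x_", gene)), de
    ),
    "unmatched|shared"
  )
})

test_that("a planted enriched and regulated factor is the unique candidate", {
  d <- simulate_screen_data(seed = 23, n_genes = 300)
  h <- compute_hss(d$expression)
  de <- de_ttest(
    normalize_counts(d$counts),
    d$samples$sample[d$samples$condition == "case"],
    d$samples$sample[d$samples$condition == "ctrl"]
  )
  cand <- nominate_candidates(h, de)
  expect_equal(cand$gene[cand$verdict], d$truth$factor_gene)
})

test_that("relative qPCR expression follows 2^-dCt", {
  expect_equal(delta_ct(25, 20), 0.03125)
  expect_equal(delta_ct(20, 20), 1)
  expect_equal(delta_ct(20, 25), 32)
  expect_equal(delta_ct(c(25, 20), c(20, 25)), c(0.03125, 32))
})
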