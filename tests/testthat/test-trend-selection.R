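# Kendall tau-b trend statistic, pairwise t-tests, BH adjustment, fold
# changes and the marker selection / Venn logic.

test_that("kendall_tau_trend handles perfect monotone cases and errors", {
  expect_equal(kendall_tau_trend(c(1, 2, 3), c(0, 1, 2)), 1)
  expect_equal(kendall_tau_trend(c(3, 2, 1), c(0, 1, 2)), -1)
  expect_error(kendall_tau_trend(c(1, 2, 3), c(0, 0, 0)), "trend undefined")
  expect_error(kendall_tau_trend(c(1, 2), c(0, 1, 2)), "equal length")
  expect_error(kendall_tau_trend(c(1, NA, 3), c(0, 1, 2)), "finite")
  deg <- kendall_tau_trend(c(2, 2, 2), c(0, 1, 2))
  expect_equal(as.numeric(deg), 0)
  expect_true(attr(deg, "degenerate"))
})

test_that("kendall_tau_trend matches brute-force pair counting with ties", {
  # spec-style tied example
  expect_equal(kendall_tau_trend(c(5, 1, 4, 2, 6, 3), c(0, 0, 1, 1, 2, 2)),
               oracle_tau(c(5, 1, 4, 2, 6, 3), c(0, 0, 1, 1, 2, 2)))
  set.seed(11)
  for (rep in 1:60) {
    n <- sample(3:12, 1)
    x <- sample(1:5, n, replace = TRUE)           # value ties
    y <- sort(sample(0:2, n, replace = TRUE))
    if (length(unique(y)) < 2) y[n] <- y[1] + 1
    x <- x + 0
    expect_equal(as.numeric(kendall_tau_trend(x, y)), oracle_tau(x, y))
    # cross-check against the reference implementation (defined only when
    # the values are not all tied)
    if (length(unique(x)) > 1)
      expect_equal(as.numeric(kendall_tau_trend(x, y)),
                   cor(x, y, method = "kendall"),
                   tolerance = 1e-12)
  }
})

test_that("tau is invariant to strictly increasing stage recodings", {
  set.seed(4)
  x <- rnorm(18)
  y <- rep(0:2, each = 6)
  for (f in list(function(s) s, function(s) 10 * s + 3, function(s) s^3 + s)) {
    expect_equal(kendall_tau_trend(x, f(y)), kendall_tau_trend(x, y))
  }
})

test_that("row-wise tau agrees with the scalar implementation", {
  set.seed(8)
  mat <- matrix(rnorm(20 * 15), nrow = 20)
  stages <- rep(0:2, each = 5)
  rt <- methmarker:::.row_kendall_tau(mat, stages)
  for (i in seq_len(nrow(mat)))
    expect_equal(rt$tau[i], as.numeric(kendall_tau_trend(mat[i, ], stages)))
})

test_that("bh_adjust equals the step-up definition and validates input", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.2, 0.2, 0.2)), c(0.2, 0.2, 0.2))
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.02)),
               oracle_bh(c(0.01, 0.04, 0.03, 0.02)))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(21)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("pairwise pooled t-tests match the textbook formula and t.test", {
  set.seed(5)
  mat <- matrix(rnorm(50 * 18, mean = 6), nrow = 50)
  stages <- rep(c("normal", "adenoma", "CRC"), each = 6)
  res <- pairwise_group_tests(mat, stages)
  i_n <- 1:6; i_ad <- 7:12; i_crc <- 13:18
  for (g in sample(50, 10)) {
    expect_equal(res$p_n_ad[g], oracle_pooled_t_p(mat[g, i_n], mat[g, i_ad]))
    expect_equal(res$p_n_crc[g], oracle_pooled_t_p(mat[g, i_n], mat[g, i_crc]))
    expect_equal(res$p_ad_crc[g],
                 t.test(mat[g, i_crc], mat[g, i_ad], var.equal = TRUE)$p.value)
  }
  expect_equal(res$q_n_ad, bh_adjust(res$p_n_ad))
})

test_that("degenerate t-test cases follow the documented conventions", {
  m <- rbind(c(1, 1, 1, 1, 1, 1),        # identical groups -> p = 1
             c(0, 0, 0, 5, 5, 5))        # separated, zero variance -> p = 0
  tt <- methmarker:::.row_t_test(m, 1:3, 4:6)
  expect_equal(tt$p, c(1, 0))
  expect_equal(tt$t[1], 0)
})

test_that("Welch option matches t.test(var.equal = FALSE)", {
  set.seed(9)
  x <- matrix(rnorm(24, sd = rep(c(1, 3), each = 12)), nrow = 2, byrow = TRUE)
  tt <- methmarker:::.row_t_test(rbind(c(x[1, 1:6], x[2, 1:6])), 1:6, 7:12,
                                 var_equal = FALSE)
  ref <- t.test(x[2, 1:6], x[1, 1:6], var.equal = FALSE)
  expect_equal(tt$p, ref$p.value)
})

test_that("log_fold_change is mean(to) - mean(from) and linear in shifts", {
  mat <- rbind(gene_a = c(4.09, 4.09, 2.20, 2.20),
               gene_b = c(1, 1, 1, 1))
  g <- c("normal", "normal", "adenoma", "adenoma")
  lfc <- log_fold_change(mat, g, "normal", "adenoma")
  expect_equal(unname(lfc), c(-1.89, 0))
  mat2 <- mat
  mat2[, 3:4] <- mat2[, 3:4] + 0.7
  expect_equal(unname(log_fold_change(mat2, g, "normal", "adenoma")),
               unname(lfc) + 0.7)
  expect_error(log_fold_change(mat, g, "normal", "CRC"), "empty")
})

test_that("zero-noise planted trends are recovered exactly", {
  sim <- gen_staged_expression(n_genes = 40, n_per_group = 5,
                               n_trend_up = 4, n_trend_down = 4,
                               step_effect = 1.5, noise_sd = 0, seed = 42)
  res <- trend_select(sim$matrix, sim$samples$stage)
  expect_setequal(res$gene[res$selected], sim$truth$trend_genes$gene)
  sel <- res[res$selected, ]
  truth_dir <- sim$truth$trend_genes$direction[
    match(sel$gene, sim$truth$trend_genes$gene)]
  expect_equal(sel$direction, truth_dir)
  # constant (degenerate) genes are never selected
  expect_false(any(res$selected[res$degenerate]))
})

test_that("select_markers applies the tau, significance and logfc rule", {
  df <- data.frame(gene = c("a", "b", "c", "d"),
                   tau = c(0.9, 0.9, 0.2, -0.8),
                   q_n_ad = c(0.01, 0.2, 0.01, 0.2),
                   q_n_crc = c(0.2, 0.01, 0.01, 0.01),
                   logfc_n_ad = c(1.5, 0.5, 2, -0.2),
                   logfc_n_crc = c(0.5, 1.5, 2, -1.8))
  out <- select_markers(df)
  expect_equal(out$selected, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(out$direction, c("up", "up", "up", "down"))
  expect_error(select_markers(df, tau_min = -1), "positive")
})

test_that("venn_categorize maps significance patterns to categories", {
  df <- data.frame(q_n_ad = c(0.001, 0.34, 0.001, 0.5, NA),
                   q_n_crc = c(0.001, 0.001, 0.5, 0.5, 0.01))
  out <- venn_categorize(df, alpha = 0.05)
  expect_equal(out$venn,
               c("both", "CRC_only", "AD_only", "neither", "not_evaluable"))
})

test_that("comparisons with too-small groups are NA without affecting others", {
  set.seed(2)
  mat <- matrix(rnorm(10 * 7), nrow = 10)
  stages <- c("normal", "normal", "normal", "adenoma",
              "CRC", "CRC", "CRC")
  expect_message(res <- pairwise_group_tests(mat, stages), "not computable")
  expect_true(all(is.na(res$p_n_ad)))
  expect_true(all(!is.na(res$p_n_crc)))
})

test_that("demethylation screen flags re-expressed genes", {
  mat <- rbind(silenced = c(2, 2, 2, 5, 5, 5),
               flat = c(4, 4, 4, 4.2, 4.2, 4.2))
  g <- rep(c("control", "treated"), each = 3)
  out <- demethylation_screen(mat, g)
  expect_equal(out$reexpressed, c(TRUE, FALSE))
  expect_equal(out$logfc, c(3, 0.2))
})
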