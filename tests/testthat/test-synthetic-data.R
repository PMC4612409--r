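# Generators: determinism, zero-noise exactness, planted structure, and
# the bisulfite read error model.

test_that("gen_staged_expression plants exact means at zero noise", {
  sim <- gen_staged_expression(n_genes = 10, n_per_group = 3,
                               n_trend_up = 1, n_trend_down = 0,
                               step_effect = 1, noise_sd = 0, seed = 2)
  g <- sim$truth$trend_genes$gene
  expect_length(g, 1)
  x <- sim$matrix[g, ]
  st <- sim$samples$stage
  means <- tapply(x, st, mean)
  expect_equal(as.vector(diff(means)), c(1, 1))
  null_gene <- setdiff(rownames(sim$matrix), g)[1]
  expect_equal(unname(diff(range(sim$matrix[null_gene, ]))), 0)
})

test_that("no planting yields empty truth; invalid arguments are rejected", {
  sim <- gen_staged_expression(10, 3, 0, 0, seed = 5)
  expect_equal(nrow(sim$truth$trend_genes), 0)
  expect_error(gen_staged_expression(5, 3, 4, 4, seed = 1), "exceed")
  expect_error(gen_staged_expression(0, 3, seed = 1), "integer")
  expect_error(gen_staged_expression(10, 3, noise_sd = -1, seed = 1), ">= 0")
})

test_that("generators are byte-deterministic under a fixed seed", {
  a <- gen_staged_expression(30, 4, 3, 3, seed = 7)
  b <- gen_staged_expression(30, 4, 3, 3, seed = 7)
  expect_identical(a, b)
  t <- fixture_template()
  r1 <- gen_bisulfite_reads(t, rep(0.5, length(t$cpg_pos)), 20,
                            sub_rate = 0.02, indel_rate = 0.02, seed = 7)
  r2 <- gen_bisulfite_reads(t, rep(0.5, length(t$cpg_pos)), 20,
                            sub_rate = 0.02, indel_rate = 0.02, seed = 7)
  expect_identical(r1, r2)
  p1 <- gen_ct_plates(8, noise_sd = 0.3, seed = 7)
  p2 <- gen_ct_plates(8, noise_sd = 0.3, seed = 7)
  expect_identical(p1, p2)
  q1 <- gen_qscore_cores(c(NAT = 100, AD = 50), noise_sd = 4, seed = 7)
  q2 <- gen_qscore_cores(c(NAT = 100, AD = 50), noise_sd = 4, seed = 7)
  expect_identical(q1, q2)
})

test_that("generator calls do not disturb the caller's RNG stream", {
  set.seed(101)
  x1 <- runif(1)
  set.seed(101)
  invisible(gen_staged_expression(5, 2, seed = 3))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("fully methylated error-free reads equal the converted template", {
  t <- fixture_template()
  n <- length(t$cpg_pos)
  sim <- gen_bisulfite_reads(t, rep(1, n), n_reads = 10, seed = 1)
  expect_true(all(sim$reads == gsub("Y", "C", t$forward_ref)))
  sim0 <- gen_bisulfite_reads(t, rep(0, n), n_reads = 10, seed = 1)
  expect_true(all(sim0$reads == gsub("Y", "T", t$forward_ref)))
  # no C outside drawn-methylated CpG columns
  for (r in sim0$reads)
    expect_false(grepl("C", r, fixed = TRUE))
})

test_that("per-site draws follow an independent binomial under the same policy", {
  t <- fixture_template()
  n <- length(t$cpg_pos)
  sim <- gen_bisulfite_reads(t, rep(0.6, n), n_reads = 500, seed = 77)
  # observed C fraction at each CpG column equals the recorded draw
  for (k in seq_len(n)) {
    col <- substring(sim$reads, t$cpg_pos[k], t$cpg_pos[k])
    expect_equal(sum(col == "C"), sim$truth$site_c_counts[[k]])
  }
  # and the draw is binomial(500, 0.6) to within 4 SE
  se <- sqrt(0.6 * 0.4 * 500)
  expect_true(all(abs(sim$truth$site_c_counts - 300) < 4 * se))
})

test_that("mismatched methylation vector length is rejected", {
  t <- fixture_template()
  expect_error(gen_bisulfite_reads(t, c(0.5), 10, seed = 1), "length")
  expect_error(gen_bisulfite_reads(t, rep(1.5, length(t$cpg_pos)), 10,
                                   seed = 1), "\\[0, 1\\]")
})

test_that("partial conversion leaves some non-CpG cytosines unconverted", {
  t <- fixture_template()
  n <- length(t$cpg_pos)
  sim <- gen_bisulfite_reads(t, rep(0, n), n_reads = 200,
                             conversion_efficiency = 0.5, seed = 3)
  non_cpg_c <- setdiff(which(strsplit(t$seq, "")[[1]] == "C"), t$cpg_pos)
  frac_c <- mean(substring(sim$reads, non_cpg_c[1], non_cpg_c[1]) == "C")
  expect_gt(frac_c, 0.3)
  expect_lt(frac_c, 0.7)
})

test_that("homopolymer multiplier concentrates indels inside runs", {
  tpl <- amplicon_template("hp", paste0("ACGGAT", strrep("T", 10), "GACGTA",
                                        strrep("A", 10), "TCAGGA"))
  n <- length(tpl$cpg_pos)
  count_len <- function(mult) {
    sim <- gen_bisulfite_reads(tpl, rep(0.5, n), n_reads = 300,
                               indel_rate = 0.01,
                               homopolymer_multiplier = mult, seed = 11)
    mean(nchar(sim$reads) != tpl$length)
  }
  expect_gt(count_len(8), count_len(1))
})

test_that("plate generator plants offsets and shifts by construction", {
  shifts <- data.frame(mirna = "mir_002", group = "CRC", shift = -3)
  sim <- gen_ct_plates(6, plate_offsets = c(0, 1.5), planted_shifts = shifts,
                       noise_sd = 0, seed = 5)
  p <- sim$plates
  crc <- p$ct[p$mirna == "mir_002" & p$group == "CRC"]
  nat <- p$ct[p$mirna == "mir_002" & p$group == "NAT"]
  expect_equal(unique(nat - 0) - unique(crc), 3)
  cal <- p[p$is_calibrator, ]
  expect_equal(cal$ct[cal$plate == 2] - cal$ct[cal$plate == 1], 1.5)
})
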